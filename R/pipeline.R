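#' Run the full study pipeline
#'
#' End-to-end driver: renders the 16 tone-pair WAVs and 8 melody WAVs with
#' their manifests, simulates response tables for both experiments (the
#' two-tone pitch comparison with 19 + 20 participants, the melody off-key
#' judgment with 18 + 20), scores them, writes cohort summaries and the
#' comparison-schedule results, and records a run manifest with an MD5
#' checksum of every output. A single global seed deterministically derives
#' per-stage child seeds, so re-running with the same seed reproduces every
#' output byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param config A [sim_config()]; cohort sizes for experiment 1. Experiment
#'   2 uses `n_young_exp2`/`n_old_exp2`.
#' @param n_young_exp2,n_old_exp2 Cohort sizes for the melody experiment.
#' @param stereo Write two-channel (diotic) WAVs.
#' @param quiet Suppress progress messages.
#'
#' @return A `run_manifest` object (list with `seed`, `config`, and a
#'   `files` tibble of paths and MD5 checksums), invisibly.
#'
#' @export
run_full_study <- function(out_dir, seed = 1L, config = sim_config(),
                           n_young_exp2 = 18L, n_old_exp2 = 20L,
                           stereo = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 2L)

  say("stage: stimuli (experiment 1)")
  pairs <- experiment1_pairs()
  for (i in seq_len(nrow(pairs))) {
    for (side in c("a", "b")) {
      tone <- pairs[[paste0("tone_", side)]][[i]]
      write_wav(synthesize_tone(tone),
                file.path(out_dir, sprintf("%s_tone%s.wav",
                                           pairs$condition[i], toupper(side))),
                stereo = stereo)
    }
  }
  readr::write_csv(stimulus_manifest(pairs),
                   file.path(out_dir, "stimuli_experiment1.csv"))

  say("stage: stimuli (experiment 2)")
  versions <- experiment2_versions()
  for (i in seq_len(nrow(versions))) {
    write_wav(render_melody(versions$notes[[i]]),
              file.path(out_dir, sprintf("melody_%s.wav",
                                         versions$condition[i])),
              stereo = stereo)
  }
  readr::write_csv(melody_manifest(versions),
                   file.path(out_dir, "stimuli_experiment2.csv"))

  say("stage: simulation + analysis")
  cfg2 <- sim_config(
    n_young = n_young_exp2, n_old = n_old_exp2,
    mu_trait = config$mu_trait, sd_trait = config$sd_trait,
    beta_lowcut = config$beta_lowcut, beta_series = config$beta_series
  )
  for (exp in 1:2) {
    cfg <- if (exp == 1L) config else cfg2
    responses <- simulate_cohort(cfg, experiment = exp, seed = child[exp])
    scores <- score_responses(responses)
    export_responses(responses,
                     file.path(out_dir, sprintf("responses_exp%d.csv", exp)))
    readr::write_csv(scores,
                     file.path(out_dir, sprintf("scores_exp%d.csv", exp)))
    readr::write_csv(cohort_summary(scores),
                     file.path(out_dir, sprintf("summary_exp%d.csv", exp)))
    readr::write_csv(cohort_summary(scores, by = "age_group"),
                     file.path(out_dir, sprintf("summary_by_age_exp%d.csv", exp)))
    readr::write_csv(comparison_schedule(scores),
                     file.path(out_dir, sprintf("tests_exp%d.csv", exp)))
    readr::write_csv(comparison_schedule(scores, by_age = TRUE),
                     file.path(out_dir, sprintf("tests_by_age_exp%d.csv", exp)))
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  manifest_tbl <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest_tbl, file.path(out_dir, "manifest.csv"))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(structure(
    list(seed = seed, config = config, files = manifest_tbl, out_dir = out_dir),
    class = "run_manifest"
  ))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed = %d, %d files in %s\n",
              x$seed, nrow(x$files), x$out_dir))
  invisible(x)
}

#' Validate a generated stimulus set
#'
#' Re-reads every WAV written by [run_full_study()] and checks it against the
#' stimulus design: exact duration in samples, a spectral peak within one FFT
#' bin of every retained partial, and all eliminated harmonics (those of the
#' fundamental falling outside the retained set, up to 2 kHz) at least
#' `min_rejection_db` below the spectral maximum. Melody files are checked
#' note by note on the stationary (ramp-free) portion of each note.
#'
#' @param out_dir Directory holding the WAVs.
#' @param min_rejection_db Required suppression of eliminated harmonics, dB.
#'
#' @return A tibble with one row per file and check: `file`, `check`,
#'   `pass`, `detail`. All-pass is `all(report$pass)`.
#'
#' @export
validate_stimuli <- function(out_dir, min_rejection_db = 40) {
  pairs <- experiment1_pairs()
  versions <- experiment2_versions()
  rows <- list()
  add <- function(file, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      file = file, check = check, pass = pass, detail = detail
    )
  }

  check_tone_segment <- function(file, seg, tone, sr) {
    spec <- waveform_spectrum(seg, sr)
    # -6 dB allows worst-case scalloping loss (~3.9 dB) of an off-bin partial
    for (f in tone$partials$frequency) {
      lev <- relative_level_db(spec, f)
      add(file, sprintf("partial_%g_present", f), lev > -6,
          sprintf("%.1f dB re max", lev))
    }
    eliminated <- setdiff(harmonic_partials(tone$f0, 2000)$frequency,
                          tone$partials$frequency)
    for (f in eliminated) {
      lev <- relative_level_db(spec, f)
      add(file, sprintf("harmonic_%g_rejected", f), lev < -min_rejection_db,
          sprintf("%.1f dB re max", lev))
    }
  }

  for (i in seq_len(nrow(pairs))) {
    for (side in c("a", "b")) {
      file <- sprintf("%s_tone%s.wav", pairs$condition[i], toupper(side))
      path <- file.path(out_dir, file)
      if (!file.exists(path)) {
        add(file, "exists", FALSE, "missing file")
        next
      }
      tone <- pairs[[paste0("tone_", side)]][[i]]
      wav <- read_wav(path)
      mono <- if (is.matrix(wav$samples)) wav$samples[, 1L] else wav$samples
      add(file, "duration_samples",
          wav$n_frames == round(tone$duration * tone$sample_rate),
          sprintf("%d frames", wav$n_frames))
      # analyse the stationary portion between the ramps
      nr <- round(tone$ramp * wav$sample_rate)
      seg <- mono[(nr + 1L):(wav$n_frames - nr)]
      check_tone_segment(file, seg, tone, wav$sample_rate)
    }
  }

  for (i in seq_len(nrow(versions))) {
    file <- sprintf("melody_%s.wav", versions$condition[i])
    path <- file.path(out_dir, file)
    if (!file.exists(path)) {
      add(file, "exists", FALSE, "missing file")
      next
    }
    notes <- versions$notes[[i]]
    wav <- read_wav(path)
    mono <- if (is.matrix(wav$samples)) wav$samples[, 1L] else wav$samples
    expected <- sum(round(notes$duration * wav$sample_rate))
    add(file, "duration_samples", wav$n_frames == expected,
        sprintf("%d frames", wav$n_frames))
    offset <- 0L
    for (j in seq_len(nrow(notes))) {
      tone <- notes$tone[[j]]
      n <- round(tone$duration * wav$sample_rate)
      nr <- round(tone$ramp * wav$sample_rate)
      seg <- mono[(offset + nr + 1L):(offset + n - nr)]
      check_tone_segment(sprintf("%s#note%d", file, j), seg, tone,
                         wav$sample_rate)
      offset <- offset + n
    }
  }

  dplyr::bind_rows(rows)
}
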