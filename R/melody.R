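#' Default scale for the "Lightly Row" passage
#'
#' Just-intonation C-major degrees anchored so that E = 230 Hz and G = 276 Hz,
#' the two fundamentals of the two-tone experiment (their 6:5 ratio is an
#' exact just minor third of ~316 cents). The note fundamentals of the
#' original recorded stimuli are not published; this anchoring is the
#' package's documented convention, chosen for maximal consistency with the
#' tone-pair experiment, and can be overridden.
#'
#' @return A named numeric vector mapping degrees C, D, E, F, G to Hz.
#'
#' @export
lightly_row_scale <- function() {
  c(C = 184, D = 207, E = 230, F = 736 / 3, G = 276)
}

#' The thirteen-note "Lightly Row" passage
#'
#' The opening phrase of the children's song "Lightly Row" (also known as
#' "Butterfly"): G E E | F D D | C D E F | G G G. Notes are 500 ms except the
#' phrase-final notes (positions 3, 6 and 13), which are 1000 ms — the song's
#' conventional rhythm.
#'
#' @param scale Named degree-to-Hz map covering C, D, E, F, G; see
#'   [lightly_row_scale()].
#' @param long_positions Positions (1-13) receiving the 1000-ms duration.
#'
#' @return A tibble with columns `position`, `degree`, `f0`, `duration`.
#'
#' @examples
#' lightly_row_passage()
#' @export
lightly_row_passage <- function(scale = lightly_row_scale(),
                                long_positions = c(3L, 6L, 13L)) {
  degrees <- c("G", "E", "E", "F", "D", "D", "C", "D", "E", "F", "G", "G", "G")
  missing <- setdiff(degrees, names(scale))
  if (length(missing) > 0L || any(!is.finite(scale)) || any(scale <= 0)) {
    abort(paste0("Scale table must map positive frequencies for degrees: ",
                 paste(unique(degrees), collapse = ", ")),
          class = "pitchshift_config_error")
  }
  tibble::tibble(
    position = seq_along(degrees),
    degree = degrees,
    f0 = unname(scale[degrees]),
    duration = ifelse(.data$position %in% long_positions, 1.0, 0.5)
  )
}

#' Band-limited versions of the melody
#'
#' Applies the eight elimination conditions of the two-tone experiment
#' (X1-X4, Y1-Y4) to every note of the passage. Each note becomes a
#' [complex_tone()] holding only the partials that survive the condition's
#' low/high cutoffs; a note whose entire spectrum would be eliminated aborts
#' construction, naming the note and version.
#'
#' @param passage A passage tibble from [lightly_row_passage()].
#' @param ramp,sample_rate,bit_depth Synthesis parameters per note.
#'
#' @return A tibble with one row per version: `condition`, `series`,
#'   `low_cut`, `high_cut`, and a `notes` list-column; each element is the
#'   passage tibble augmented with a `tone` list-column and an `n_partials`
#'   column.
#'
#' @examples
#' versions <- experiment2_versions()
#' versions$notes[[8]][, c("position", "degree", "f0", "n_partials")]
#' @export
experiment2_versions <- function(passage = lightly_row_passage(),
                                 ramp = 0.01, sample_rate = 44100,
                                 bit_depth = 16L) {
  stopifnot(is.data.frame(passage), nrow(passage) == 13L)
  design <- tidyr::expand_grid(series = c("X", "Y"), index = 1:4) |>
    dplyr::mutate(
      condition = paste0(.data$series, .data$index),
      low_cut = c(250, 500, 750, 1000)[.data$index],
      high_cut = ifelse(.data$series == "X", 1600, 1300)
    )

  build_notes <- function(cond, lo, hi) {
    tones <- purrr::pmap(
      list(passage$position, passage$degree, passage$f0, passage$duration),
      function(pos, deg, f0, dur) {
        tryCatch(
          complex_tone(f0, low_cut = lo, high_cut = hi, duration = dur,
                       ramp = ramp, sample_rate = sample_rate,
                       bit_depth = bit_depth),
          pitchshift_empty_spectrum = function(e) {
            abort(sprintf(
              "Note %d (%s, %g Hz) of version %s retains no partials.",
              pos, deg, f0, cond
            ), class = "pitchshift_construction_error")
          }
        )
      }
    )
    dplyr::mutate(
      passage,
      tone = tones,
      n_partials = purrr::map_int(tones, ~ nrow(.x$partials))
    )
  }

  design |>
    dplyr::mutate(
      notes = purrr::pmap(
        list(.data$condition, .data$low_cut, .data$high_cut), build_notes
      )
    ) |>
    dplyr::select("condition", "series", "low_cut", "high_cut", "notes")
}

#' Tabulate the retained partials of all melody versions
#'
#' @param versions A tibble from [experiment2_versions()].
#'
#' @return A tibble with one row per note per retained partial: `condition`,
#'   `position`, `degree`, `f0`, `rank`, `frequency`, `duration`.
#'
#' @export
melody_manifest <- function(versions) {
  versions |>
    dplyr::select("condition", "notes") |>
    dplyr::mutate(notes = purrr::map(.data$notes, function(nt) {
      nt |>
        dplyr::mutate(tbl = purrr::map(.data$tone, ~ .x$partials)) |>
        dplyr::select("position", "degree", "f0", "duration", "tbl") |>
        tidyr::unnest("tbl")
    })) |>
    tidyr::unnest("notes")
}
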