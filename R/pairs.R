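#' The eight two-tone conditions of the pitch-comparison experiment
#'
#' Builds the eight tone pairs used in the forced-choice experiment. Each pair
#' holds tone A (F0 = 230 Hz) and tone B (F0 = 276 Hz), a 316-cent interval.
#' The X series eliminates partials above 1600 Hz, the Y series above 1300 Hz;
#' within each series the low-frequency elimination cutoff steps through 250,
#' 500, 750 and 1000 Hz (conditions 1-4), simulating increasingly severe
#' low-tone hearing loss. The design makes the lowest retained partial of tone
#' A (lower F0) higher than that of tone B, so a listener attending to the
#' audible spectrum ranks the pair opposite to a listener attending to the
#' (possibly missing) fundamental.
#'
#' @param f0_a,f0_b Fundamentals of tones A and B in Hz.
#' @param duration,ramp,sample_rate,bit_depth Synthesis parameters passed to
#'   [complex_tone()].
#'
#' @return A tibble with one row per condition: `condition`, `series`,
#'   `low_cut`, `high_cut`, list-columns `tone_a`/`tone_b` of
#'   [complex_tone()] objects, and derived columns `lowest_a`, `lowest_b`,
#'   `top_a`, `top_b`, `n_partials_a`, `n_partials_b`.
#'
#' @examples
#' pairs <- experiment1_pairs()
#' pairs[, c("condition", "low_cut", "high_cut", "lowest_a", "lowest_b")]
#' @export
experiment1_pairs <- function(f0_a = 230, f0_b = 276,
                              duration = 0.5, ramp = 0.01,
                              sample_rate = 44100, bit_depth = 16L) {
  design <- tidyr::expand_grid(
    series = c("X", "Y"),
    index = 1:4
  ) |>
    dplyr::mutate(
      condition = paste0(.data$series, .data$index),
      low_cut = c(250, 500, 750, 1000)[.data$index],
      high_cut = ifelse(.data$series == "X", 1600, 1300)
    )

  pairs <- design |>
    dplyr::mutate(
      tone_a = purrr::map2(.data$low_cut, .data$high_cut, function(lo, hi) {
        complex_tone(f0_a, low_cut = lo, high_cut = hi, duration = duration,
                     ramp = ramp, sample_rate = sample_rate,
                     bit_depth = bit_depth)
      }),
      tone_b = purrr::map2(.data$low_cut, .data$high_cut, function(lo, hi) {
        complex_tone(f0_b, low_cut = lo, high_cut = hi, duration = duration,
                     ramp = ramp, sample_rate = sample_rate,
                     bit_depth = bit_depth)
      }),
      lowest_a = purrr::map_dbl(.data$tone_a, lowest_partial),
      lowest_b = purrr::map_dbl(.data$tone_b, lowest_partial),
      top_a = purrr::map_dbl(.data$tone_a, top_partial),
      top_b = purrr::map_dbl(.data$tone_b, top_partial),
      n_partials_a = purrr::map_int(.data$tone_a, ~ nrow(.x$partials)),
      n_partials_b = purrr::map_int(.data$tone_b, ~ nrow(.x$partials))
    ) |>
    dplyr::select(
      "condition", "series", "low_cut", "high_cut", "tone_a", "tone_b",
      "lowest_a", "lowest_b", "top_a", "top_b",
      "n_partials_a", "n_partials_b"
    )

  # designed crossover: spectral and F0 orderings must disagree in every pair
  bad <- pairs$lowest_a <= pairs$lowest_b
  if (any(bad)) {
    abort(paste0(
      "Designed crossover violated (lowest partial of tone A not above ",
      "tone B) for: ", paste(pairs$condition[bad], collapse = ", ")
    ), class = "pitchshift_design_error")
  }
  pairs
}

#' Tabulate the partials of a stimulus set
#'
#' Flattens a pair table from [experiment1_pairs()] into one row per retained
#' partial, the layout used for the stimulus manifest CSV.
#'
#' @param pairs A tibble from [experiment1_pairs()].
#'
#' @return A tibble with columns `condition`, `tone` (`"A"`/`"B"`), `f0`,
#'   `rank`, `frequency`, `duration`.
#'
#' @export
stimulus_manifest <- function(pairs) {
  long <- tidyr::pivot_longer(
    dplyr::select(pairs, "condition", "tone_a", "tone_b"),
    cols = c("tone_a", "tone_b"),
    names_to = "tone", values_to = "obj"
  ) |>
    dplyr::mutate(tone = ifelse(.data$tone == "tone_a", "A", "B"))
  long |>
    dplyr::mutate(tbl = purrr::map(.data$obj, tidy)) |>
    dplyr::select("condition", "tone", "tbl") |>
    tidyr::unnest("tbl")
}
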