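#' The paired comparison schedule over the eight conditions
#'
#' Runs the study's statistical schedule on a score table:
#' * Wilcoxon signed-rank tests on Shift Index values for the within-series
#'   contrasts against the mildest low-cut condition (X1 vs X2/X3/X4, Y1 vs
#'   Y2/Y3/Y4) and the matched between-series contrasts (Xk vs Yk, k =
#'   1..4) — 10 comparisons;
#' * McNemar tests on the ambiguity flag of every other condition against
#'   the Y4 baseline (the pure-tone pair expected to elicit the fewest
#'   ambiguous responses) — 7 comparisons.
#'
#' P-values are unadjusted by default; `holm = TRUE` appends a `p_holm`
#' column (Holm correction within each test family).
#'
#' @param scores A score tibble from [score_responses()] covering all eight
#'   conditions; two repetitions are required for the McNemar block.
#' @param by_age Re-run the whole schedule within each age group.
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank()].
#' @param mcnemar_exact Use the exact binomial McNemar variant.
#' @param holm Append Holm-adjusted p-values.
#'
#' @return A tibble with one row per comparison: `comparison`, `method`,
#'   `statistic`, `p_value`, `n_effective`, `mode` (plus `age_group` when
#'   stratified and `p_holm` when requested).
#'
#' @examples
#' simulate_cohort(seed = 7) |> score_responses() |> comparison_schedule()
#' @export
comparison_schedule <- function(scores, by_age = FALSE,
                                mode = "auto", mcnemar_exact = FALSE,
                                holm = FALSE) {
  stopifnot(is.data.frame(scores))
  if (by_age) {
    out <- scores |>
      dplyr::group_split(.data$age_group) |>
      purrr::map(function(g) {
        comparison_schedule(g, by_age = FALSE, mode = mode,
                            mcnemar_exact = mcnemar_exact, holm = holm) |>
          dplyr::mutate(age_group = g$age_group[1L], .before = 1L)
      })
    return(dplyr::bind_rows(out))
  }

  absent <- setdiff(condition_levels(), unique(scores$condition))
  if (length(absent) > 0L) {
    abort(paste0("Schedule needs all eight conditions; missing: ",
                 paste(absent, collapse = ", ")),
          class = "pitchshift_schedule_error")
  }

  si_wide <- scores |>
    dplyr::select("participant_id", "condition", "si") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "si")

  wilcoxon_pairs <- list(
    c("X1", "X2"), c("X1", "X3"), c("X1", "X4"),
    c("Y1", "Y2"), c("Y1", "Y3"), c("Y1", "Y4"),
    c("X1", "Y1"), c("X2", "Y2"), c("X3", "Y3"), c("X4", "Y4")
  )
  wres <- purrr::map(wilcoxon_pairs, function(pr) {
    tidy(wilcoxon_signed_rank(
      si_wide[[pr[1L]]], si_wide[[pr[2L]]], mode = mode,
      comparison = paste(pr[1L], "vs", pr[2L])
    ))
  })

  mres <- list()
  if (all(!is.na(scores$ambiguous))) {
    amb_wide <- scores |>
      dplyr::select("participant_id", "condition", "ambiguous") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "ambiguous")
    others <- setdiff(condition_levels(), "Y4")
    mres <- purrr::map(others, function(cond) {
      b <- sum(amb_wide[[cond]] & !amb_wide$Y4)
      c <- sum(!amb_wide[[cond]] & amb_wide$Y4)
      tidy(mcnemar_test(b, c, exact = mcnemar_exact,
                        comparison = paste(cond, "vs Y4")))
    })
  }

  res <- dplyr::bind_rows(c(wres, mres))
  if (holm) {
    res <- res |>
      dplyr::group_by(.data$method) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  res
}
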