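#' Shift Index
#'
#' `SI = (sp - f0) / (sp + f0)`, the normalised excess of spectral over F0
#' responses for one participant-condition: +1 for all-spectral responding,
#' -1 for all-F0. With the study design's two repetitions per task the only
#' attainable values are -1, 0 and +1.
#'
#' @param sp,f0 Counts of spectral and F0 responses (non-negative,
#'   vectorised).
#'
#' @return SI value(s) in `[-1, 1]`.
#'
#' @examples
#' shift_index(2, 0)
#' shift_index(c(2, 1, 0), c(0, 1, 2))
#' @export
shift_index <- function(sp, f0) {
  if (any(sp < 0) || any(f0 < 0)) {
    abort("Counts must be non-negative.", class = "pitchshift_invalid_parameter")
  }
  if (any(sp + f0 == 0)) {
    abort("SI is undefined when sp + f0 = 0.",
          class = "pitchshift_undefined_score")
  }
  (sp - f0) / (sp + f0)
}

#' Classify a tally as ambiguous
#'
#' An ambiguous response is a difference between the participant's two
#' responses to the same task: `sp = f0 = 1` in the two-repetition design.
#' The definition is specific to two repetitions; other designs are
#' rejected rather than silently generalised.
#'
#' @param sp,f0 Counts of spectral and F0 responses (vectorised); each pair
#'   must sum to 2.
#'
#' @return Logical vector, `TRUE` where the two responses disagree.
#'
#' @export
classify_ambiguous <- function(sp, f0) {
  if (any(sp + f0 != 2)) {
    abort("Ambiguity is defined only for the two-repetition design.",
          class = "pitchshift_unsupported_design")
  }
  sp == 1 & f0 == 1
}

#' Score a response table
#'
#' Tallies spectral and F0 responses per participant and condition, and
#' derives the Shift Index and (for two-repetition designs) the ambiguity
#' flag. Incomplete records — a participant-condition cell with fewer
#' repetitions than the rest of the table — are rejected, not imputed.
#'
#' @param responses A response tibble in the [simulate_cohort()] schema.
#'
#' @return A tibble with one row per participant-condition: `participant_id`,
#'   `age_group` (if present), `experiment` (if present), `condition`, `sp`,
#'   `f0`, `si`, `ambiguous` (`NA` unless the design has two repetitions).
#'
#' @examples
#' simulate_cohort(seed = 7) |> score_responses()
#' @export
score_responses <- function(responses) {
  stopifnot(is.data.frame(responses), nrow(responses) > 0)
  bad <- setdiff(unique(responses$response), c("spectral", "f0"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown response values: ", paste(bad, collapse = ", ")),
          class = "pitchshift_invalid_parameter")
  }
  keys <- intersect(c("participant_id", "age_group", "experiment", "condition"),
                    names(responses))
  scores <- responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      sp = sum(.data$response == "spectral"),
      f0 = sum(.data$response == "f0"),
      .groups = "drop"
    )
  reps <- unique(scores$sp + scores$f0)
  if (length(reps) != 1L) {
    abort("Unbalanced design: participant-condition cells differ in repetition count (missing responses are rejected, not imputed).",
          class = "pitchshift_unsupported_design")
  }
  scores |>
    dplyr::mutate(
      si = shift_index(.data$sp, .data$f0),
      ambiguous = if (reps == 2L) classify_ambiguous(.data$sp, .data$f0)
                  else NA
    )
}

#' Cohort summary per condition
#'
#' For each condition (optionally within groups, e.g. age group): mean Shift
#' Index, and the percentage breakdown of participants into ambiguous,
#' unambiguous-spectral (SI = +1) and unambiguous-F0 (SI = -1) responses.
#' The three percentages sum to 100 within rounding. Conditions with no
#' scores are dropped with a warning.
#'
#' @param scores A score tibble from [score_responses()].
#' @param by Optional extra grouping column name (e.g. `"age_group"`).
#'
#' @return A tibble with columns `condition` (and `by`, if given), `n`,
#'   `mean_si`, `pct_ambiguous`, `pct_spectral`, `pct_f0`.
#'
#' @export
cohort_summary <- function(scores, by = NULL) {
  stopifnot(is.data.frame(scores))
  missing_cond <- setdiff(condition_levels(), unique(scores$condition))
  if (length(missing_cond) > 0L) {
    warn(paste0("No scores for condition(s): ",
                paste(missing_cond, collapse = ", "), "; omitted."))
  }
  keys <- c(by, "condition")
  out <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_si = mean(.data$si),
      pct_ambiguous = 100 * mean(.data$ambiguous),
      pct_spectral = 100 * mean(.data$si == 1),
      pct_f0 = 100 * mean(.data$si == -1),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  class(out) <- c("si_summary", class(out))
  out
}
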