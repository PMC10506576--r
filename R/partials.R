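#' Enumerate the harmonic series of a fundamental
#'
#' Lists every integer multiple of `f0` up to `max_freq`. The k-th harmonic of
#' a complex tone has frequency `k * f0`; rank 1 is the fundamental itself.
#'
#' @param f0 Fundamental frequency in Hz (positive).
#' @param max_freq Highest frequency to include, in Hz; must be at least `f0`.
#'
#' @return A tibble with columns `rank` (integer) and `frequency` (Hz),
#'   ascending.
#'
#' @examples
#' harmonic_partials(230, 1400)
#' @export
harmonic_partials <- function(f0, max_freq) {
  check_positive_freq(f0, "f0")
  if (!is.numeric(max_freq) || length(max_freq) != 1L || !is.finite(max_freq)) {
    abort("`max_freq` must be a single finite number.",
          class = "pitchshift_invalid_parameter")
  }
  # relative tolerance keeps a harmonic sitting exactly on max_freq
  n <- floor(max_freq / f0 + 1e-9)
  if (n < 1L) {
    abort(sprintf("No harmonic of f0 = %g Hz fits below %g Hz.", f0, max_freq),
          class = "pitchshift_invalid_parameter")
  }
  ranks <- seq_len(n)
  tibble::tibble(rank = as.integer(ranks), frequency = ranks * f0)
}

#' Band-limit a harmonic series
#'
#' Keeps the harmonics of `f0` whose frequencies survive the hearing-loss
#' simulation: partials with frequencies strictly below `low_cut` (simulated
#' low-tone loss) and strictly above `high_cut` (simulated high-tone loss, or
#' low-pass filtering by obstacles) are eliminated. A partial exactly at a
#' cutoff is retained.
#'
#' @param f0 Fundamental frequency in Hz (positive).
#' @param low_cut,high_cut Elimination cutoffs in Hz, `low_cut < high_cut`.
#'
#' @return A tibble with columns `rank` and `frequency`, ascending. Raises a
#'   `pitchshift_empty_spectrum` error when no partial survives, so the caller
#'   can distinguish a fully eliminated tone from a construction bug.
#'
#' @examples
#' band_limited_partials(230, 1000, 1600) # 5th and 6th harmonics
#' @export
band_limited_partials <- function(f0, low_cut, high_cut) {
  check_positive_freq(f0, "f0")
  if (!(low_cut < high_cut)) {
    abort("`low_cut` must be below `high_cut`.",
          class = "pitchshift_invalid_parameter")
  }
  all <- harmonic_partials(f0, high_cut)
  tol <- 1e-9 * f0
  kept <- dplyr::filter(all, .data$frequency >= low_cut - tol)
  if (nrow(kept) == 0L) {
    abort(sprintf(
      "All partials of f0 = %g Hz are eliminated by the [%g, %g] Hz band.",
      f0, low_cut, high_cut
    ), class = "pitchshift_empty_spectrum")
  }
  kept
}

#' Interval between two frequencies in cents
#'
#' One cent is 1/100 of an equal-tempered semitone; the interval from `f_low`
#' to `f_high` is `1200 * log2(f_high / f_low)`. Negative when `f_high` is the
#' lower frequency.
#'
#' @param f_low,f_high Frequencies in Hz (positive). Vectorised.
#'
#' @return Interval(s) in cents.
#'
#' @examples
#' cents_interval(230, 276) # ~316 cents, a just minor third
#' cents_interval(220, 440) # one octave = 1200 cents
#' @export
cents_interval <- function(f_low, f_high) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      any(!is.finite(f_low)) || any(!is.finite(f_high)) ||
      any(f_low <= 0) || any(f_high <= 0)) {
    abort("Frequencies must be positive and finite.",
          class = "pitchshift_invalid_parameter")
  }
  1200 * log2(f_high / f_low)
}

check_positive_freq <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive frequency in Hz.", name),
          class = "pitchshift_invalid_parameter")
  }
  invisible(x)
}
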