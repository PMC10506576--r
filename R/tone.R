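#' Construct a harmonic complex tone
#'
#' A complex tone is a set of sinusoidal partials drawn from the harmonic
#' series of a fundamental `f0`, with a fixed duration, raised-cosine
#' rise/fall ramps, and a target sample format. Partials can be given
#' explicitly (a tibble as returned by [harmonic_partials()]) or derived by
#' band-limiting with `low_cut`/`high_cut`.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param partials Tibble with columns `rank`, `frequency`; defaults to the
#'   band-limited harmonic series when `low_cut`/`high_cut` are given.
#' @param low_cut,high_cut Optional elimination cutoffs in Hz (used only when
#'   `partials` is missing).
#' @param duration Tone duration in seconds; must exceed twice the ramp.
#' @param ramp Rise time = fall time, seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth Target PCM bit depth.
#'
#' @return An object of class `complex_tone`.
#'
#' @examples
#' complex_tone(230, low_cut = 1000, high_cut = 1600)
#' @export
complex_tone <- function(f0, partials = NULL, low_cut = NULL, high_cut = NULL,
                         duration = 0.5, ramp = 0.01,
                         sample_rate = 44100, bit_depth = 16L) {
  check_positive_freq(f0, "f0")
  if (is.null(partials)) {
    if (is.null(low_cut) || is.null(high_cut)) {
      abort("Supply either `partials` or both `low_cut` and `high_cut`.",
            class = "pitchshift_invalid_parameter")
    }
    partials <- band_limited_partials(f0, low_cut, high_cut)
  }
  partials <- tibble::as_tibble(partials)
  if (nrow(partials) == 0L) {
    abort("A complex tone must retain at least one partial.",
          class = "pitchshift_empty_spectrum")
  }
  if (any(abs(partials$frequency - partials$rank * f0) >
            1e-9 * partials$frequency)) {
    abort("Every partial must equal harmonic_rank * f0.",
          class = "pitchshift_invalid_parameter")
  }
  if (is.unsorted(partials$rank, strictly = TRUE) ||
      is.unsorted(partials$frequency, strictly = TRUE)) {
    abort("Partials must be strictly increasing in rank and frequency.",
          class = "pitchshift_invalid_parameter")
  }
  if (!(duration > 2 * ramp)) {
    abort("`duration` must exceed twice the ramp time.",
          class = "pitchshift_invalid_parameter")
  }
  structure(
    list(
      f0 = f0,
      partials = partials,
      duration = duration,
      ramp = ramp,
      sample_rate = sample_rate,
      bit_depth = as.integer(bit_depth)
    ),
    class = "complex_tone"
  )
}

#' @export
print.complex_tone <- function(x, ...) {
  cat(sprintf(
    "<complex_tone> f0 = %g Hz, %d partial%s (%s Hz), %g ms\n",
    x$f0, nrow(x$partials), if (nrow(x$partials) == 1L) "" else "s",
    paste(round(x$partials$frequency, 1), collapse = ", "),
    1000 * x$duration
  ))
  invisible(x)
}

#' @rdname complex_tone
#' @param x A `complex_tone`.
#' @param ... Unused.
#' @export
tidy.complex_tone <- function(x, ...) {
  tibble::tibble(
    f0 = x$f0,
    rank = x$partials$rank,
    frequency = x$partials$frequency,
    duration = x$duration
  )
}

is_pure_tone <- function(tone) nrow(tone$partials) == 1L

lowest_partial <- function(tone) tone$partials$frequency[1L]

top_partial <- function(tone) tone$partials$frequency[nrow(tone$partials)]
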