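#' Render a complex tone to a waveform
#'
#' Additive synthesis: equal-amplitude, zero-phase sine partials are summed,
#' shaped by raised-cosine (Hann half-window) rise and fall ramps, and peak-
#' normalised so the largest sample magnitude is `1 - 2^-(bit_depth - 1)`,
#' the largest value representable after signed PCM quantisation.
#'
#' @param tone A [complex_tone()].
#'
#' @return A numeric vector of `round(duration * sample_rate)` samples in
#'   `[-1, 1]`, with attribute `sample_rate`.
#'
#' @examples
#' w <- synthesize_tone(complex_tone(230, low_cut = 1000, high_cut = 1600))
#' length(w) # 22050 samples for 500 ms at 44.1 kHz
#' @export
synthesize_tone <- function(tone) {
  stopifnot(inherits(tone, "complex_tone"))
  n <- round(tone$duration * tone$sample_rate)
  t <- (seq_len(n) - 1) / tone$sample_rate
  x <- rowSums(sapply(tone$partials$frequency, function(f) sin(2 * pi * f * t)))
  x <- x * ramp_envelope(n, tone$ramp, tone$sample_rate)
  peak_target <- 1 - 2^-(tone$bit_depth - 1L)
  x <- x * (peak_target / max(abs(x)))
  if (max(abs(x)) > peak_target + 1e-12) {
    abort("Internal error: waveform clips after normalisation.")
  }
  structure(x, sample_rate = tone$sample_rate)
}

# Hann half-window ramps; first and last samples are exactly zero.
ramp_envelope <- function(n, ramp, sample_rate) {
  nr <- round(ramp * sample_rate)
  env <- rep(1, n)
  if (nr >= 2L) {
    rise <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
    env[seq_len(nr)] <- rise
    env[n + 1L - seq_len(nr)] <- rise
  }
  env
}

#' Render a melody version to a single waveform
#'
#' Concatenates the per-note waveforms of one band-limited melody version,
#' each note carrying its own rise/fall ramps; there is no inter-note
#' silence, the ramps alone shape note onsets and offsets.
#'
#' @param notes A notes tibble with a `tone` list-column of [complex_tone()]
#'   objects (one element of the `notes` column of
#'   [experiment2_versions()]), or a single row of that versions table.
#'
#' @return A numeric waveform vector with attribute `sample_rate`.
#'
#' @export
render_melody <- function(notes) {
  if (is.data.frame(notes) && "notes" %in% names(notes)) {
    stopifnot(nrow(notes) == 1L)
    notes <- notes$notes[[1L]]
  }
  waves <- purrr::map(notes$tone, synthesize_tone)
  sr <- unique(purrr::map_dbl(waves, ~ attr(.x, "sample_rate")))
  stopifnot(length(sr) == 1L)
  structure(unlist(waves, use.names = FALSE), sample_rate = sr)
}

#' Locate spectral peaks of a waveform
#'
#' Discrete-Fourier magnitude spectrum of a (windowless) waveform segment,
#' used to verify that rendered stimuli contain energy only at their retained
#' partials.
#'
#' @param waveform Numeric samples.
#' @param sample_rate Sampling rate in Hz; taken from the waveform's
#'   `sample_rate` attribute when absent.
#'
#' @return A tibble with columns `frequency` (Hz, up to Nyquist) and
#'   `magnitude` (linear, unnormalised).
#'
#' @export
waveform_spectrum <- function(waveform, sample_rate = attr(waveform, "sample_rate")) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, !is.null(sample_rate))
  n <- length(waveform)
  mag <- Mod(fft(as.numeric(waveform)))[seq_len(floor(n / 2) + 1L)]
  tibble::tibble(
    frequency = (seq_along(mag) - 1) * sample_rate / n,
    magnitude = mag
  )
}

# dB level of the spectrum near `freq` (max within `halfwidth_bins` bins),
# relative to the global spectral maximum.
relative_level_db <- function(spectrum, freq, halfwidth_bins = 1) {
  binwidth <- spectrum$frequency[2L] - spectrum$frequency[1L]
  near <- abs(spectrum$frequency - freq) <= halfwidth_bins * binwidth + 1e-9
  if (!any(near)) return(-Inf)
  20 * log10(max(spectrum$magnitude[near]) / max(spectrum$magnitude))
}
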