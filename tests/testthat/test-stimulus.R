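test_that("complex_tone enforces its invariants", {
  t1 <- complex_tone(230, low_cut = 1000, high_cut = 1600)
  expect_s3_class(t1, "complex_tone")
  expect_equal(t1$partials$frequency, t1$partials$rank * t1$f0)

  bad <- tibble::tibble(rank = c(1L, 2L), frequency = c(230, 500))
  expect_error(complex_tone(230, partials = bad),
               class = "pitchshift_invalid_parameter")
  expect_error(complex_tone(230, partials = tibble::tibble(rank = integer(),
                                                           frequency = numeric())),
               class = "pitchshift_empty_spectrum")
  expect_error(complex_tone(230, low_cut = 250, high_cut = 1600,
                            duration = 0.015, ramp = 0.01),
               class = "pitchshift_invalid_parameter")
  expect_equal(tidy(t1)$frequency, c(1150, 1380))
})

test_that("the eight tone pairs match the published design", {
  pairs <- experiment1_pairs()
  expect_equal(nrow(pairs), 8L)
  expect_equal(pairs$condition, paste0(rep(c("X", "Y"), each = 4), 1:4))
  expect_equal(pairs$low_cut, rep(c(250, 500, 750, 1000), 2))
  expect_equal(pairs$high_cut, rep(c(1600, 1300), each = 4))

  # designed crossover: tone A (lower F0) starts higher in every pair
  expect_true(all(pairs$lowest_a > pairs$lowest_b))

  # shared top frequency in X, tone A above tone B in Y
  expect_true(all(pairs$top_a[pairs$series == "X"] == 1380))
  expect_true(all(pairs$top_b[pairs$series == "X"] == 1380))
  expect_true(all(pairs$top_a[pairs$series == "Y"] == 1150))
  expect_true(all(pairs$top_b[pairs$series == "Y"] == 1104))

  # exactly one all-pure pair: Y4
  pure <- pairs$n_partials_a == 1 & pairs$n_partials_b == 1
  expect_equal(pairs$condition[pure], "Y4")
  y4 <- pairs[pairs$condition == "Y4", ]
  expect_equal(y4$tone_a[[1]]$partials,
               tibble::tibble(rank = 5L, frequency = 1150))
  expect_equal(y4$tone_b[[1]]$partials,
               tibble::tibble(rank = 4L, frequency = 1104))

  # X1 tone A keeps five partials, 460..1380
  x1a <- pairs$tone_a[[1]]$partials
  expect_equal(nrow(x1a), 5L)
  expect_equal(range(x1a$frequency), c(460, 1380))

  man <- stimulus_manifest(pairs)
  expect_equal(nrow(man), sum(pairs$n_partials_a) + sum(pairs$n_partials_b))
  expect_named(man, c("condition", "tone", "f0", "rank", "frequency",
                      "duration"))
})

test_that("synthesis produces ramped, normalised, spectrally clean tones", {
  tone <- complex_tone(230, low_cut = 250, high_cut = 1600)
  w <- synthesize_tone(tone)
  expect_length(w, 22050L)
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_lte(max(abs(w)), 1 - 2^-15)
  expect_gt(max(abs(w)), 0.9) # peak-normalised

  # stationary outside the ramps: envelope of the middle equals the peak
  nr <- round(tone$ramp * tone$sample_rate)
  mid <- w[(nr + 1):(length(w) - nr)]
  expect_gt(max(abs(mid)), 0.99 * max(abs(w)))

  # pure tone: single spectral peak at its frequency within one bin
  pure <- complex_tone(276, low_cut = 1000, high_cut = 1300)
  wp <- synthesize_tone(pure)
  spec <- waveform_spectrum(wp, 44100)
  peak <- spec$frequency[which.max(spec$magnitude)]
  expect_lt(abs(peak - 1104), 44100 / length(wp) + 1e-9)

  # retained partials present, eliminated harmonics >= 40 dB down
  seg <- structure(mid, sample_rate = tone$sample_rate)
  spec2 <- waveform_spectrum(seg)
  for (f in tone$partials$frequency) {
    expect_gt(relative_level_db(spec2, f), -6)
  }
  for (f in setdiff((1:8) * 230, tone$partials$frequency)) {
    expect_lt(relative_level_db(spec2, f), -40)
  }
})

test_that("WAV files round-trip through the 16-bit PCM format", {
  tone <- complex_tone(230, low_cut = 1000, high_cut = 1600)
  w <- synthesize_tone(tone)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)

  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100L)
  expect_equal(back$bit_depth, 16L)
  expect_equal(back$n_channels, 1L)
  expect_equal(back$n_frames, length(w))
  expect_lte(max(abs(back$samples - as.numeric(w))), 2 / 2^15)

  # declared sizes are exact: 44-byte header + 2 bytes per sample
  expect_equal(file.size(path), 44 + 2 * length(w))

  # diotic option duplicates the channel
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path2, stereo = TRUE)
  st <- read_wav(path2)
  expect_equal(st$n_channels, 2L)
  expect_equal(st$samples[, 1], st$samples[, 2])
  expect_equal(st$n_frames, length(w))

  expect_error(write_wav(numeric(0), path, sample_rate = 44100),
               class = "pitchshift_invalid_parameter")
  expect_error(write_wav(c(0, 1.5), path, sample_rate = 44100),
               class = "pitchshift_invalid_parameter")
})
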