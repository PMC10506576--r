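test_that("the passage has thirteen notes with the conventional rhythm", {
  p <- lightly_row_passage()
  expect_equal(nrow(p), 13L)
  expect_equal(p$degree,
               c("G", "E", "E", "F", "D", "D", "C", "D", "E", "F",
                 "G", "G", "G"))
  expect_equal(p$duration[c(3, 6, 13)], rep(1.0, 3))
  expect_equal(p$duration[-c(3, 6, 13)], rep(0.5, 10))
  expect_equal(sum(p$duration), 8.0)

  # scale anchoring: E and G carry the two tone-pair fundamentals,
  # a just minor third (~316 cents) apart
  expect_equal(p$f0[p$degree == "E"][1], 230)
  expect_equal(p$f0[p$degree == "G"][1], 276)
  expect_equal(round(cents_interval(230, 276)), 316)

  expect_error(lightly_row_passage(scale = c(C = 184)),
               class = "pitchshift_config_error")
})

test_that("eight versions band-limit every note like the tone-pair design", {
  v <- experiment2_versions()
  expect_equal(nrow(v), 8L)
  expect_equal(v$condition, paste0(rep(c("X", "Y"), each = 4), 1:4))
  expect_true(all(purrr::map_int(v$notes, nrow) == 13L))

  # per-note band limiting commutes with direct construction
  p <- lightly_row_passage()
  for (i in c(1L, 8L)) {
    direct <- purrr::map2(p$f0, p$duration, function(f0, dur) {
      complex_tone(f0, low_cut = v$low_cut[i], high_cut = v$high_cut[i],
                   duration = dur)$partials
    })
    via_version <- purrr::map(v$notes[[i]]$tone, ~ .x$partials)
    expect_equal(via_version, direct)
  }

  # pure tones appear in the severest narrow-band version
  expect_gte(sum(v$notes[[which(v$condition == "Y4")]]$n_partials == 1), 1L)

  # a scale outside the band aborts naming the note and version
  high_scale <- 4 * lightly_row_scale()
  expect_error(
    experiment2_versions(lightly_row_passage(scale = high_scale)),
    class = "pitchshift_construction_error"
  )
})

test_that("melody rendering concatenates notes without gaps", {
  v <- experiment2_versions()
  w <- render_melody(v$notes[[1]])
  expect_length(w, 352800L) # 8.0 s at 44.1 kHz
  expect_equal(attr(w, "sample_rate"), 44100)

  # degenerate single-note version equals direct synthesis
  one <- v$notes[[1]][1, ]
  expect_equal(as.numeric(render_melody(one)),
               as.numeric(synthesize_tone(one$tone[[1]])))

  # note order is preserved: each note window peaks at that note's partials
  sr <- 44100
  lens <- round(v$notes[[1]]$duration * sr)
  starts <- c(0, cumsum(lens))[seq_along(lens)]
  for (j in c(1L, 3L, 7L)) {
    tone <- v$notes[[1]]$tone[[j]]
    seg <- w[(starts[j] + 500):(starts[j] + lens[j] - 500)]
    spec <- waveform_spectrum(seg, sr)
    peak <- spec$frequency[which.max(spec$magnitude)]
    expect_lt(min(abs(tone$partials$frequency - peak)), 2 * sr / length(seg))
  }
})
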