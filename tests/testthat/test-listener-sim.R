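test_that("spectral probability follows the logistic condition model", {
  null_cfg <- sim_config(beta_lowcut = 0, beta_series = 0)
  expect_equal(spectral_probability(0, "X1", null_cfg), 0.5)
  expect_equal(spectral_probability(0, "Y3", null_cfg), 0.5)

  # extreme traits give near-pure F0 / spectral listeners
  expect_lt(spectral_probability(-30, "X4"), 1e-9)
  expect_gt(spectral_probability(30, "X1"), 1 - 1e-9)

  # positive beta_lowcut: probability strictly increasing in low-cut index
  cfg <- sim_config(beta_lowcut = 0.7, beta_series = 0.4)
  for (series in c("X", "Y")) {
    p <- spectral_probability(0.3, paste0(series, 1:4), cfg)
    expect_true(all(diff(p) > 0))
  }
  # positive beta_series lifts Y above matched X at any trait
  expect_true(all(
    spectral_probability(-1, paste0("Y", 1:4), cfg) >
      spectral_probability(-1, paste0("X", 1:4), cfg)
  ))

  expect_error(spectral_probability(0, "Z1"),
               class = "pitchshift_invalid_parameter")
})

test_that("cohort simulation honours the design and the seed", {
  sim <- simulate_cohort(sim_config(), experiment = 1, seed = 11)
  expect_equal(nrow(sim), 39L * 16L) # 16 tasks per participant
  expect_equal(dplyr::n_distinct(sim$participant_id), 39L)
  expect_equal(unique(table(sim$participant_id)), 16L)
  counts <- dplyr::count(sim, condition, repetition)
  expect_equal(nrow(counts), 16L)
  expect_true(all(counts$n == 39L))
  expect_equal(sum(sim$age_group == "young"), 19L * 16L)

  # determinism: same seed, identical table
  expect_identical(sim, simulate_cohort(sim_config(), experiment = 1, seed = 11))
  sim2 <- simulate_cohort(sim_config(), experiment = 1, seed = 12)
  expect_false(identical(sim$response, sim2$response))

  # degenerate all-spectral cohort pushes every SI to +1 downstream
  forced <- sim_config(mu_trait = 60, sd_trait = 0)
  all_sp <- simulate_cohort(forced, seed = 1)
  expect_true(all(all_sp$response == "spectral"))
  expect_true(all(score_responses(all_sp)$si == 1))

  expect_equal(nrow(simulate_cohort(sim_config(n_young = 0, n_old = 0),
                                    seed = 1)), 0L)
})

test_that("response tables round-trip through CSV", {
  sim <- simulate_cohort(sim_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_responses(sim, path)
  expect_equal(length(readLines(path)), nrow(sim) + 1L)
  back <- import_responses(path)
  expect_equal(as.data.frame(back), as.data.frame(sim))

  empty <- simulate_cohort(sim_config(n_young = 0, n_old = 0), seed = 1)
  export_responses(empty, path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("age groups are exchangeable under the default configuration", {
  cfg <- sim_config(n_young = 300, n_old = 300)
  sc <- score_responses(simulate_cohort(cfg, seed = 5))
  by_age <- cohort_summary(sc, by = "age_group")
  wide <- tidyr::pivot_wider(by_age[, c("age_group", "condition", "mean_si")],
                             names_from = "age_group",
                             values_from = "mean_si")
  # no age term in the model: group means differ only by sampling noise
  expect_lt(max(abs(wide$young - wide$old)), 0.25)
})

test_that("marginal ML recovers the generating parameters", {
  cfg <- sim_config(n_young = 200, n_old = 200, seed = 202)
  sim <- simulate_cohort(cfg, repetitions = 6)
  fit <- fit_listener_model(sim)
  expect_true(glance(fit)$converged)
  td <- tidy(fit)
  truth <- c(mu_trait = cfg$mu_trait, sd_trait = cfg$sd_trait,
             beta_lowcut = cfg$beta_lowcut, beta_series = cfg$beta_series)
  for (term in names(truth)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std.error)
  }
  # informative data: slope standard errors are tight
  expect_lt(td$std.error[td$term == "beta_lowcut"], 0.1)
})
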