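test_that("model-building preset reproduces the trial observation counts", {
  d <- simulate_dataset("model_building", seed = 123)
  obs <- d[d$EVID == 0, ]
  expect_equal(nrow(obs), 648)
  expect_equal(sum(obs$DAY == -1), 336)   # 24 x 14 baseline samples
  expect_equal(sum(obs$DAY == 1), 312)    # 24 x 13 post-dose samples
  expect_equal(length(unique(d$ID)), 24)
  expect_equal(sum(d$EVID == 1), 24)      # one dose record per subject
  expect_equal(sort(unique(d$AMT[d$EVID == 1])), c(10, 20, 30))
  # baseline schedule: 14 points ending at 24 h
  bt <- sort(unique(d$TIME[d$EVID == 0 & d$DAY == -1]))
  expect_equal(length(bt), 14)
  expect_equal(max(bt), 24)
  expect_equal(bt[1:5], c(0, 10, 20, 30, 45) / 60)
})

test_that("validation preset has single-dose and BID phases", {
  d <- simulate_dataset("validation", seed = 9)
  expect_equal(length(unique(d$ID)), 7)
  expect_equal(sum(d$EVID == 0 & d$DAY == -1), 7 * 14)
  expect_equal(sum(d$EVID == 0 & d$DAY == 1), 7 * 13)
  expect_equal(sum(d$EVID == 1), 7 * 15)  # single + 14 BID doses
  expect_true(all(d$AMT[d$EVID == 1] == 15))
})

test_that("unknown presets are rejected with the preset list", {
  expect_error(build_scenario("no_such_trial"), "model_building")
})

test_that("deterministic scenario collapses to the endogenous constant", {
  sc <- scenario(n_subjects = 3, dose = 0, regimen_kind = "single",
                 residual_error = FALSE, weights = 70)
  d <- simulate_dataset(sc, omega = omega_matrix(), seed = 1)
  expect_equal(unique(d$DV[d$EVID == 0]), 12.53, tolerance = 1e-3)
})

test_that("datasets are byte-identical under the same seed", {
  d1 <- simulate_dataset("model_building", seed = 77)
  d2 <- simulate_dataset("model_building", seed = 77)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_dataset("model_building", seed = 78)
  expect_false(identical(d1$DV, d3$DV))
})

test_that("simulated concentrations sit above the assay quantification limit", {
  # the trial reported no observation below 4 ug/mL. Under the log-normal
  # IIV + Gaussian proportional-error generator the sub-LLOQ rate is not
  # exactly zero (the normal noise tail is heavier than real assay data):
  # well under 0.3% of observations fall below 4 ug/mL
  tot <- 0L; low <- 0L
  for (s in 1:20) {
    d <- simulate_dataset("model_building", seed = 1000 + s)
    dv <- d$DV[d$EVID == 0]
    tot <- tot + length(dv)
    low <- low + sum(dv <= 4)
  }
  expect_lt(low / tot, 0.003)
})

test_that("vpc percentiles match the order-statistics oracle", {
  set.seed(8)
  mat <- matrix(runif(1e5 * 3), nrow = 1e5)
  bands <- vpc_percentiles(mat, probs = c(0.05, 0.5, 0.95), times = c(1, 2, 3))
  expect_equal(unname(unlist(bands[1, c("p5", "p50", "p95")])),
               c(0.05, 0.5, 0.95), tolerance = 0.01)
  # identical replicates collapse onto the profile, bands monotone
  prof <- tibble::tibble(time = c(1, 2), conc = c(5, 9))
  b2 <- vpc_percentiles(list(prof, prof, prof))
  expect_equal(b2$p5, c(5, 9))
  expect_equal(b2$p95, c(5, 9))
  expect_true(all(bands$p5 <= bands$p50 & bands$p50 <= bands$p95))
  # mismatched grids are an error
  expect_error(vpc_percentiles(list(prof, tibble::tibble(time = c(1, 3),
                                                         conc = c(5, 9)))),
               "grids")
})
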