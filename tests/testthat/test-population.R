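test_that("zero omega reproduces the population values exactly", {
  p <- ast001_params()
  ind <- sample_individuals(p, omega_matrix(), 5, seed = 1)
  expect_equal(ind$V1F, rep(p$V1F, 5))
  expect_equal(ind$CLF, rep(p$CLF, 5))
  expect_equal(ind$D1, rep(p$D1, 5))
  expect_equal(ind$R1, rep(p$R1, 5))
  expect_true(all(ind$eta_V1F == 0))
})

test_that("sampled eta moments reproduce the omega matrix", {
  p <- ast001_params()
  om <- ast001_omega()
  ind <- sample_individuals(p, om, 1e5, seed = 2)
  lv <- log(ind$V1F); lc <- log(ind$CLF)
  # empirical covariance of (log V1, log CL) and SD of log CL
  expect_equal(stats::cov(lv, lc), 0.0483, tolerance = 0.02)
  expect_equal(stats::sd(lc), 0.222, tolerance = 0.01)
  expect_equal(stats::sd(log(ind$D1)), 0.38, tolerance = 0.01)
  # implied correlation ~ 0.0483 / (0.290 * 0.222) = 0.75
  expect_equal(stats::cor(lv, lc), 0.0483 / (0.290 * 0.222), tolerance = 0.02)
  # log-normal median converges to the population value
  expect_equal(stats::median(ind$CLF), p$CLF, tolerance = 0.01)
  # V2F and QF carry no variability
  expect_equal(stats::sd(ind$V2F), 0)
})

test_that("lognormal CV transform is available as an alternative", {
  om <- omega_matrix(cv_cl = 22.2, cv_as = "lognormal")
  expect_equal(om["CLF", "CLF"], log(1 + 0.222^2), tolerance = 1e-12)
})

test_that("non-PSD omega is rejected with an informative error", {
  expect_error(omega_matrix(cv_v1 = 10, cv_cl = 10, cov_v1_cl = 0.5),
               "positive semidefinite")
  bad <- diag(c(0.01, 0.01, 0, 0))
  bad[1, 2] <- bad[2, 1] <- 0.5
  expect_error(sample_individuals(ast001_params(), bad, 2),
               "positive semidefinite")
})

test_that("proportional residual error has the stated magnitude and floor", {
  prof <- tibble::tibble(time = seq_len(1e5), conc = rep(50, 1e5))
  noisy <- apply_residual_error(prof, 0.183, seed = 3)
  expect_equal(stats::sd(noisy$conc / 50 - 1), 0.183, tolerance = 0.01)
  # sigma 0 is the identity
  same <- apply_residual_error(prof, 0, seed = 3)
  expect_equal(same$conc, prof$conc)
  expect_equal(attr(same, "n_floored"), 0L)
  # zero prediction stays zero
  z <- apply_residual_error(tibble::tibble(time = 1:5, conc = rep(0, 5)),
                            0.183, seed = 4)
  expect_equal(z$conc, rep(0, 5))
  # heavy noise on a small concentration gets floored and counted
  fl <- apply_residual_error(tibble::tibble(time = 1:1000, conc = rep(1, 1000)),
                             1.5, seed = 5)
  expect_true(all(fl$conc >= 0))
  expect_gt(attr(fl, "n_floored"), 0)
})

test_that("allometric scaling follows the fixed 0.75/1 exponents", {
  p <- ast001_params()
  expect_equal(allometric_scale(p, 70), p)            # identity at reference
  half <- allometric_scale(p, 35)
  expect_equal(half$CLF, 22.9 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(half$CLF, 13.62, tolerance = 1e-3)
  expect_equal(half$QF, 16.4 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(half$V1F, 34.2, tolerance = 1e-12)
  expect_equal(half$V2F, 98, tolerance = 1e-12)
  expect_equal(half$D1, p$D1)                         # unscaled
  expect_equal(half$R1, p$R1)                         # unscaled by default
  expect_equal(allometric_scale(p, 17.5)$CLF, 8.10, tolerance = 1e-2)
  expect_error(allometric_scale(p, -5), "positive")
  # scaling composes multiplicatively
  q <- allometric_scale(allometric_scale(p, 35), 70,
                        rule = scaling_rule(reference_weight = 35))
  expect_equal(q$CLF, p$CLF * 0.5^0.75 * 2^0.75, tolerance = 1e-12)
})

test_that("adult weights respect the truncation bounds and centre", {
  set.seed(6)
  w <- sample_adult_weights(2e4)
  expect_true(all(w >= 54.5 & w <= 86.9))
  expect_equal(stats::median(w), 72.5, tolerance = 0.01)
})
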