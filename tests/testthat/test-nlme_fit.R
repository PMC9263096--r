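test_that("objective equals the closed form when omega is zero", {
  d <- simulate_dataset("model_building", seed = 123)
  p <- ast001_params()
  r <- foce_objective(d, p, omega_matrix(), 0.183)
  closed <- 0
  for (s in serinepk:::dataset_subjects(d)) {
    f <- serinepk:::predict_conc_cpp(s$times, s$amt, s$dstart,
                                     c(p$V1F, p$CLF, p$V2F, p$QF, p$D1, p$R1),
                                     TRUE)
    closed <- closed - 2 * sum(stats::dnorm(s$y, f, 0.183 * f, log = TRUE))
  }
  expect_equal(r$ofv, closed, tolerance = 1e-12)
  expect_true(all(r$eta == 0))
})

test_that("objective tracks adaptive Gauss-Hermite quadrature", {
  p <- ast001_params()
  sig <- 0.183
  set.seed(4)
  # subject with dosing data and one random effect on CL
  om_cl <- omega_matrix(cv_cl = 22.2)
  ind <- sample_individuals(p, om_cl, 1)
  tt <- c(0.5, 1, 2, 6, 12)
  pind <- serinepk:::individual_params(ind, 1)
  f_true <- serinepk:::predict_conc_cpp(
    tt, 10, 0, c(pind$V1F, pind$CLF, pind$V2F, pind$QF, pind$D1, pind$R1), TRUE)
  y <- f_true * (1 + stats::rnorm(5, 0, sig))
  d <- one_subject_dataset(tt, y, amt = 10, dstart = 0)
  for (mult in c(0.8, 0.9, 1, 1.1, 1.25)) {
    pp <- p; pp$CLF <- p$CLF * mult
    exact <- agq_m2ll_1d(y, function(eta) {
      serinepk:::predict_conc_cpp(
        tt, 10, 0, c(pp$V1F, pp$CLF * exp(eta), pp$V2F, pp$QF, pp$D1, pp$R1),
        TRUE)
    }, omega2 = 0.222^2, sigma = sig)
    foce <- foce_objective(d, pp, om_cl, sig)$ofv
    expect_lt(abs(foce - exact), 0.5)
  }
  # baseline-only subject with a random effect on R1
  om_r1 <- omega_matrix(cv_r1 = 18)
  yb <- 12.53 * exp(0.1) * (1 + stats::rnorm(8, 0, sig))
  db <- one_subject_dataset(seq(0, 21, by = 3), yb)
  exact <- agq_m2ll_1d(yb, function(eta) {
    rep(1000 * p$R1 * exp(eta) / p$CLF, 8)
  }, omega2 = 0.18^2, sigma = sig)
  foce <- foce_objective(db, p, om_r1, sig)$ofv
  expect_lt(abs(foce - exact), 0.5)
})

test_that("near-noiseless rich data recovers the fixed effects within 2%", {
  sc <- scenario(n_subjects = 6, dose = rep(c(10, 20, 30), 2),
                 regimen_kind = "single", residual_error = TRUE, weights = 70)
  d <- simulate_dataset(sc, omega = omega_matrix(), sigma_prop = 0.01,
                        seed = 21)
  init <- list(p = pk_params(V1F = 80, CLF = 19, V2F = 160, QF = 20,
                             D1 = 1.6, R1 = 0.35),
               omega = omega_matrix(), sigma = 0.02)
  fit <- fit_model(d, init = init, fixed = "omega")
  truth <- ast001_params()
  for (nm in c("V1F", "CLF", "V2F", "QF", "D1", "R1")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 0.02)
  }
  expect_equal(fit$sigma, 0.01, tolerance = 0.25)
})

test_that("refitting from a converged solution leaves the OFV unchanged", {
  sc <- scenario(n_subjects = 6, dose = rep(c(10, 20, 30), 2),
                 regimen_kind = "single", residual_error = TRUE, weights = 70)
  d <- simulate_dataset(sc, omega = omega_matrix(), sigma_prop = 0.01,
                        seed = 21)
  init <- list(p = pk_params(V1F = 80, CLF = 19, V2F = 160, QF = 20,
                             D1 = 1.6, R1 = 0.35),
               omega = omega_matrix(), sigma = 0.02)
  fit1 <- fit_model(d, init = init, fixed = "omega")
  fit2 <- fit_model(d, init = list(p = fit1$params, omega = fit1$omega,
                                   sigma = fit1$sigma), fixed = "omega")
  expect_lt(abs(fit2$ofv - fit1$ofv), 0.01)
})

test_that("likelihood-ratio thresholds follow the chi-square quantiles", {
  expect_equal(stats::qchisq(0.95, 1), 3.841, tolerance = 1e-3)
  expect_false(lrt_compare(100, 100, df = 1)$significant)
  expect_true(lrt_compare(103.85, 100, df = 1, direction = "forward")$significant)
  expect_false(lrt_compare(103.5, 100, df = 1, direction = "forward")$significant)
  # backward elimination needs > 6.63
  expect_false(lrt_compare(106, 100, df = 1, direction = "backward")$significant)
  expect_true(lrt_compare(106.7, 100, df = 1, direction = "backward")$significant)
  expect_equal(lrt_compare(110, 100, df = 1)$delta_ofv, 10)
  # optimizer-failure signal
  expect_warning(lrt_compare(100, 105, df = 1), "higher OFV")
})

test_that("eta shrinkage formula behaves at its anchors", {
  om <- ast001_omega()
  set.seed(30)
  eta <- sapply(sqrt(diag(om)), function(w) stats::rnorm(4000, 0, w))
  colnames(eta) <- serinepk:::eta_names()
  sh <- eta_shrinkage(eta, om)
  expect_true(all(abs(sh) < 5))          # ~0% at large n
  sh0 <- eta_shrinkage(matrix(0, 10, 4, dimnames = list(NULL, colnames(eta))), om)
  expect_equal(unname(sh0), rep(100, 4))
  # undefined for a zero-variance effect
  shna <- eta_shrinkage(eta, omega_matrix(cv_cl = 22.2))
  expect_true(is.na(shna["V1F"]))
  expect_false(is.na(shna["CLF"]))
})

test_that("bootstrap resampling is seed-reproducible and well-formed", {
  sc <- scenario(n_subjects = 6, dose = rep(c(10, 20, 30), 2),
                 regimen_kind = "single", residual_error = TRUE, weights = 70)
  d <- simulate_dataset(sc, omega = omega_matrix(), sigma_prop = 0.01,
                        seed = 21)
  init <- list(p = ast001_params(), omega = omega_matrix(), sigma = 0.01)
  fit <- fit_model(d, init = init, fixed = "omega")
  b1 <- suppressWarnings(bootstrap_fit(d, fit, n_boot = 3, seed = 11,
                                       control = list(nm_maxit = 200)))
  b2 <- suppressWarnings(bootstrap_fit(d, fit, n_boot = 3, seed = 11,
                                       control = list(nm_maxit = 200)))
  expect_identical(b1$indices, b2$indices)
  expect_identical(b1$estimates, b2$estimates)
  s <- b1$summary
  expect_true(all(s$ci_lower <= s$median & s$median <= s$ci_upper,
                  na.rm = TRUE))
})

test_that("weight-covariate power model is estimable and LRT-testable", {
  # adults with diverse weights but no true weight effect in the generator:
  # the estimated exponents should sit near zero and the LRT should not
  # reach the forward-inclusion threshold
  sc <- scenario(n_subjects = 8, dose = 15, regimen_kind = "single",
                 residual_error = TRUE,
                 weights = c(50, 55, 60, 65, 75, 85, 95, 100))
  d <- simulate_dataset(sc, omega = omega_matrix(), sigma_prop = 0.05,
                        seed = 31)
  init <- list(p = ast001_params(), omega = omega_matrix(), sigma = 0.05)
  f0 <- fit_model(d, init = init, fixed = "omega")
  f1 <- fit_model(d, init = init, fixed = "omega", covariate = "power_weight")
  expect_length(f1$cov_exponents, 2)
  expect_lt(max(abs(f1$cov_exponents)), 0.5)
  expect_lte(f1$ofv, f0$ofv + 1e-6)      # nested: full can only improve
  lrt <- lrt_compare(f0, f1, df = 2)
  expect_false(lrt$significant)
  expect_equal(lrt$critical, stats::qchisq(0.95, 2), tolerance = 1e-12)
})
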