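test_that("micro constants match the quadratic-root and eigenvalue oracles", {
  p <- ast001_params()
  mc <- micro_constants(p)
  expect_equal(mc$k10, 22.9 / 68.4, tolerance = 1e-12)
  expect_equal(mc$k10, 0.3348, tolerance = 1e-3)
  # alpha/beta are roots of s^2 - (k10+k12+k21)s + k10*k21
  expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-12)
  expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21, tolerance = 1e-12)
  expect_gt(mc$alpha, mc$beta)
  # eigenvalues of the 2x2 disposition rate matrix
  A <- matrix(c(-(mc$k10 + mc$k12), mc$k21, mc$k12, -mc$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A, only.values = TRUE)$values)
  expect_equal(ev, c(mc$beta, mc$alpha), tolerance = 1e-12)
  # terminal half-life from the quadratic root
  expect_equal(log(2) / mc$beta, 15.15, tolerance = 1e-2)
})

test_that("QF = 0 degenerates to a decoupled one-compartment system", {
  p <- pk_params(V1F = 50, CLF = 10, V2F = 100, QF = 0, D1 = 1, R1 = 0.2)
  mc <- micro_constants(p)
  expect_equal(mc$k12, 0)
  expect_equal(mc$k21, 0)
  expect_equal(mc$alpha, 10 / 50)
  expect_equal(mc$beta, 0)
  # prediction agrees with the ODE reference in the one-compartment limit
  reg <- regimen(10, 0, 1)
  tt <- c(0.5, 1, 2, 6, 12)
  expect_equal(predict_conc(p, reg, tt)$conc,
               ode_reference(p, reg, tt)$conc, tolerance = 1e-8)
})

test_that("invalid parameters are rejected", {
  expect_error(pk_params(V1F = -1, CLF = 22.9, V2F = 196, QF = 16.4,
                         D1 = 1.26, R1 = 0.287), "positive")
  expect_error(pk_params(V1F = Inf, CLF = 22.9, V2F = 196, QF = 16.4,
                         D1 = 1.26, R1 = 0.287), "finite")
  expect_error(predict_conc(ast001_params(), regimen(), c(-1, 0)), "negative")
})

test_that("endogenous-only prediction is the constant R1/CLF", {
  p <- ast001_params()
  prof <- predict_conc(p, regimen(), c(0, 1, 7.3, 24, 100))
  expect_equal(prof$conc, rep(1000 * 0.287 / 22.9, 5), tolerance = 1e-12)
  expect_equal(prof$conc[1], 12.53, tolerance = 1e-3)
  # no production, no drug
  p0 <- pk_params(V1F = 68.4, CLF = 22.9, V2F = 196, QF = 16.4,
                  D1 = 1.26, R1 = 0)
  expect_equal(predict_conc(p0, regimen(), c(0, 5))$conc, c(0, 0))
})

test_that("ODE reference reproduces the endogenous steady state from any start", {
  # wash-in: integrating the mass balance from a zero state converges to
  # R1/CLF within ~10 terminal half-lives
  p <- ast001_params()
  mc <- micro_constants(p)
  t10 <- 10 * log(2) / mc$beta
  deriv <- function(t, A, parms) {
    list(c(p$R1 - (mc$k10 + mc$k12) * A[1] + mc$k21 * A[2],
           mc$k12 * A[1] - mc$k21 * A[2]))
  }
  out <- deSolve::lsoda(c(0, 0), c(0, t10), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(1000 * out[2, 2] / p$V1F), 1000 * p$R1 / p$CLF, tolerance = 1e-2)
})

test_that("closed form matches the ODE oracle on a single dose", {
  p <- ast001_params()
  reg <- regimen(10, 0, 1.26)
  tt <- c(0.1, 0.5, 1, 1.26, 1.5, 2, 3, 4, 6, 9, 12, 24, 48)
  a <- predict_conc(p, reg, tt, include_endogenous = FALSE)
  b <- ode_reference(p, reg, tt, include_endogenous = FALSE)
  expect_equal(a$conc, b$conc, tolerance = 1e-8)
})

test_that("superposition and dose proportionality hold exactly", {
  p <- ast001_params()
  tt <- seq(0.5, 36, by = 0.5)
  r1 <- regimen(10, 0, 1.26)
  r2 <- regimen(20, 12, 2)
  r12 <- regimen(c(10, 20), c(0, 12), c(1.26, 2))
  c1 <- predict_conc(p, r1, tt, include_endogenous = FALSE)$conc
  c2 <- predict_conc(p, r2, tt, include_endogenous = FALSE)$conc
  c12 <- predict_conc(p, r12, tt, include_endogenous = TRUE)$conc
  endo <- 1000 * p$R1 / p$CLF
  expect_equal(c12, c1 + c2 + endo, tolerance = 1e-12)
  # linear in amount
  c5x <- predict_conc(p, regimen(50, 0, 1.26), tt,
                      include_endogenous = FALSE)$conc
  expect_equal(c5x, 5 * c1, tolerance = 1e-12)
})

test_that("7-day BID dosing reaches steady state (intervals 13 vs 14)", {
  p <- ast001_params()
  reg <- regimen_repeated(15, n_doses = 14, tau = 12, duration = 1.26)
  tt <- seq(0, 12, by = 0.25)
  c13 <- predict_conc(p, reg, 144 + tt, include_endogenous = FALSE)$conc
  c14 <- predict_conc(p, reg, 156 + tt, include_endogenous = FALSE)$conc
  expect_lt(max(abs(c14 - c13) / c13), 0.005)
})

test_that("exogenous steady-state AUC over one interval equals dose/CLF", {
  p <- ast001_params()
  reg <- regimen_repeated(15, n_doses = 200, tau = 12, duration = 1.26)
  tt <- 12 * 199 + seq(0, 12, by = 0.01)
  prof <- predict_conc(p, reg, tt, include_endogenous = FALSE)
  auc <- serinepk:::auc_trapezoid(prof$time, prof$conc, tt[1], tt[length(tt)])
  expect_equal(auc, auc_tau_analytic(15, 22.9), tolerance = 2e-4)
})

test_that("R and C++ predictions agree", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    k <- sample(1:3, 1)
    # the compiled path uses D1 as the input duration for every event
    reg <- regimen(amount = runif(k, 1, 30), start = sort(runif(k, 0, 24)),
                   duration = p$D1)
    tt <- sort(runif(15, 0, 48))
    a <- predict_conc(p, reg, tt, include_endogenous = TRUE)$conc
    b <- serinepk:::predict_conc_cpp(tt, reg$amount, reg$start,
                                     c(p$V1F, p$CLF, p$V2F, p$QF, p$D1, p$R1),
                                     TRUE)
    expect_equal(a, as.numeric(b), tolerance = 1e-12)
  }
})
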