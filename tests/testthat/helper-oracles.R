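# Independent oracles used across the suite.

# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact -2 log marginal likelihood for one subject with a single random
# effect, by adaptive Gauss-Hermite quadrature centered at the conditional
# mode. pred_fn(eta) returns the prediction vector for the subject.
agq_m2ll_1d <- function(y, pred_fn, omega2, sigma, n_nodes = 64) {
  loglik <- function(eta) {
    f <- pred_fn(eta)
    sum(stats::dnorm(y, f, sigma * f, log = TRUE))
  }
  nl <- function(eta) -loglik(eta) + eta^2 / (2 * omega2)
  o <- stats::optimize(nl, c(-4, 4), tol = 1e-12)
  m <- o$minimum
  h <- (nl(m + 1e-4) - 2 * nl(m) + nl(m - 1e-4)) / 1e-8
  s <- 1 / sqrt(max(h, 1e-8))
  q <- gauss_hermite(n_nodes)
  lt <- vapply(seq_along(q$x), function(k) {
    eta <- m + sqrt(2) * s * q$x[k]
    log(q$w[k]) + q$x[k]^2 + loglik(eta) +
      stats::dnorm(eta, 0, sqrt(omega2), log = TRUE)
  }, numeric(1))
  M <- max(lt)
  -2 * (M + log(sum(exp(lt - M))) + log(sqrt(2) * s))
}

# Random two-compartment parameter set with physiologic ranges.
random_params <- function() {
  pk_params(V1F = runif(1, 20, 150), CLF = runif(1, 5, 60),
            V2F = runif(1, 50, 400), QF = runif(1, 2, 40),
            D1 = runif(1, 0.3, 3), R1 = runif(1, 0.05, 0.6))
}

# Random regimen of 0-3 zero-order dose events within 0-24 h.
random_regimen <- function() {
  k <- sample(0:3, 1)
  if (k == 0) return(regimen())
  regimen(amount = runif(k, 1, 30), start = sort(runif(k, 0, 24)),
          duration = runif(k, 0.5, 3))
}

# Analytic exogenous steady-state AUC over one dosing interval: dose/CL,
# in h*ug/mL.
auc_tau_analytic <- function(dose, clf) 1000 * dose / clf

# pk_dataset from raw vectors (single subject) for small fit fixtures.
one_subject_dataset <- function(times, y, amt = numeric(), dstart = numeric(),
                                dur = 1.26) {
  obs <- tibble::tibble(ID = 1, TIME = times, AMT = 0, DUR = 0, EVID = 0L,
                        MDV = 0L, DV = y, WT = 70, DAY = 1L)
  if (length(amt)) {
    dose <- tibble::tibble(ID = 1, TIME = dstart, AMT = amt, DUR = dur,
                           EVID = 1L, MDV = 1L, DV = NA_real_, WT = 70,
                           DAY = 1L)
    obs <- rbind(obs, dose)
    obs <- obs[order(obs$TIME, obs$EVID), ]
  }
  class(obs) <- c("pk_dataset", class(obs))
  obs
}
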