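# Split a pk_dataset into per-subject observation/dose lists for the
# compiled objective. The zero-order input duration used in fitting is the
# model parameter D1 (per-subject via eta), not the dataset DUR column,
# which records the generating value.
dataset_subjects <- function(data) {
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    d <- data[data$ID == id, ]
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    dos <- d[d$EVID == 1, ]
    if (nrow(obs) < 1) stop("subject ", id, " has no observations")
    list(id = id, times = obs$TIME, y = obs$DV,
         amt = dos$AMT, dstart = dos$TIME,
         wt = if (length(d$WT)) d$WT[1] else NA_real_)
  })
}

#' FOCE-with-interaction objective function
#'
#' For each subject, finds the conditional mode of the log-scale random
#' effects by Newton minimization of the exact joint -2 log density (with
#' the proportional-error variance evaluated at the conditional prediction,
#' i.e. the interaction term), then returns the first-order-linearized -2
#' log marginal likelihood summed over subjects. The `n log(2 pi)` constant
#' is included, so values are directly comparable to exact quadrature of
#' the marginal likelihood; likelihood-ratio differences are unaffected.
#' With `omega = 0` the objective is the exact closed-form
#' `-2 sum log N(DV; pred, (sigma * pred)^2)`.
#'
#' Deterministic given data and parameters.
#'
#' @param data a `pk_dataset` (from [simulate_dataset] or [read_pk_dataset])
#' @param p population parameters ([pk_params])
#' @param omega 4x4 IIV covariance matrix
#' @param sigma_prop proportional residual error CV (> 0)
#' @param weights per-subject likelihood weights (bootstrap multiplicities)
#' @param eta_start warm-start matrix of eta modes (subjects x 4)
#' @param cov_exp optional length-2 power-of-weight exponents on CL/F and
#'   V1/F (the covariate model tested by likelihood ratio)
#' @param multistart solve each conditional mode from both the zero and the
#'   warm start (default; keeps mode selection stable for gradient-based
#'   outer optimization) or from the warm start alone (cheaper, used for
#'   simplex-only bootstrap refits)
#' @return list with `ofv`, per-subject `ofv_i`, `eta` mode matrix
#'   (subjects x 4, named columns), `n_fail`
#' @export
foce_objective <- function(data, p, omega, sigma_prop, weights = NULL,
                           eta_start = NULL, cov_exp = NULL,
                           multistart = TRUE) {
  stopifnot(inherits(p, "pk_params"), sigma_prop > 0)
  subs <- if (inherits(data, "pk_subjects")) data else dataset_subjects(data)
  n <- length(subs)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(eta_start)) eta_start <- matrix(0, n, 4)
  theta <- c(p$V1F, p$CLF, p$V2F, p$QF, p$D1, p$R1)
  if (!is.null(cov_exp)) theta <- c(theta, cov_exp)
  ptr <- attr(subs, "cpp_ptr")
  res <- if (!is.null(ptr)) {
    foce_ofv_ptr(ptr, theta, omega, sigma_prop, weights, eta_start, multistart)
  } else {
    foce_ofv_cpp(subs, theta, omega, sigma_prop, weights, eta_start, multistart)
  }
  if (res$n_fail > 0)
    warning("foce_objective: inner optimization flagged ", res$n_fail,
            " subject(s)")
  colnames(res$eta) <- eta_names()
  res
}

# -- outer parameter packing ------------------------------------------------
# theta: log of the six fixed effects
# omega: log-Cholesky of the (V1, CL) block (logL11, L21, logL22) when the
#        covariance structure is on, plus log sd for D1 and R1
# sigma: log
pack_params <- function(p, omega, sigma, cov_block = TRUE, cov_exp = NULL) {
  th <- log(c(p$V1F, p$CLF, p$V2F, p$QF, p$D1, p$R1))
  sd4 <- sqrt(diag(omega))
  if (cov_block) {
    blk <- omega[1:2, 1:2]
    L <- t(chol(blk + diag(1e-12, 2)))
    om <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  } else {
    om <- log(sd4[1:2])
  }
  c(th, cov_exp, om, log(sd4[3]), log(sd4[4]), log(sigma))
}

unpack_params <- function(x, cov_block = TRUE, covariate = FALSE) {
  x <- unname(x)
  p <- pk_params(V1F = exp(x[1]), CLF = exp(x[2]), V2F = exp(x[3]),
                 QF = exp(x[4]), D1 = exp(x[5]), R1 = exp(x[6]))
  cov_exp <- NULL
  j <- 6
  if (covariate) { cov_exp <- x[7:8]; j <- 8 }
  om <- matrix(0, 4, 4, dimnames = list(eta_names(), eta_names()))
  if (cov_block) {
    L <- matrix(c(exp(x[j + 1]), x[j + 2], 0, exp(x[j + 3])), 2, 2,
                byrow = TRUE)
    om[1:2, 1:2] <- L %*% t(L)
    k <- j + 3
  } else {
    om[1, 1] <- exp(x[j + 1])^2; om[2, 2] <- exp(x[j + 2])^2
    k <- j + 2
  }
  om[3, 3] <- exp(x[k + 1])^2
  om[4, 4] <- exp(x[k + 2])^2
  list(p = p, omega = om, sigma = exp(x[k + 3]), cov_exp = cov_exp)
}

#' Fit the population model by FOCE with interaction
#'
#' Minimizes [foce_objective] over the unfixed fixed effects, the omega
#' entries (log-Cholesky parameterized, so positive semidefiniteness is
#' enforced) and the proportional error. Positive parameters are
#' log-transformed. The outer search is a restarted Nelder-Mead simplex --
#' robust to the small kinks that conditional-mode selection leaves in the
#' objective -- followed by a quasi-Newton polish with explicit
#' central-difference gradients; eta modes are warm-started across
#' objective evaluations. Reproducible given data and initial values; no
#' randomness enters the objective.
#'
#' @param data a `pk_dataset`
#' @param init list with `p` ([pk_params]), `omega`, `sigma` initial values
#' @param fixed names of fixed (not estimated) components among
#'   `"V1F","CLF","V2F","QF","D1","R1","omega","sigma"`
#' @param cov_block estimate the V1-CL covariance (on, matching the final
#'   model structure)?
#' @param covariate `"none"` (final-model structure) or `"power_weight"`:
#'   adds estimated power-of-weight exponents on CL/F and V1/F (referenced
#'   to 70 kg) for likelihood-ratio testing of the weight covariate
#' @param compute_se compute relative standard errors of the fixed effects
#'   and sigma from the numerical Hessian (slower)?
#' @param control list overriding the outer-search settings: `nm_maxit`
#'   and `nm_restarts` (restarted Nelder-Mead rounds), `nm_tol` (restart
#'   stopping improvement, OFV units), `rel.tol`/`iter.max` (gradient
#'   polish)
#' @return a `pk_fit` list: `params`, `omega`, `sigma`, `ofv`, `eta`
#'   (per-subject conditional modes), `convergence` flag, `rse` (named, %)
#'   when computed, optimizer bookkeeping
#' @export
fit_model <- function(data, init = list(p = ast001_params(),
                                        omega = ast001_omega(),
                                        sigma = ast001_sigma()),
                      fixed = character(), cov_block = TRUE,
                      covariate = c("none", "power_weight"),
                      compute_se = FALSE, control = list()) {
  covariate <- match.arg(covariate)
  has_cov <- covariate == "power_weight"
  subs <- dataset_subjects(data)
  class(subs) <- "pk_subjects"
  attr(subs, "cpp_ptr") <- foce_data_ptr(unclass(subs))
  n <- length(subs)
  x0 <- pack_params(init$p, init$omega, init$sigma, cov_block,
                    cov_exp = if (has_cov) c(0, 0) else NULL)
  npar <- length(x0)
  fe_names <- c("V1F", "CLF", "V2F", "QF", "D1", "R1")
  free <- rep(TRUE, npar)
  free[match(intersect(fixed, fe_names), fe_names)] <- FALSE
  om_idx <- (7 + 2 * has_cov):(npar - 1)
  if ("omega" %in% fixed) free[om_idx] <- FALSE
  if ("sigma" %in% fixed) free[npar] <- FALSE

  # eta modes are warm-started from the best point seen so far; updating
  # only on improvement keeps the objective a deterministic function of the
  # parameters along the optimizer's finite-difference probes
  warm <- new.env(parent = emptyenv())
  warm$eta <- matrix(0, n, 4)
  warm$best <- Inf
  n_eval <- 0L
  obj_core <- function(xf, update = TRUE) {
    x <- x0; x[free] <- xf
    u <- unpack_params(x, cov_block, covariate = has_cov)
    res <- tryCatch(
      suppressWarnings(foce_objective(subs, u$p, u$omega, u$sigma,
                                      eta_start = warm$eta,
                                      cov_exp = u$cov_exp)),
      error = function(e) NULL)
    n_eval <<- n_eval + 1L
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    if (update && res$ofv < warm$best) { warm$eta <- res$eta; warm$best <- res$ofv }
    res$ofv
  }
  obj <- function(xf) obj_core(xf)
  # explicit central-difference gradient: a step of 1e-5 on the log scale
  # stays well above the numerical floor of the objective, so the gradient
  # is far less noisy than optimizer-internal sqrt(eps) differences
  grad <- function(xf) {
    g <- numeric(length(xf))
    for (k in seq_along(xf)) {
      hp <- hm <- xf
      hp[k] <- xf[k] + 1e-5
      hm[k] <- xf[k] - 1e-5
      g[k] <- (obj_core(hp, update = FALSE) - obj_core(hm, update = FALSE)) / 2e-5
    }
    g
  }
  # Outer search: restarted Nelder-Mead (robust to the small kinks that
  # conditional-mode selection leaves in the objective), then a local
  # gradient polish. The polish uses central differences well above the
  # numerical floor of the objective.
  ctrl <- utils::modifyList(list(nm_maxit = 1500, nm_restarts = 12,
                                 nm_tol = 0.01, rel.tol = 1e-8,
                                 iter.max = 100, cycles = 3), control)
  xcur <- x0[free]
  vcur <- obj(xcur)
  opt <- list(par = xcur, objective = vcur, convergence = 0L,
              iterations = 0L, message = "no optimization")
  for (cycle in seq_len(ctrl$cycles)) {
    v_cycle <- vcur
    for (round in seq_len(ctrl$nm_restarts)) {
      nm <- stats::optim(xcur, obj, method = "Nelder-Mead",
                         control = list(maxit = ctrl$nm_maxit, reltol = 1e-10))
      stalled <- vcur - nm$value < ctrl$nm_tol
      xcur <- nm$par; vcur <- nm$value
      if (stalled) break
    }
    opt <- stats::nlminb(xcur, obj, gradient = grad,
                         control = list(rel.tol = ctrl$rel.tol,
                                        iter.max = ctrl$iter.max))
    if (opt$objective > vcur) {    # polish must never make things worse
      opt$par <- xcur
      opt$objective <- vcur
      opt$convergence <- 0L
      opt$message <- "Nelder-Mead solution retained"
    }
    xcur <- opt$par; vcur <- opt$objective
    # a fresh full-size simplex from the polished point escapes shallow
    # local basins; stop once a whole cycle no longer improves
    if (v_cycle - vcur < 0.05) break
  }
  x <- x0; x[free] <- opt$par
  u <- unpack_params(x, cov_block, covariate = has_cov)
  final <- suppressWarnings(foce_objective(subs, u$p, u$omega, u$sigma,
                                           eta_start = warm$eta,
                                           cov_exp = u$cov_exp))
  rse <- NULL
  if (compute_se) {
    H <- stats::optimHess(opt$par, obj)
    cv <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      se_log <- sqrt(pmax(diag(cv), 0))
      # delta method: parameters are log-scale, so RSE% = 100 * se(log)
      nm <- c(fe_names, if (has_cov) c("exp_CL", "exp_V1"),
              paste0("om", seq_along(om_idx)), "sigma")[free]
      rse <- stats::setNames(100 * se_log, nm)
      rse <- rse[names(rse) %in% c(fe_names, "sigma")]
    }
  }
  structure(list(params = u$p, omega = u$omega, sigma = u$sigma,
                 cov_exponents = u$cov_exp,
                 ofv = final$ofv, eta = final$eta,
                 convergence = opt$convergence == 0 ||
                   abs(opt$objective - vcur) < 0.1, rse = rse,
                 n_eval = n_eval, iterations = opt$iterations,
                 message = opt$message, init = init, fixed = fixed,
                 cov_block = cov_block, covariate = covariate),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("FOCE-I fit: OFV =", format(x$ofv, digits = 8),
      if (x$convergence) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  omega CV%%: V1 %.1f, CL %.1f, D1 %.1f, R1 %.1f; cov(V1,CL) %.4f\n",
              100 * sqrt(x$omega[1, 1]), 100 * sqrt(x$omega[2, 2]),
              100 * sqrt(x$omega[3, 3]), 100 * sqrt(x$omega[4, 4]),
              x$omega[1, 2]))
  cat(sprintf("  proportional error: %.3f\n", x$sigma))
  if (!is.null(x$rse)) {
    cat("  RSE%:", paste(names(x$rse), sprintf("%.1f", x$rse)), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Forward inclusion requires a drop in OFV greater than the chi-square
#' critical value at p < 0.05 (3.84 for 1 df); backward retention requires
#' that removal raises OFV by more than the p < 0.01 value (6.63 for 1 df).
#'
#' @param reduced,full OFV values or `pk_fit` objects (full = more
#'   parameters)
#' @param df additional parameters in the full model
#' @param direction `"forward"` (alpha 0.05) or `"backward"` (alpha 0.01)
#' @return list with `delta_ofv`, `critical`, `significant`
#' @export
lrt_compare <- function(reduced, full, df = 1,
                        direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (df < 1) stop("lrt_compare: df must be >= 1")
  ofv_r <- if (inherits(reduced, "pk_fit")) reduced$ofv else reduced
  ofv_f <- if (inherits(full, "pk_fit")) full$ofv else full
  delta <- ofv_r - ofv_f
  if (delta < -1e-6)
    warning("lrt_compare: full model has higher OFV than reduced ",
            "(optimizer failure signal)")
  alpha <- if (direction == "forward") 0.05 else 0.01
  crit <- stats::qchisq(1 - alpha, df)
  list(delta_ofv = delta, critical = crit, significant = delta > crit)
}

#' Nonparametric bootstrap of the fit
#'
#' Resamples subjects with replacement (original n) and refits each
#' replicate starting from the original estimates. Because replicates are
#' multisets of the original subjects, each refit reuses the per-subject
#' likelihood with multiplicity weights. Non-converged replicates are
#' excluded from the summaries and counted.
#'
#' @param data a `pk_dataset`
#' @param fit the original `pk_fit` (source of initial values)
#' @param n_boot number of bootstrap replicates
#' @param seed RNG seed for the resampling (the objective itself is
#'   deterministic)
#' @param control optimizer control for the replicate fits
#' @return a `pk_boot` list: `summary` tibble (median and 2.5/97.5
#'   percentiles per parameter), `estimates` matrix, `n_boot`,
#'   `n_nonconverged`, `indices`
#' @export
bootstrap_fit <- function(data, fit, n_boot = 1000, seed = NULL,
                          control = list()) {
  stopifnot(inherits(fit, "pk_fit"))
  subs <- dataset_subjects(data)
  class(subs) <- "pk_subjects"
  attr(subs, "cpp_ptr") <- foce_data_ptr(unclass(subs))
  n <- length(subs)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  has_cov <- identical(fit$covariate, "power_weight")
  x0 <- pack_params(fit$params, fit$omega, fit$sigma, fit$cov_block,
                    cov_exp = fit$cov_exponents)
  npar <- length(x0)
  fe_names <- c("V1F", "CLF", "V2F", "QF", "D1", "R1")
  free <- rep(TRUE, npar)
  free[match(intersect(fit$fixed, fe_names), fe_names)] <- FALSE
  if ("omega" %in% fit$fixed) free[(7 + 2 * has_cov):(npar - 1)] <- FALSE
  if ("sigma" %in% fit$fixed) free[npar] <- FALSE
  ctrl <- utils::modifyList(list(nm_maxit = 500), control)
  pars <- matrix(NA_real_, n_boot, 8,
                 dimnames = list(NULL, c("V1F", "CLF", "V2F", "QF", "D1",
                                         "R1", "cov_V1_CL", "sigma")))
  conv <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(idx[, b], nbins = n)
    warm <- new.env(parent = emptyenv())
    warm$eta <- fit$eta
    warm$best <- Inf
    obj_core <- function(xf, update = TRUE) {
      x <- x0; x[free] <- xf
      u <- unpack_params(x, fit$cov_block, covariate = has_cov)
      res <- tryCatch(
        suppressWarnings(foce_objective(subs, u$p, u$omega, u$sigma,
                                        weights = w, eta_start = warm$eta,
                                        cov_exp = u$cov_exp,
                                        multistart = FALSE)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$ofv)) return(1e10)
      if (update && res$ofv < warm$best) { warm$eta <- res$eta; warm$best <- res$ofv }
      res$ofv
    }
    opt <- stats::optim(x0[free], obj_core, method = "Nelder-Mead",
                        control = list(maxit = ctrl$nm_maxit, reltol = 1e-9))
    # a short second simplex round measures remaining improvement; the
    # replicate counts as converged when it is essentially stationary
    opt2 <- stats::optim(opt$par, obj_core, method = "Nelder-Mead",
                         control = list(maxit = ctrl$nm_maxit %/% 2,
                                        reltol = 1e-9))
    conv[b] <- is.finite(opt2$value) && opt$value - opt2$value < 2
    xb <- x0; xb[free] <- opt2$par
    u <- unpack_params(xb, fit$cov_block, covariate = has_cov)
    pars[b, ] <- c(u$p$V1F, u$p$CLF, u$p$V2F, u$p$QF, u$p$D1, u$p$R1,
                   u$omega[1, 2], u$sigma)
  }
  keep <- conv
  if (mean(!keep) > 0.2)
    warning("bootstrap_fit: ", sum(!keep), " of ", n_boot,
            " replicates did not converge")
  qs <- apply(pars[keep, , drop = FALSE], 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  summary <- tibble::tibble(parameter = colnames(pars),
                            median = qs[1, ], ci_lower = qs[2, ],
                            ci_upper = qs[3, ])
  structure(list(summary = summary, estimates = pars, n_boot = n_boot,
                 n_nonconverged = sum(!conv), indices = idx),
            class = "pk_boot")
}

#' Eta shrinkage
#'
#' `shrinkage = (1 - SD(eta modes) / omega) * 100` per random effect; under
#' 30% is the conventional acceptability bound. Random effects with zero
#' population variance are undefined and reported as `NA`.
#'
#' @param eta matrix of per-subject conditional eta modes (columns `V1F`,
#'   `CLF`, `D1`, `R1`), e.g. `fit$eta`
#' @param omega the omega matrix of the fit
#' @return named numeric vector of shrinkage percentages
#' @export
eta_shrinkage <- function(eta, omega) {
  if (nrow(eta) < 2) stop("eta_shrinkage: need at least 2 subjects")
  w <- sqrt(diag(omega))
  sh <- ifelse(w > 0, (1 - apply(eta, 2, stats::sd) / w) * 100, NA_real_)
  stats::setNames(sh, eta_names())
}
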