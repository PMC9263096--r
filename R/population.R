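#' Inter-individual variability (omega) matrix
#'
#' Builds the 4x4 covariance matrix of the log-scale random effects
#' (eta) on `V1F`, `CLF`, `D1` and `R1`. Individual parameters are
#' `population value * exp(eta)`; `V2F` and `QF` carry no variability.
#' Variability is supplied as coefficients of variation (%) and interpreted,
#' by default, as `omega = CV/100` (the common reporting convention for
#' log-normal models); the exact log-normal transform
#' `omega^2 = log(1 + CV^2)` is available via `cv_as = "lognormal"`.
#'
#' @param cv_v1,cv_cl,cv_d1,cv_r1 coefficients of variation (%)
#' @param cov_v1_cl covariance between eta_V1 and eta_CL (log scale)
#' @param cv_as interpretation of CV%: `"sd"` (omega = CV/100) or
#'   `"lognormal"` (omega^2 = log(1 + (CV/100)^2))
#' @return 4x4 covariance matrix with dimnames `V1F`, `CLF`, `D1`, `R1`
#' @export
omega_matrix <- function(cv_v1 = 0, cv_cl = 0, cv_d1 = 0, cv_r1 = 0,
                         cov_v1_cl = 0, cv_as = c("sd", "lognormal")) {
  cv_as <- match.arg(cv_as)
  cv <- c(cv_v1, cv_cl, cv_d1, cv_r1) / 100
  if (any(cv < 0)) stop("omega_matrix: CV% must be non-negative")
  w2 <- if (cv_as == "sd") cv^2 else log(1 + cv^2)
  om <- diag(w2, 4)
  om[1, 2] <- om[2, 1] <- cov_v1_cl
  dimnames(om) <- list(eta_names(), eta_names())
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("omega_matrix: not positive semidefinite; cov(V1,CL) = ", cov_v1_cl,
         " is incompatible with variances ", w2[1], " and ", w2[2])
  }
  om
}

eta_names <- function() c("V1F", "CLF", "D1", "R1")

#' Final-model omega matrix for AST-001
#'
#' CV% of 29.0 (V1/F), 22.2 (CL/F), 38.0 (D1) and 18.0 (R1) with a
#' V1-CL covariance of 0.0483 (log scale).
#'
#' @inheritParams omega_matrix
#' @return 4x4 covariance matrix
#' @export
ast001_omega <- function(cv_as = "sd") {
  omega_matrix(cv_v1 = 29.0, cv_cl = 22.2, cv_d1 = 38.0, cv_r1 = 18.0,
               cov_v1_cl = 0.0483, cv_as = cv_as)
}

#' Proportional residual error magnitude of the final AST-001 model
#' @return the proportional error coefficient of variation (0.183)
#' @export
ast001_sigma <- function() 0.183

# Square-root factor of a PSD matrix that tolerates zero variances
# (chol() would fail on semidefinite input).
psd_factor <- function(om) {
  e <- eigen(om, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), nrow(om))
}

#' Sample individual parameter sets
#'
#' Draws eta vectors from a multivariate normal with covariance `omega` and
#' forms individual parameters as `population * exp(eta)` for `V1F`, `CLF`,
#' `D1`, `R1` (exponential model; positivity guaranteed). `V2F` and `QF` are
#' copied unchanged.
#'
#' @param p a [pk_params] object (population values)
#' @param omega 4x4 covariance matrix from [omega_matrix]
#' @param n number of individuals
#' @param weights body weights (kg), recycled to length `n`
#' @param seed optional RNG seed (set with [set.seed] when given)
#' @return tibble with columns `id`, `weight`, `eta_*` and the six
#'   individual parameters
#' @export
sample_individuals <- function(p, omega, n, weights = NA_real_, seed = NULL) {
  stopifnot(inherits(p, "pk_params"), n >= 1)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("sample_individuals: omega is not positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  L <- psd_factor(omega)
  eta <- matrix(stats::rnorm(n * 4), n, 4) %*% t(L)
  colnames(eta) <- eta_names()
  tibble::tibble(
    id = seq_len(n),
    weight = rep_len(as.numeric(weights), n),
    eta_V1F = eta[, "V1F"], eta_CLF = eta[, "CLF"],
    eta_D1 = eta[, "D1"], eta_R1 = eta[, "R1"],
    V1F = p$V1F * exp(eta[, "V1F"]),
    CLF = p$CLF * exp(eta[, "CLF"]),
    V2F = p$V2F, QF = p$QF,
    D1 = p$D1 * exp(eta[, "D1"]),
    R1 = p$R1 * exp(eta[, "R1"])
  )
}

# One row of a sample_individuals() tibble as a pk_params object.
individual_params <- function(ind, i) {
  pk_params(V1F = ind$V1F[i], CLF = ind$CLF[i], V2F = ind$V2F[i],
            QF = ind$QF[i], D1 = ind$D1[i], R1 = ind$R1[i])
}

#' Apply proportional residual error to a concentration profile
#'
#' Observed = predicted * (1 + eps) with eps ~ N(0, sigma_prop^2), i.i.d.
#' per observation. Concentrations cannot be negative, so negative results
#' are floored at 0; the number of floored observations is returned in the
#' `n_floored` attribute.
#'
#' @param profile tibble with columns `time`, `conc` (from [predict_conc])
#' @param sigma_prop proportional error coefficient of variation (>= 0)
#' @param seed optional RNG seed
#' @return the profile with perturbed `conc` and attribute `n_floored`
#' @export
apply_residual_error <- function(profile, sigma_prop, seed = NULL) {
  stopifnot(sigma_prop >= 0, all(profile$conc >= 0))
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(nrow(profile), 0, sigma_prop)
  obs <- profile$conc * (1 + eps)
  n_floored <- sum(obs < 0)
  profile$conc <- pmax(obs, 0)
  attr(profile, "n_floored") <- n_floored
  profile
}

#' Allometric scaling rule
#'
#' Fixed-exponent power model referenced to an adult weight: clearances
#' scale with `(weight/reference)^exponent_clearance` and volumes with
#' `(weight/reference)^exponent_volume`. The defaults are the conventional
#' 0.75 / 1 exponents at a 70 kg reference.
#'
#' @param exponent_clearance exponent for CLF and QF
#' @param exponent_volume exponent for V1F and V2F
#' @param reference_weight reference body weight (kg)
#' @return a `scaling_rule` list
#' @export
scaling_rule <- function(exponent_clearance = 0.75, exponent_volume = 1,
                         reference_weight = 70) {
  if (reference_weight <= 0) stop("scaling_rule: reference_weight must be > 0")
  structure(list(exponent_clearance = exponent_clearance,
                 exponent_volume = exponent_volume,
                 reference_weight = reference_weight),
            class = "scaling_rule")
}

#' Allometrically scale population parameters to a body weight
#'
#' `CLF` and `QF` are multiplied by `(weight/ref)^0.75`, `V1F` and `V2F` by
#' `(weight/ref)^1` (defaults of [scaling_rule]). `D1` is a duration and
#' `R1` the endogenous production rate; neither is scaled by default --
#' `scale_r1 = TRUE` additionally scales `R1` with the clearance exponent
#' for sensitivity analyses.
#'
#' @param p a [pk_params] object (adult reference values)
#' @param weight body weight (kg), > 0
#' @param rule a [scaling_rule]
#' @param scale_r1 also scale `R1` with the clearance exponent?
#' @return a scaled [pk_params] object
#' @export
allometric_scale <- function(p, weight, rule = scaling_rule(), scale_r1 = FALSE) {
  stopifnot(inherits(p, "pk_params"), inherits(rule, "scaling_rule"))
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("allometric_scale: weight must be a single positive number")
  fcl <- (weight / rule$reference_weight)^rule$exponent_clearance
  fv  <- (weight / rule$reference_weight)^rule$exponent_volume
  pk_params(V1F = p$V1F * fv, CLF = p$CLF * fcl,
            V2F = p$V2F * fv, QF = p$QF * fcl,
            D1 = p$D1, R1 = if (scale_r1) p$R1 * fcl else p$R1)
}

#' Sample adult body weights
#'
#' Normal distribution (mean 72.5 kg, SD 8 kg) truncated to the observed
#' phase-I range 54.5-86.9 kg, matching the reported median (range) of the
#' study population.
#'
#' @param n number of weights
#' @param mean,sd,lower,upper distribution parameters (kg)
#' @return numeric vector of weights (kg)
#' @export
sample_adult_weights <- function(n, mean = 72.5, sd = 8,
                                 lower = 54.5, upper = 86.9) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
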