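#' Population pharmacokinetic parameters
#'
#' Container for the six fixed effects of the structural model: apparent
#' central volume `V1F` (L), apparent clearance `CLF` (L/h), apparent
#' peripheral volume `V2F` (L), apparent inter-compartmental clearance `QF`
#' (L/h), zero-order absorption duration `D1` (h), and endogenous production
#' rate `R1` (g/h). Internal units are g, L and h throughout; concentrations
#' are converted to ug/mL only at the interface (1 g/L = 1000 ug/mL).
#'
#' `QF = 0` or `V2F = 0` is accepted and treated as the one-compartment
#' limit (decoupled or absent peripheral compartment) rather than an error.
#'
#' @param V1F apparent central volume of distribution (L)
#' @param CLF apparent clearance (L/h)
#' @param V2F apparent peripheral volume of distribution (L)
#' @param QF apparent inter-compartmental clearance (L/h)
#' @param D1 duration of zero-order absorption (h)
#' @param R1 endogenous production rate (g/h)
#' @return an object of class `pk_params` (named list)
#' @export
pk_params <- function(V1F, CLF, V2F, QF, D1, R1) {
  p <- list(V1F = V1F, CLF = CLF, V2F = V2F, QF = QF, D1 = D1, R1 = R1)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("pk_params: '", nm, "' must be a single finite number")
  }
  if (p$V1F <= 0 || p$CLF <= 0 || p$D1 <= 0)
    stop("pk_params: V1F, CLF and D1 must be strictly positive")
  if (p$R1 < 0) stop("pk_params: R1 must be non-negative")
  if (p$V2F < 0 || p$QF < 0)
    stop("pk_params: V2F and QF must be non-negative")
  structure(p, class = "pk_params")
}

#' Final model estimates for AST-001 (L-serine) in healthy adults
#'
#' The published final population estimates: V1/F 68.4 L, CL/F 22.9 L/h,
#' V2/F 196 L, Q/F 16.4 L/h, D1 1.26 h, R1 0.287 g/h. These imply an
#' endogenous steady-state plasma concentration of R1/CLF = 12.53 ug/mL.
#'
#' @return a [pk_params] object
#' @export
ast001_params <- function() {
  pk_params(V1F = 68.4, CLF = 22.9, V2F = 196, QF = 16.4, D1 = 1.26, R1 = 0.287)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Population PK parameters (g, L, h):\n")
  cat(sprintf("  V1/F %.4g L, CL/F %.4g L/h, V2/F %.4g L, Q/F %.4g L/h\n",
              x$V1F, x$CLF, x$V2F, x$QF))
  cat(sprintf("  D1 %.4g h, R1 %.4g g/h (baseline %.4g ug/mL)\n",
              x$D1, x$R1, 1000 * x$R1 / x$CLF))
  invisible(x)
}

#' Micro rate constants and hybrid disposition exponents
#'
#' Standard two-compartment reparameterization: `k10 = CLF/V1F`,
#' `k12 = QF/V1F`, `k21 = QF/V2F`; `alpha` and `beta` are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0` with `alpha >= beta`.
#' In the one-compartment limit (`QF = 0` or `V2F = 0`) the compartments
#' decouple: `k12 = k21 = 0`, `alpha = k10`, `beta = 0`.
#'
#' @param p a [pk_params] object
#' @return list with `k10`, `k12`, `k21`, `alpha`, `beta` (1/h)
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  k10 <- p$CLF / p$V1F
  if (p$QF == 0 || p$V2F == 0) {
    return(list(k10 = k10, k12 = 0, k21 = 0, alpha = k10, beta = 0))
  }
  k12 <- p$QF / p$V1F
  k21 <- p$QF / p$V2F
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta  <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}
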