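#' Dosing regimen
#'
#' A regimen is an ordered set of zero-order input events. Each event
#' delivers `amount` grams into the central compartment at a constant rate
#' over `duration` hours starting at clock time `start`. Overlapping events
#' are legal (their input rates add). An empty regimen describes the
#' endogenous-only condition.
#'
#' @param amount dose amounts (g), vector
#' @param start administration clock times (h), vector
#' @param duration zero-order input durations (h), vector (recycled)
#' @return a `pk_regimen` tibble with columns `amount`, `start`, `duration`
#' @export
regimen <- function(amount = numeric(), start = numeric(), duration = numeric()) {
  n <- length(amount)
  if (length(start) != n) stop("regimen: amount and start must have equal length")
  duration <- rep_len(duration, n)
  if (n > 0) {
    if (any(amount < 0)) stop("regimen: amounts must be non-negative")
    if (any(duration <= 0)) stop("regimen: durations must be strictly positive")
    if (is.unsorted(start)) stop("regimen: event starts must be non-decreasing")
  }
  out <- tibble::tibble(amount = as.numeric(amount), start = as.numeric(start),
                        duration = as.numeric(duration))
  class(out) <- c("pk_regimen", class(out))
  out
}

#' Repeated (e.g. twice-daily) dosing regimen
#'
#' @param amount dose per administration (g)
#' @param n_doses number of administrations
#' @param tau inter-dose interval (h); 12 for BID
#' @param duration zero-order input duration (h)
#' @param start clock time of the first dose (h)
#' @return a `pk_regimen`
#' @export
regimen_repeated <- function(amount, n_doses = 14, tau = 12, duration, start = 0) {
  regimen(amount = rep(amount, n_doses),
          start = start + tau * (seq_len(n_doses) - 1),
          duration = duration)
}

# Exogenous central concentration (g/L) from zero-order input events.
# Biexponential constant-rate-input solution, superposed over events;
# one-compartment closed form in the degenerate limit.
conc_exogenous_gL <- function(p, reg, times) {
  mc <- micro_constants(p)
  conc <- numeric(length(times))
  if (nrow(reg) == 0) return(conc)
  one_cpt <- (p$QF == 0 || p$V2F == 0)
  if (!one_cpt) {
    # alpha - beta >= k12 > 0 whenever both compartments are live, so the
    # hybrid-coefficient denominators cannot cancel catastrophically
    ab <- mc$alpha - mc$beta
    A <- (mc$alpha - mc$k21) / ab
    B <- (mc$k21 - mc$beta) / ab
  }
  for (i in seq_len(nrow(reg))) {
    if (reg$amount[i] == 0) next
    rate <- reg$amount[i] / reg$duration[i]          # g/h
    te <- times - reg$start[i]                        # time since event start
    act <- te > 0
    if (!any(act)) next
    t1 <- pmin(te[act], reg$duration[i])              # infusion-phase time
    t2 <- pmax(te[act] - reg$duration[i], 0)          # washout time
    if (one_cpt) {
      k <- mc$k10
      c_end <- (rate / p$CLF) * (1 - exp(-k * t1))
      conc[act] <- conc[act] + c_end * exp(-k * t2)
    } else {
      ca <- (A / mc$alpha) * (1 - exp(-mc$alpha * t1)) * exp(-mc$alpha * t2)
      cb <- (B / mc$beta)  * (1 - exp(-mc$beta  * t1)) * exp(-mc$beta  * t2)
      conc[act] <- conc[act] + (rate / p$V1F) * (ca + cb)
    }
  }
  conc
}

#' Predict plasma concentration over time
#'
#' Analytic concentration-time prediction of the structural model: the
#' superposition of (a) the endogenous steady state -- a constant central
#' concentration `R1/CLF` with the peripheral compartment at equilibrium --
#' and (b) the two-compartment constant-rate-input solution for every dose
#' event (input at rate `amount/duration` during the event, biexponential
#' washout afterwards). Deterministic; no randomness.
#'
#' @param p a [pk_params] object
#' @param reg a [regimen] (possibly empty)
#' @param times sampling times (h), non-negative
#' @param include_endogenous add the endogenous steady-state contribution?
#' @param label optional profile label carried in a `label` column
#' @return tibble with columns `time` (h) and `conc` (ug/mL)
#' @export
predict_conc <- function(p, reg, times, include_endogenous = TRUE, label = NULL) {
  stopifnot(inherits(p, "pk_params"))
  if (any(times < 0)) stop("predict_conc: negative sampling times")
  conc <- conc_exogenous_gL(p, reg, times)
  if (include_endogenous) conc <- conc + p$R1 / p$CLF
  out <- tibble::tibble(time = as.numeric(times), conc = 1000 * conc)
  if (!is.null(label)) out$label <- label
  out
}

#' Numerical ODE reference solution
#'
#' Integrates the two-compartment mass-balance equations with
#' piecewise-constant input numerically (lsoda, segment-wise between input
#' breakpoints, rtol/atol 1e-12). Same contract as [predict_conc]; retained
#' as an independent cross-check of the closed form, not a production path.
#'
#' @inheritParams predict_conc
#' @return tibble with columns `time` (h) and `conc` (ug/mL)
#' @export
ode_reference <- function(p, reg, times, include_endogenous = TRUE) {
  stopifnot(inherits(p, "pk_params"))
  if (any(times < 0)) stop("ode_reference: negative sampling times")
  if (any(diff(times) < 0)) stop("ode_reference: times must be non-decreasing")
  mc <- micro_constants(p)
  r_endo <- if (include_endogenous) p$R1 else 0
  # start at the endogenous steady state (or zero if excluded)
  a0 <- c(A1 = r_endo * p$V1F / p$CLF,
          A2 = if (p$CLF > 0) r_endo * p$V2F / p$CLF else 0)
  rate_at <- function(t) {
    r <- r_endo
    if (nrow(reg) > 0) {
      on <- t >= reg$start & t < reg$start + reg$duration
      r <- r + sum(reg$amount[on] / reg$duration[on])
    }
    r
  }
  deriv <- function(t, A, parms) {
    list(c(parms$rate - (mc$k10 + mc$k12) * A[1] + mc$k21 * A[2],
           mc$k12 * A[1] - mc$k21 * A[2]))
  }
  brk <- sort(unique(c(0, reg$start, reg$start + reg$duration, times)))
  brk <- brk[brk >= 0]
  state <- a0
  sol <- matrix(NA_real_, nrow = length(brk), ncol = 2)
  sol[1, ] <- state
  for (i in seq_len(length(brk) - 1)) {
    seg <- c(brk[i], brk[i + 1])
    rate <- rate_at(mean(seg))
    out <- deSolve::lsoda(y = state, times = seg, func = deriv,
                          parms = list(rate = rate),
                          rtol = 1e-12, atol = 1e-12)
    if (attr(out, "istate")[1] < 0)
      stop("ode_reference: integrator failure on segment [",
           seg[1], ", ", seg[2], "]")
    state <- out[nrow(out), c("A1", "A2")]
    sol[i + 1, ] <- state
  }
  conc <- sol[match(times, brk), 1] / p$V1F
  tibble::tibble(time = as.numeric(times), conc = 1000 * conc)
}
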