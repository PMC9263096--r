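#' Time-matched baseline adjustment
#'
#' Subtracts the time-matched baseline (day -1) concentration from the
#' dose-day concentration and floors negative differences at 0, the
#' standard correction for an endogenous analyte. Both profiles must be
#' sampled at the same relative times (tolerance 1e-6 h).
#'
#' @param dose_day tibble with `time` (h relative to dose) and `conc`
#' @param baseline_day tibble with `time` (h relative to the matching
#'   baseline clock time) and `conc`
#' @return tibble with `time`, `conc` (adjusted), and `n_floored` attribute
#' @export
baseline_adjust <- function(dose_day, baseline_day) {
  if (nrow(dose_day) != nrow(baseline_day))
    stop("baseline_adjust: profiles have different numbers of samples")
  dt <- abs(dose_day$time - baseline_day$time)
  if (any(dt > 1e-6))
    stop("baseline_adjust: unmatched sampling times at t = ",
         paste(signif(dose_day$time[dt > 1e-6], 6), collapse = ", "))
  adj <- dose_day$conc - baseline_day$conc
  out <- tibble::tibble(time = dose_day$time, conc = pmax(adj, 0))
  attr(out, "n_floored") <- sum(adj < 0)
  out
}

# Linear-trapezoid AUC over [t0, t1] on observed points, with linear
# interpolation at the window edges; no extrapolation outside the grid.
auc_trapezoid <- function(time, conc, t0, t1) {
  if (t0 >= t1) stop("auc_trapezoid: empty window")
  if (t0 < min(time) - 1e-9 || t1 > max(time) + 1e-9)
    stop("auc_trapezoid: window [", t0, ", ", t1,
         "] outside the sampled range [", min(time), ", ", max(time), "]")
  keep <- time > t0 + 1e-12 & time < t1 - 1e-12
  tt <- c(t0, time[keep], t1)
  cc <- c(stats::approx(time, conc, xout = t0)$y, conc[keep],
          stats::approx(time, conc, xout = t1)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Non-compartmental exposure metrics over a window
#'
#' Computes `cmax` and `tmax` (maximum sampled concentration and its time,
#' first occurrence on ties), `ctrough` (the concentration at the end of
#' the window, i.e. the end of the dosing interval) and `auc` (linear
#' trapezoid over the window) from a sampled profile. All metrics are
#' interval-bounded -- no terminal-slope extrapolation.
#'
#' @param profile tibble with `time` (h) and `conc` (ug/mL), strictly
#'   increasing times
#' @param window `c(t0, t1)`: analysis window, e.g. `c(0, 12)` for AUC12h
#'   or one steady-state interval for AUCtau
#' @return tibble row with `cmax`, `tmax`, `ctrough`, `auc`
#' @export
exposure_metrics <- function(profile, window) {
  time <- profile$time; conc <- profile$conc
  if (any(diff(time) <= 0)) stop("exposure_metrics: times must be strictly increasing")
  inw <- time >= window[1] - 1e-9 & time <= window[2] + 1e-9
  if (sum(inw) < 2) stop("exposure_metrics: fewer than 2 points inside the window")
  i <- which.max(conc[inw])
  iend <- which(abs(time - window[2]) <= 1e-9)
  ctr <- if (length(iend)) conc[iend[1]] else stats::approx(time, conc, xout = window[2])$y
  tibble::tibble(
    cmax = conc[inw][i],
    tmax = time[inw][i],
    ctrough = ctr,
    auc = auc_trapezoid(time, conc, window[1], window[2])
  )
}
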