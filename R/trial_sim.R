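#' Phase-I serial sampling times
#'
#' The trial schedule: 0, 10, 20, 30, 45 min, 1, 1.5, 2, 3, 4, 6, 9, 12 and
#' 24 h (14 points). The baseline day uses all 14; a dosing day uses the 13
#' post-dose points (the 0 h pre-dose sample coincides with the 24 h
#' baseline sample and is counted with the baseline).
#'
#' @param post_dose drop the 0 h point?
#' @return numeric vector of times (h)
#' @export
trial_sampling_times <- function(post_dose = FALSE) {
  tt <- c(0, 10 / 60, 20 / 60, 30 / 60, 45 / 60, 1, 1.5, 2, 3, 4, 6, 9, 12, 24)
  if (post_dose) tt[-1] else tt
}

#' Trial and simulation scenario presets
#'
#' Returns a `scenario` list describing subjects, dosing and sampling:
#' \describe{
#'   \item{`model_building`}{24 subjects, 8 per 10/20/30 g single-dose arm,
#'     24 h baseline day (14 samples) then dose day (13 post-dose samples);
#'     648 observations in total (336 baseline + 312 post-dose).}
#'   \item{`validation`}{7 subjects, 15 g single dose, then 15 g BID for 7
#'     days with sampling through 48 h after the final dose.}
#'   \item{`adult_single_<dose>` / `adult_bid_<dose>`}{200 simulated adults
#'     at 10, 15, 20 or 30 g, single dose or 7-day BID.}
#' }
#' Custom scenarios are built with [scenario()].
#'
#' @param name preset name
#' @return a `scenario` list
#' @export
build_scenario <- function(name) {
  presets <- c("model_building", "validation",
               paste0("adult_single_", c(10, 15, 20, 30)),
               paste0("adult_bid_", c(10, 15, 20, 30)))
  if (!name %in% presets)
    stop("build_scenario: unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  if (name == "model_building") {
    scenario(n_subjects = 24, dose = rep(c(10, 20, 30), each = 8),
             regimen_kind = "single", include_baseline_day = TRUE,
             residual_error = TRUE, label = name)
  } else if (name == "validation") {
    scenario(n_subjects = 7, dose = 15, regimen_kind = "single_then_bid",
             include_baseline_day = TRUE, residual_error = TRUE, label = name)
  } else {
    dose <- as.numeric(sub(".*_", "", name))
    kind <- if (grepl("single", name)) "single" else "bid"
    scenario(n_subjects = 200, dose = dose, regimen_kind = kind,
             include_baseline_day = TRUE, residual_error = FALSE, label = name)
  }
}

#' Construct a simulation scenario
#'
#' @param n_subjects number of subjects (>= 1)
#' @param dose dose amount (g), scalar or one per subject
#' @param regimen_kind `"single"`, `"bid"` (q12h x 7 days, 14 doses) or
#'   `"single_then_bid"` (the validation design)
#' @param n_doses number of doses for the BID phase
#' @param tau dosing interval (h) for the BID phase
#' @param include_baseline_day simulate the day -1 endogenous profile?
#' @param residual_error apply proportional residual error to DV?
#' @param weights `"adult"` (truncated-normal phase-I weights) or a numeric
#'   vector of body weights (kg)
#' @param label scenario label
#' @return a `scenario` list
#' @export
scenario <- function(n_subjects, dose, regimen_kind = "single",
                     n_doses = 14, tau = 12,
                     include_baseline_day = TRUE, residual_error = FALSE,
                     weights = "adult", label = "custom") {
  stopifnot(n_subjects >= 1, all(dose >= 0))
  regimen_kind <- match.arg(regimen_kind, c("single", "bid", "single_then_bid"))
  structure(list(n_subjects = as.integer(n_subjects),
                 dose = rep_len(dose, n_subjects),
                 regimen_kind = regimen_kind, n_doses = n_doses, tau = tau,
                 include_baseline_day = include_baseline_day,
                 residual_error = residual_error,
                 weights = weights, label = label),
            class = "scenario")
}

# Event schedule (dose starts, h) for one subject under a scenario.
# The baseline day, when present, occupies 0-24 h and the first dose is
# given at 24 h (same clock time as dosing on day 1); otherwise dosing
# starts at 0 h. The validation design washes out the single dose for
# 72 h before the BID phase.
scenario_dose_times <- function(sc) {
  t0 <- if (sc$include_baseline_day) 24 else 0
  switch(sc$regimen_kind,
    single = t0,
    bid = t0 + sc$tau * (seq_len(sc$n_doses) - 1),
    single_then_bid = c(t0, t0 + 72 + sc$tau * (seq_len(sc$n_doses) - 1))
  )
}

#' Simulate a NONMEM-style longitudinal dataset under a scenario
#'
#' Samples body weights and individual parameters, predicts concentrations
#' at the trial sampling times (baseline day: endogenous only; dosing days:
#' full superposition), optionally applies proportional residual error, and
#' emits a dataset with columns `ID`, `TIME` (h), `AMT` (g), `DUR` (h),
#' `EVID`, `MDV`, `DV` (ug/mL), `WT` (kg), `DAY`. Dose records have
#' `EVID 1, MDV 1, DV NA`; observations have `EVID 0, AMT 0`. Fully
#' reproducible given `seed`.
#'
#' @param sc a [scenario] or preset name for [build_scenario]
#' @param p population parameters ([pk_params])
#' @param omega IIV covariance matrix ([omega_matrix])
#' @param sigma_prop proportional residual error CV
#' @param seed RNG seed
#' @return tibble of class `pk_dataset`; attributes `individuals` (the
#'   sampled parameter tibble) and `n_floored`
#' @export
simulate_dataset <- function(sc, p = ast001_params(), omega = ast001_omega(),
                             sigma_prop = ast001_sigma(), seed = NULL) {
  if (is.character(sc)) sc <- build_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  wts <- if (identical(sc$weights, "adult")) {
    sample_adult_weights(sc$n_subjects)
  } else rep_len(as.numeric(sc$weights), sc$n_subjects)
  ind <- sample_individuals(p, omega, sc$n_subjects, weights = wts)

  rows <- vector("list", sc$n_subjects)
  n_floored <- 0L
  for (i in seq_len(sc$n_subjects)) {
    pi <- individual_params(ind, i)
    dose_times <- scenario_dose_times(sc)
    reg <- regimen(amount = rep(ind_dose <- sc$dose[i], length(dose_times)),
                   start = dose_times, duration = pi$D1)
    obs <- obs_schedule(sc, dose_times)
    prof <- predict_conc(pi, reg, obs$time)
    if (sc$residual_error && sigma_prop > 0) {
      prof <- apply_residual_error(prof, sigma_prop)
      n_floored <- n_floored + attr(prof, "n_floored")
    }
    obs_rows <- tibble::tibble(
      ID = i, TIME = obs$time, AMT = 0, DUR = 0, EVID = 0L, MDV = 0L,
      DV = prof$conc, WT = wts[i], DAY = obs$day)
    dose_rows <- tibble::tibble(
      ID = i, TIME = dose_times, AMT = ind_dose, DUR = pi$D1, EVID = 1L,
      MDV = 1L, DV = NA_real_, WT = wts[i],
      DAY = ceiling((dose_times - if (sc$include_baseline_day) 24 else 0) / 24) + 1)
    sub <- rbind(obs_rows, dose_rows)
    # a pre-dose observation sorts before the dose record at the same time
    rows[[i]] <- sub[order(sub$TIME, sub$EVID), ]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pk_dataset", class(out))
  attr(out, "individuals") <- ind
  attr(out, "n_floored") <- n_floored
  attr(out, "scenario") <- sc$label
  out
}

# Observation times and day labels for a scenario.
obs_schedule <- function(sc, dose_times) {
  time <- numeric(); day <- integer()
  t0 <- if (sc$include_baseline_day) 24 else 0
  if (sc$include_baseline_day) {
    time <- trial_sampling_times()          # 14 points, 0..24 h
    day <- rep(-1L, length(time))
  }
  post <- trial_sampling_times(post_dose = TRUE)
  if (sc$regimen_kind %in% c("single", "single_then_bid")) {
    time <- c(time, t0 + post)              # 13 post-dose points
    day <- c(day, rep(1L, 13))
  }
  if (sc$regimen_kind %in% c("bid", "single_then_bid")) {
    last <- max(dose_times)
    # post final dose: pre-dose trough, the 13 serial points, and 48 h
    tt <- last + c(0, post, 48)
    time <- c(time, tt)
    day <- c(day, rep.int(as.integer(ceiling((last - t0) / 24) + 1), length(tt)))
  }
  list(time = time, day = day)
}

#' Pointwise prediction percentiles across simulation replicates
#'
#' The numerical core of a visual predictive check: given replicate
#' concentration profiles simulated on a common time grid, returns the
#' pointwise simulation percentiles (default 5th, 50th and 95th).
#'
#' @param profiles list of tibbles with identical `time` grids, or a
#'   numeric matrix (replicates x times) plus `times`
#' @param probs percentiles in (0, 1)
#' @param times time grid when `profiles` is a matrix
#' @return tibble with column `time` and one `p<100q>` column per percentile
#' @export
vpc_percentiles <- function(profiles, probs = c(0.05, 0.5, 0.95), times = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles) && !is.matrix(profiles)) {
    times <- profiles[[1]]$time
    for (pr in profiles) {
      if (length(pr$time) != length(times) || any(abs(pr$time - times) > 1e-9))
        stop("vpc_percentiles: replicate time grids differ")
    }
    mat <- do.call(rbind, lapply(profiles, function(pr) pr$conc))
  } else {
    mat <- profiles
    if (is.null(times) || length(times) != ncol(mat))
      stop("vpc_percentiles: matrix input needs a matching 'times' vector")
  }
  q <- apply(mat, 2, stats::quantile, probs = probs, names = FALSE)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  out <- tibble::tibble(time = as.numeric(times))
  for (k in seq_along(probs)) out[[paste0("p", probs[k] * 100)]] <- q[k, ]
  out
}
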