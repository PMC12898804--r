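#' Pharmacokinetic parameters for NX210 / NX210c
#'
#' One-compartment model per species with first-order conversion of the
#' linear peptide (NX210) to its cyclic form (NX210c) in blood. The linear
#' form is short-lived (half-life ~2 min) because cyclization and other loss
#' routes are fast; the conversion fraction
#' `cyclization_rate / (cyclization_rate + elimination_rate_nx210)` is 0.1
#' with the defaults, which fixes the 10-fold higher NX210c exposure when the
#' cyclic form is dosed directly at the same mg/kg level.
#'
#' @param volume_of_distribution L/kg.
#' @param elimination_rate_nx210c first-order elimination of NX210c (1/h).
#' @param cyclization_rate NX210 -> NX210c conversion rate (1/h).
#' @param elimination_rate_nx210 other first-order loss of NX210 (1/h).
#' @return object of class `pk_params`.
#' @export
pk_params <- function(volume_of_distribution = 0.1,
                      elimination_rate_nx210c = 1,
                      cyclization_rate = 2,
                      elimination_rate_nx210 = 18) {
  check_number(volume_of_distribution, "volume_of_distribution", lower = 1e-9)
  check_number(elimination_rate_nx210c, "elimination_rate_nx210c", lower = 0)
  check_number(cyclization_rate, "cyclization_rate", lower = 0)
  check_number(elimination_rate_nx210, "elimination_rate_nx210", lower = 0)
  p <- as.list(environment())
  class(p) <- "pk_params"
  p
}

#' Dosing regimen
#'
#' Intravenous infusion schedule machinery: single doses, thrice-weekly
#' cycles (e.g. days 0/2/4 of each week for 4 weeks) and repeated cycles at a
#' fixed interval.
#'
#' @param compound `"NX210"` or `"NX210c"`.
#' @param dose mg/kg per infusion (> 0; 0 allowed to represent placebo).
#' @param infusion_duration minutes (> 0), default 10.
#' @param schedule_days days within each week on which an infusion is given
#'   (default `c(0, 2, 4)`, thrice weekly).
#' @param cycle_length_weeks weeks per treatment cycle (default 4).
#' @param cycle_interval_months months between cycle starts (default 6).
#' @param n_cycles number of cycles (>= 1). `n_cycles = 1` with
#'   `cycle_length_weeks = 0` denotes a single dose.
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(compound = c("NX210c", "NX210"), dose = 10,
                         infusion_duration = 10, schedule_days = c(0, 2, 4),
                         cycle_length_weeks = 4, cycle_interval_months = 6,
                         n_cycles = 1) {
  compound <- match.arg(compound)
  check_number(dose, "dose", lower = 0)
  check_number(infusion_duration, "infusion_duration", lower = 1e-9)
  check_number(schedule_days, "schedule_days", lower = 0, upper = 6)
  check_number(cycle_length_weeks, "cycle_length_weeks", lower = 0)
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(cycle_interval_months, "cycle_interval_months", lower = 0)
  r <- list(
    compound = compound, dose = dose,
    infusion_duration = infusion_duration,
    schedule_days = sort(unique(schedule_days)),
    cycle_length_weeks = cycle_length_weeks,
    cycle_interval_months = cycle_interval_months,
    n_cycles = as.integer(n_cycles)
  )
  class(r) <- "dose_regimen"
  r
}

#' Dosing days of a regimen
#'
#' @param regimen a [dose_regimen()].
#' @return integer vector of days (0-based) on which an infusion starts.
#' @export
dosing_days <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (regimen$cycle_length_weeks == 0) {
    within_cycle <- 0
  } else {
    weeks <- seq_len(regimen$cycle_length_weeks) - 1L
    within_cycle <- as.vector(outer(regimen$schedule_days, weeks * 7L, `+`))
  }
  cycle_starts <- (seq_len(regimen$n_cycles) - 1L) *
    round(regimen$cycle_interval_months * 30.4375)
  sort(as.integer(outer(within_cycle, cycle_starts, `+`)))
}

#' Named regimen presets
#'
#' Includes the single-ascending-dose levels (0.4-10 mg/kg single IV dose of
#' NX210), the multiple-ascending-dose cycles (5 or 10 mg/kg NX210c
#' thrice-weekly for 4 weeks via 10-min infusions), and repeated 4-week
#' cycles every 6 months.
#'
#' @param name preset name, e.g. `"sad_nx210_2.5"`, `"sad_nx210c_10"`,
#'   `"nx210c_5mgkg_cycle"`, `"nx210c_10mgkg_cycle"`,
#'   `"nx210c_10mgkg_repeat6mo"`, `"nx210_10mgkg_cycle"`.
#' @param n_cycles cycles for the repeated-cycle preset (default 4 = 2 years).
#' @return a [dose_regimen()].
#' @export
regimen_preset <- function(name, n_cycles = 4) {
  sad <- c(0.4, 1.25, 2.5, 5, 10)
  presets <- list()
  for (d in sad) {
    presets[[paste0("sad_nx210_", d)]] <-
      dose_regimen("NX210", d, cycle_length_weeks = 0)
    presets[[paste0("sad_nx210c_", d)]] <-
      dose_regimen("NX210c", d, cycle_length_weeks = 0)
  }
  presets$nx210c_5mgkg_cycle <- dose_regimen("NX210c", 5)
  presets$nx210c_10mgkg_cycle <- dose_regimen("NX210c", 10)
  presets$nx210_10mgkg_cycle <- dose_regimen("NX210", 10)
  presets$nx210c_10mgkg_repeat6mo <-
    dose_regimen("NX210c", 10, n_cycles = n_cycles)
  if (!name %in% names(presets)) {
    stop_bbbms("unknown regimen preset '", name, "'")
  }
  presets[[name]]
}

#' Simulate concentration-time profiles
#'
#' Numerically integrates the two-species linear system (deSolve::lsoda) with
#' piecewise-constant infusion input. Kinetics are linear: doubling the dose
#' doubles every concentration, and multi-dose profiles superpose.
#'
#' @param regimen a [dose_regimen()].
#' @param params a [pk_params()].
#' @param grid_min strictly increasing time grid in minutes. Resolution must
#'   be at most `infusion_duration / 2` so infusions are resolved.
#' @return object of class `pk_sim`: data.frame with columns `time_min`,
#'   `conc_nx210`, `conc_nx210c` (mg/L).
#' @export
#' @examples
#' pk <- simulate_pk(regimen_preset("sad_nx210c_10"), pk_params(),
#'                   grid_min = seq(0, 360, by = 2))
#' head(pk)
simulate_pk <- function(regimen, params = pk_params(),
                        grid_min = seq(0, 1440, by = 2)) {
  stopifnot(inherits(regimen, "dose_regimen"))
  check_number(grid_min, "grid_min", lower = 0)
  if (length(grid_min) < 2L || any(diff(grid_min) <= 0)) {
    stop_bbbms("grid_min must be strictly increasing")
  }
  if (max(diff(grid_min)) > regimen$infusion_duration / 2) {
    stop_bbbms("grid resolution coarser than infusion_duration/2")
  }
  if (!regimen$compound %in% c("NX210", "NX210c")) {
    stop_bbbms("unsupported compound")
  }

  dose_h <- dosing_days(regimen) * 24
  dur_h <- regimen$infusion_duration / 60
  rate <- regimen$dose / dur_h # mg/kg/h while infusing

  if (regimen$dose == 0) {
    out <- data.frame(time_min = grid_min, conc_nx210 = 0, conc_nx210c = 0)
  } else {
    # piecewise-constant infusion rate as a step forcing function
    rate_at <- function(t) {
      on <- vapply(t, function(tt) any(tt >= dose_h & tt < dose_h + dur_h), logical(1))
      ifelse(on, rate, 0)
    }
    k10 <- params$cyclization_rate + params$elimination_rate_nx210
    deriv <- function(t, y, parms) {
      r <- rate_at(t)
      d1 <- (if (regimen$compound == "NX210") r else 0) - k10 * y[1]
      d2 <- (if (regimen$compound == "NX210c") r else 0) +
        params$cyclization_rate * y[1] - params$elimination_rate_nx210c * y[2]
      list(c(d1, d2))
    }
    times_h <- grid_min / 60
    sol <- deSolve::lsoda(c(A1 = 0, A2 = 0), times_h, deriv, parms = NULL,
                          rtol = 1e-9, atol = 1e-12, hmax = dur_h / 2)
    out <- data.frame(
      time_min = grid_min,
      conc_nx210 = pmax(sol[, "A1"], 0) / params$volume_of_distribution,
      conc_nx210c = pmax(sol[, "A2"], 0) / params$volume_of_distribution
    )
  }
  class(out) <- c("pk_sim", "data.frame")
  attr(out, "regimen") <- regimen
  attr(out, "params") <- params
  out
}

#' Area under the concentration-time curve
#'
#' Trapezoidal AUC. Additive over contiguous sub-intervals and exact for
#' piecewise-linear profiles.
#'
#' @param x a `pk_sim` or a numeric time vector.
#' @param ... passed on.
#' @return AUC in mg.h/L (time converted from minutes for `pk_sim` input).
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @param conc concentration vector matching the time vector `x`.
#' @export
auc.default <- function(x, conc, ...) {
  check_number(x, "time", lower = 0)
  if (any(diff(x) <= 0)) stop_bbbms("time must be strictly increasing")
  check_number(conc, "conc", lower = 0)
  if (length(conc) != length(x)) stop_bbbms("time/conc length mismatch")
  trapz(x, conc)
}

#' @rdname auc
#' @param compound which species to integrate (`"nx210c"` default).
#' @export
auc.pk_sim <- function(x, compound = c("nx210c", "nx210"), ...) {
  compound <- match.arg(compound)
  col <- paste0("conc_", compound)
  auc.default(x$time_min / 60, x[[col]])
}

#' NX210c exposure ratio between two regimens
#'
#' Ratio of NX210c AUCs (regimen A over regimen B) at equal dose levels,
#' integrated over a horizon long enough for full washout.
#'
#' @param regimen_a,regimen_b [dose_regimen()]s with equal `dose`.
#' @param params a [pk_params()].
#' @param horizon_h integration horizon in hours after the last dose.
#' @return dimensionless exposure ratio (> 0).
#' @export
exposure_ratio <- function(regimen_a, regimen_b, params = pk_params(),
                           horizon_h = 48) {
  if (!isTRUE(all.equal(regimen_a$dose, regimen_b$dose))) {
    stop_bbbms("exposure_ratio requires equal dose levels")
  }
  grid <- seq(0, horizon_h * 60, by = 1)
  a <- auc(simulate_pk(regimen_a, params, grid))
  b <- auc(simulate_pk(regimen_b, params, grid))
  if (b <= 0) stop_bbbms("denominator AUC is zero")
  a / b
}

#' @export
print.pk_sim <- function(x, ...) {
  r <- attr(x, "regimen")
  cat(sprintf(
    "PK simulation: %s %.3g mg/kg, %d infusion(s), %d time points\n",
    r$compound, r$dose, length(dosing_days(r)), nrow(x)
  ))
  cat(sprintf("  Cmax NX210c = %.3g mg/L, AUC NX210c = %.4g mg.h/L\n",
              max(x$conc_nx210c), auc(x)))
  invisible(x)
}

#' @export
plot.pk_sim <- function(x, ...) {
  plot(x$time_min, x$conc_nx210c, type = "l", xlab = "time (min)",
       ylab = "concentration (mg/L)", ...)
  graphics::lines(x$time_min, x$conc_nx210, lty = 2)
  graphics::legend("topright", c("NX210c", "NX210"), lty = c(1, 2), bty = "n")
  invisible(x)
}
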