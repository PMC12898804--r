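#' Blood-brain barrier integrity state
#'
#' Container for the mechanistic barrier state. `tjp_level` is a composite
#' claudin-5/occludin tight-junction expression level normalised so that 1 is
#' the healthy age-40 baseline; `bmec_density` and `pericyte_coverage` are the
#' endothelial and mural-cell fractions on the same convention. `damage` is an
#' accumulated inflammatory-injury burden (dimensionless, >= 0) fed by CNS
#' infiltration, and `repair_capital` is the cumulative drug-driven repair
#' exposure that carries the persistent effect of NX210c (set-point uplift,
#' paracellular tightening); both start at 0 in an untreated subject.
#'
#' @param tjp_level,bmec_density,pericyte_coverage fractions in `[0, 1]`.
#' @param damage non-negative injury burden.
#' @param repair_capital non-negative cumulative repair exposure (effect-days).
#' @return object of class `bbb_state`.
#' @export
#' @examples
#' bbb_state() # healthy age-40 baseline
bbb_state <- function(tjp_level = 1, bmec_density = 1, pericyte_coverage = 1,
                      damage = 0, repair_capital = 0) {
  st <- list(
    tjp_level = tjp_level, bmec_density = bmec_density,
    pericyte_coverage = pericyte_coverage, damage = damage,
    repair_capital = repair_capital
  )
  class(st) <- "bbb_state"
  validate_bbb_state(st)
  st
}

#' @rdname bbb_state
#' @param state object to validate.
#' @export
validate_bbb_state <- function(state) {
  if (!inherits(state, "bbb_state")) stop_bbbms("not a bbb_state")
  check_fraction(state$tjp_level, "tjp_level")
  check_fraction(state$bmec_density, "bmec_density")
  check_fraction(state$pericyte_coverage, "pericyte_coverage")
  check_number(state$damage, "damage", lower = 0)
  check_number(state$repair_capital, "repair_capital", lower = 0)
  invisible(state)
}

#' Parameters of the BBB integrity model
#'
#' Defaults are the shipped calibration: a first-order decline of TJP level
#' toward a floor, with the decline rate multiplied in RRMS, tuned so that an
#' untreated RRMS cohort ends ~15% below untreated healthy subjects after a
#' 30-year simulation from age 40, and one 4-week 10 mg/kg NX210c cycle yields
#' ~7% higher TJP and ~8% higher TEER at the same horizon.
#'
#' @param healthy_decline_rate per-year first-order TJP loss rate (> 0).
#'   Default `log(4/3)/30`: healthy TJP falls 1 -> 0.85 over 30 years.
#' @param disease_decline_multiplier dimensionless >= 1 acceleration in RRMS.
#' @param tjp_floor asymptote of the untreated decline law.
#' @param teer_baseline normalised TEER of the healthy age-40 state (1).
#' @param teer_floor paracellular-leak floor of TEER when `tjp_level = 0`.
#' @param teer_alpha,teer_beta elasticities of TEER in TJP level and BMEC
#'   density (>= 1). `teer_alpha = 1.22` reproduces the observed amplification
#'   of treatment effects on electrical resistance relative to TJP expression.
#' @param teer_invitro_scale ohm.cm^2 corresponding to TEER = 1 when reporting
#'   in vitro monolayer units.
#' @param perm_baseline normalised apparent (dextran) permeability at baseline.
#' @param perm_exponent sensitivity of permeability to relative TEER loss.
#' @param perm_damage_weight permeability increase per unit damage burden.
#' @param perm_pericyte_weight permeability increase per unit pericyte loss.
#' @param inflammation_injury_gain damage increment per infiltrated cell.
#' @param damage_recovery_rate slow spontaneous damage resolution (per day).
#' @param repair_damage_clear damage clearance per unit repair exposure.
#' @param uplift_max,uplift_rate persistent set-point uplift channel:
#'   `uplift = uplift_max * (1 - exp(-uplift_rate * repair_capital))`.
#' @param tighten_max,tighten_rate paracellular tightening channel (reduces
#'   leak-driven permeability and hence infiltration).
#' @param force_atten_rate slow attenuation of adhesion-driven (forced)
#'   infiltration with cumulative repair.
#' @param infil_baseline_prob baseline per-candidate, per-step (6 h) CNS
#'   crossing probability at healthy permeability and baseline adhesion.
#' @return object of class `bbb_params`.
#' @export
bbb_params <- function(healthy_decline_rate = log(4 / 3) / 30,
                       disease_decline_multiplier = 1.8556,
                       tjp_floor = 0.4,
                       teer_baseline = 1,
                       teer_floor = 0.05,
                       teer_alpha = 1.22,
                       teer_beta = 1,
                       teer_invitro_scale = 150,
                       perm_baseline = 1,
                       perm_exponent = 2,
                       perm_damage_weight = 0.02,
                       perm_pericyte_weight = 0.5,
                       inflammation_injury_gain = 0.01,
                       damage_recovery_rate = 0.001,
                       repair_damage_clear = 0.5,
                       uplift_max = 0.15,
                       uplift_rate = 1.0874,
                       tighten_max = 0.97,
                       tighten_rate = 2.0539,
                       force_atten_rate = 0.18531,
                       infil_baseline_prob = 0.005) {
  check_number(healthy_decline_rate, "healthy_decline_rate", lower = 1e-12)
  check_number(disease_decline_multiplier, "disease_decline_multiplier", lower = 1)
  check_fraction(tjp_floor, "tjp_floor")
  check_number(teer_baseline, "teer_baseline", lower = 1e-12)
  check_number(teer_floor, "teer_floor", lower = 0)
  if (teer_floor >= teer_baseline) stop_bbbms("teer_floor must be below teer_baseline")
  check_number(teer_alpha, "teer_alpha", lower = 1)
  check_number(teer_beta, "teer_beta", lower = 1)
  check_number(perm_baseline, "perm_baseline", lower = 1e-12)
  p <- as.list(environment())
  class(p) <- "bbb_params"
  p
}

# persistent-repair channels -------------------------------------------------

tjp_setpoint <- function(params, repair_capital) {
  params$tjp_floor +
    params$uplift_max * (1 - exp(-params$uplift_rate * repair_capital))
}

leak_tightening <- function(params, repair_capital) {
  params$tighten_max * (1 - exp(-params$tighten_rate * repair_capital))
}

force_attenuation <- function(params, repair_capital) {
  exp(-params$force_atten_rate * repair_capital)
}

#' Transendothelial electrical resistance readout
#'
#' `TEER = floor + (baseline - floor) * tjp^alpha * bmec^beta`, strictly
#' increasing in both TJP level and BMEC density; the paracellular-leak floor
#' is the residual resistance of a fully junction-depleted monolayer.
#'
#' @param state a [bbb_state()] (fields may be equal-length vectors).
#' @param params a [bbb_params()].
#' @param units `"normalized"` (baseline = 1) or `"ohm_cm2"` for in vitro
#'   monolayer units via `teer_invitro_scale`.
#' @return positive numeric TEER.
#' @export
compute_teer <- function(state, params = bbb_params(),
                         units = c("normalized", "ohm_cm2")) {
  validate_bbb_state(state)
  units <- match.arg(units)
  teer <- params$teer_floor + (params$teer_baseline - params$teer_floor) *
    state$tjp_level^params$teer_alpha * state$bmec_density^params$teer_beta
  if (units == "ohm_cm2") teer <- teer * params$teer_invitro_scale
  teer
}

#' Apparent paracellular permeability readout
#'
#' Normalised dextran-permeability proxy: rises as TEER falls (power law),
#' with additive contributions from accumulated inflammatory damage and
#' pericyte loss, and reduced by the persistent NX210c paracellular
#' tightening. At the fully healthy untreated state it equals `perm_baseline`.
#'
#' @inheritParams compute_teer
#' @return positive numeric permeability, strictly decreasing in `tjp_level`.
#' @export
compute_permeability <- function(state, params = bbb_params()) {
  validate_bbb_state(state)
  teer <- compute_teer(state, params)
  rel <- (params$teer_baseline / teer)^params$perm_exponent
  params$perm_baseline * rel *
    (1 - leak_tightening(params, state$repair_capital)) *
    (1 + params$perm_damage_weight * state$damage) *
    (1 + params$perm_pericyte_weight * (1 - state$pericyte_coverage))
}

#' Advance the BBB state by one time step
#'
#' TJP level follows a first-order decay toward its set point,
#' `tjp' = -k (tjp - setpoint)`, with `k = healthy_decline_rate` (per year,
#' converted internally to days) multiplied by `disease_decline_multiplier`
#' when `disease = TRUE`. `repair_input` (repair exposure accrued during the
#' step, from the NX210c pharmacodynamic coupling) accumulates into
#' `repair_capital`, which persistently raises the set point and clears
#' damage; `infiltration_load` (cells crossing during the step) adds damage.
#' The update is exact for piecewise-constant inputs, so with zero inputs the
#' stepper matches the analytic exponential solution to rounding error.
#'
#' @param state a [bbb_state()].
#' @param params a [bbb_params()].
#' @param age subject age in years at the start of the step (interface
#'   convention; the first-order law itself is age-homogeneous).
#' @param disease logical, RRMS disease flag.
#' @param infiltration_load cells crossing into the CNS during the step (>= 0).
#' @param repair_input repair exposure accrued during the step (>= 0).
#' @param dt step length in days (> 0).
#' @return the updated `bbb_state`.
#' @export
#' @examples
#' st <- bbb_state()
#' step_bbb(st, bbb_params(), age = 40, disease = FALSE, dt = 1)
step_bbb <- function(state, params = bbb_params(), age = 40, disease = FALSE,
                     infiltration_load = 0, repair_input = 0, dt = 1) {
  validate_bbb_state(state)
  check_number(age, "age", lower = 0)
  check_flag(disease, "disease")
  check_number(infiltration_load, "infiltration_load", lower = 0)
  check_number(repair_input, "repair_input", lower = 0)
  check_number(dt, "dt", lower = 1e-12)

  u_new <- state$repair_capital + repair_input
  s <- tjp_setpoint(params, u_new)
  k_day <- params$healthy_decline_rate / 365 *
    ifelse(disease, params$disease_decline_multiplier, 1)
  tjp_new <- s + (state$tjp_level - s) * exp(-k_day * dt)
  if (any(tjp_new < 0) || any(tjp_new > 1)) {
    stop_bbbms("tjp_level left [0, 1] during update; check calibration")
  }
  dmg <- state$damage * exp(-params$damage_recovery_rate * dt) +
    params$inflammation_injury_gain * infiltration_load
  dmg <- pmax(0, dmg * exp(-params$repair_damage_clear * repair_input))

  out <- state
  out$tjp_level <- tjp_new
  out$damage <- dmg
  out$repair_capital <- u_new
  validate_bbb_state(out)
  out
}

#' CNS infiltration probability of a candidate effector cell
#'
#' Per-candidate, per-step probability that an activated effector crosses the
#' BBB: `p = (1 - block) * p0 * (perm / perm_baseline + (adhesion - 1))`.
#' The first term is passive paracellular leak (closed by NX210c tightening,
#' which already lowers `permeability`); the second is adhesion-molecule-driven
#' forced entry, a patient trait elevated in highly active disease. An
#' infiltration-blocking treatment (natalizumab) scales the whole probability
#' by `1 - block_factor`.
#'
#' @param permeability positive normalised permeability (e.g. from
#'   [compute_permeability()]).
#' @param adhesion_upregulation dimensionless >= 0, 1 = baseline adhesion.
#' @param block_factor fraction of crossings blocked, in `[0, 1]`.
#' @param params a [bbb_params()] (supplies the baseline probability).
#' @return probability in `[0, 1]`, strictly increasing in permeability.
#' @export
infiltration_probability <- function(permeability, adhesion_upregulation = 1,
                                     block_factor = 0, params = bbb_params()) {
  check_number(permeability, "permeability", lower = 1e-12)
  check_number(adhesion_upregulation, "adhesion_upregulation", lower = 0)
  check_fraction(block_factor, "block_factor")
  p <- (1 - block_factor) * params$infil_baseline_prob *
    (permeability / params$perm_baseline + pmax(adhesion_upregulation - 1, 0))
  pmin(pmax(p, 0), 1)
}

#' Simulate untreated or treated BBB trajectories for a cohort
#'
#' Vectorised multi-year integration of the decline law at daily resolution
#' for `length(tjp0)` subjects sharing parameters and treatment but with
#' individual baseline integrity. Used by the trial engine for the long-term
#' marker scenarios.
#'
#' @param tjp0 vector of baseline TJP levels (fractions).
#' @param params a [bbb_params()].
#' @param years simulation horizon in years.
#' @param disease RRMS flag.
#' @param repair_daily optional numeric vector of daily repair exposures
#'   (effect-days per day) of length >= `years * 365`; `NULL` = untreated.
#' @param dt_days step in days.
#' @return list with `time_days`, and matrices (`days + 1` x n) `tjp`, `teer`,
#'   plus final-state summaries `tjp_final`, `teer_final`.
#' @export
simulate_bbb_cohort <- function(tjp0, params = bbb_params(), years = 30,
                                disease = FALSE, repair_daily = NULL,
                                dt_days = 1) {
  check_fraction(tjp0, "tjp0")
  check_number(years, "years", lower = 1e-9)
  n_steps <- ceiling(years * 365 / dt_days)
  n <- length(tjp0)
  if (!is.null(repair_daily)) {
    check_number(repair_daily, "repair_daily", lower = 0)
    if (length(repair_daily) < n_steps * dt_days) {
      repair_daily <- c(repair_daily, rep(0, n_steps * dt_days - length(repair_daily)))
    }
  }
  k_day <- params$healthy_decline_rate / 365 *
    if (disease) params$disease_decline_multiplier else 1
  decay <- exp(-k_day * dt_days)

  tjp <- matrix(NA_real_, n_steps + 1L, n)
  tjp[1L, ] <- tjp0
  cur <- tjp0
  u <- 0
  for (j in seq_len(n_steps)) {
    if (!is.null(repair_daily)) {
      day <- floor((j - 1) * dt_days) + 1L
      u <- u + repair_daily[day] * dt_days
    }
    s <- tjp_setpoint(params, u)
    cur <- s + (cur - s) * decay
    tjp[j + 1L, ] <- cur
  }
  teer <- params$teer_floor + (params$teer_baseline - params$teer_floor) *
    tjp^params$teer_alpha
  list(
    time_days = seq(0, n_steps * dt_days, by = dt_days),
    tjp = tjp, teer = teer,
    repair_capital = u,
    tjp_final = tjp[n_steps + 1L, ], teer_final = teer[n_steps + 1L, ]
  )
}

#' @export
print.bbb_state <- function(x, ...) {
  cat("BBB state: tjp_level =", format(x$tjp_level, digits = 4),
      " bmec_density =", format(x$bmec_density, digits = 4),
      " pericyte =", format(x$pericyte_coverage, digits = 4),
      "\n  damage =", format(x$damage, digits = 4),
      " repair_capital =", format(x$repair_capital, digits = 4), "\n")
  invisible(x)
}
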