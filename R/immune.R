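#' Disease-layer parameters
#'
#' Rates of the stochastic immune/relapse layer. Antigen challenges arrive as
#' a Poisson process (patient-modulated rate); an arriving challenge
#' activates an autoreactive clone with the patient's activation propensity
#' scaled by the antigen-presentation drive; activated clones expand into an
#' effector burst whose cells cross the BBB with the infiltration
#' probability; infiltrated effectors kill oligodendrocytes, which otherwise
#' recover logistically toward baseline.
#'
#' The oligodendrocyte baseline of 50,000 cells/uL makes the two relapse
#' thresholds consistent: a clinical relapse is a fall below 42,500 cells/uL,
#' i.e. more than 15% below baseline.
#'
#' @param odc_baseline oligodendrocyte baseline, cells/uL.
#' @param antigen_event_rate self-antigen challenge rate, events/year,
#'   multiplied per patient by `antigen_rate_multiplier`.
#' @param odc_kill_rate fractional ODC kill per infiltrated effector per day, scaled by the remaining ODC fraction (mass action).
#' @param odc_recovery_rate logistic ODC recovery rate, 1/day.
#' @param treg_suppression_gain suppression of activation by regulatory T
#'   cells above baseline (neutral default 0).
#' @param effector_burst mean effector burst size (cells/uL) of an activated
#'   clone at baseline proliferation.
#' @param burst_sdlog lognormal event-to-event burst variability.
#' @param effector_decay contraction rate of activated effectors, 1/day.
#' @param infiltrate_decay clearance of CNS infiltrate, 1/day.
#' @param antigen_clearance self-antigen clearance, 1/day.
#' @param apc_weight_dc,apc_weight_b weights of dendritic cells and B cells
#'   in the antigen-presentation drive of activation.
#' @param bcell_recovery,lymph_recovery reconstitution rates of depleted
#'   pools, 1/day (slow: depletion persists across dosing intervals).
#' @param baselines named list of homeostatic population baselines
#'   (cells/uL): dc, th1, th2, th17, treg, ctl, b_cells, microglia.
#' @return object of class `disease_params`.
#' @export
disease_params <- function(odc_baseline = 50000,
                           antigen_event_rate = 3,
                           odc_kill_rate = 110,
                           odc_recovery_rate = 0.09,
                           treg_suppression_gain = 0,
                           effector_burst = 150,
                           burst_sdlog = 0.3,
                           effector_decay = 0.18,
                           infiltrate_decay = 0.18,
                           antigen_clearance = 0.2,
                           apc_weight_dc = 0.2,
                           apc_weight_b = 0.8,
                           bcell_recovery = 0.001,
                           lymph_recovery = 0.002,
                           baselines = list(dc = 20, th1 = 100, th2 = 150,
                                            th17 = 50, treg = 60, ctl = 300,
                                            b_cells = 200, microglia = 10)) {
  check_number(odc_baseline, "odc_baseline", lower = 1)
  check_number(antigen_event_rate, "antigen_event_rate", lower = 0)
  check_number(odc_kill_rate, "odc_kill_rate", lower = 0)
  check_number(odc_recovery_rate, "odc_recovery_rate", lower = 0)
  check_number(treg_suppression_gain, "treg_suppression_gain", lower = 0)
  p <- as.list(environment())
  class(p) <- "disease_params"
  p
}

#' Immune-state container
#'
#' Cell-population counts (cells/uL, or abstract counts for antibody titre)
#' for `n` patients, initialised at homeostatic baselines with the
#' oligodendrocyte population at its baseline and no CNS infiltrate.
#'
#' @param n number of patients the state tracks.
#' @param params a [disease_params()].
#' @return object of class `immune_state`: list of length-`n` numeric
#'   vectors (`dendritic_cells`, `th1`, `th2`, `th17`, `treg`, `ctl`,
#'   `b_cells`, `antibody_titer`, `microglia_activated`, `odc`,
#'   `cns_infiltrate`, `antigen`, `effectors_activated`).
#' @export
immune_state <- function(n = 1, params = disease_params()) {
  b <- params$baselines
  st <- list(
    dendritic_cells = rep(b$dc, n), th1 = rep(b$th1, n), th2 = rep(b$th2, n),
    th17 = rep(b$th17, n), treg = rep(b$treg, n), ctl = rep(b$ctl, n),
    b_cells = rep(b$b_cells, n), antibody_titer = rep(0, n),
    microglia_activated = rep(b$microglia, n),
    odc = rep(params$odc_baseline, n), cns_infiltrate = rep(0, n),
    antigen = rep(0, n), effectors_activated = rep(0, n)
  )
  class(st) <- "immune_state"
  st
}

# Vectorised transition kernel: one step of length dt days for n patients.
# st: immune_state vectors; bbb: list(tjp, damage) vectors; u: n x 4 uniforms
# (antigen arrival, activation, crossing, burst size); traits: list of
# per-patient vectors; ctx: treatment context at this step (scalars:
# dc_mult, prolif_mult, block, bcell_dep, lymph_dep, theta, f_atten,
# setpoint, rexp, k_day); dp/bp: parameter objects.
immune_kernel <- function(st, bbb, u, traits, ctx, dp, bp, dt) {
  b <- dp$baselines
  basesum <- b$th1 + b$th17 + b$ctl

  # antigen challenges (Poisson via quantile transform: paired across arms)
  lam <- dp$antigen_event_rate * traits$antigen_rate_multiplier * dt / 365
  arrivals <- stats::qpois(u[, 1], lam)
  st$antigen <- st$antigen * exp(-dp$antigen_clearance * dt) + arrivals

  # activation of an autoreactive clone
  drive <- (dp$apc_weight_dc * (st$dendritic_cells / b$dc) * ctx$dc_mult +
              dp$apc_weight_b * (st$b_cells / b$b_cells)) /
    (dp$apc_weight_dc + dp$apc_weight_b)
  treg_fac <- 1 / (1 + dp$treg_suppression_gain * (st$treg / b$treg - 1))
  p_act <- pmin(1, traits$activation_prob * drive * treg_fac)
  activated <- (arrivals > 0) & (u[, 2] < p_act)

  # effector burst, scaled by proliferation multiplier and availability of
  # the (possibly depleted) lymphocyte pools
  lymph_avail <- pmin(1.2, (st$th1 + st$th17 + st$ctl) / basesum)
  burst <- dp$effector_burst * traits$effector_burst_scale *
    stats::qlnorm(u[, 4], 0, dp$burst_sdlog) * ctx$prolif_mult * lymph_avail

  # homeostatic pools: depletion events, then slow reconstitution of
  # deficits / faster contraction of excess
  relax <- function(x, x0, dep) {
    x <- x * (1 - dep)
    lo <- pmin(x, x0)
    hi <- pmax(x - x0, 0)
    x0 + (lo - x0) * exp(-dp$lymph_recovery * dt) + hi * exp(-dp$effector_decay * dt)
  }
  st$th1 <- relax(st$th1, b$th1, ctx$lymph_dep)
  st$th2 <- relax(st$th2, b$th2, ctx$lymph_dep)
  st$th17 <- relax(st$th17, b$th17, ctx$lymph_dep)
  st$treg <- relax(st$treg, b$treg, ctx$lymph_dep)
  st$ctl <- relax(st$ctl, b$ctl, ctx$lymph_dep)
  st$b_cells <- st$b_cells * (1 - ctx$bcell_dep) * (1 - ctx$lymph_dep)
  st$b_cells <- b$b_cells + (st$b_cells - b$b_cells) * exp(-dp$bcell_recovery * dt)
  st$dendritic_cells <- b$dc + (st$dendritic_cells - b$dc) * exp(-0.2 * dt) +
    5 * arrivals
  st$antibody_titer <- st$antibody_titer * exp(-0.05 * dt) +
    0.02 * st$b_cells * st$antigen * dt

  # activated effectors expand and contract
  st$effectors_activated <- st$effectors_activated * exp(-dp$effector_decay * dt) +
    burst * activated

  # BBB-gated CNS crossing
  teer <- bp$teer_floor + (bp$teer_baseline - bp$teer_floor) * bbb$tjp^bp$teer_alpha
  perm_rel <- (bp$teer_baseline / teer)^bp$perm_exponent *
    (1 + bp$perm_damage_weight * bbb$damage) * (1 - ctx$theta)
  a_eff <- 1 + (traits$adhesion_upregulation - 1) * ctx$f_atten
  p_inf <- pmin(1, pmax(0, (1 - ctx$block) * bp$infil_baseline_prob *
                          (perm_rel + pmax(a_eff - 1, 0))))
  crossings <- stats::qpois(u[, 3], st$effectors_activated * p_inf)
  st$cns_infiltrate <- st$cns_infiltrate * exp(-dp$infiltrate_decay * dt) + crossings
  st$microglia_activated <- b$microglia * (1 + st$cns_infiltrate / 50)

  # oligodendrocyte kill (mass action: infiltrated effectors destroy a
  # fraction of the remaining pool) and logistic recovery toward baseline
  odc <- st$odc + dt * dp$odc_recovery_rate * st$odc * (1 - st$odc / dp$odc_baseline) -
    dt * dp$odc_kill_rate * st$cns_infiltrate * st$odc / dp$odc_baseline
  st$odc <- pmin(pmax(odc, 0), dp$odc_baseline)

  # barrier: injury from crossings, repair clearance, first-order decline
  bbb$damage <- bbb$damage * exp(-bp$damage_recovery_rate * dt) +
    bp$inflammation_injury_gain * crossings
  bbb$damage <- bbb$damage * exp(-bp$repair_damage_clear * ctx$rexp)
  bbb$tjp <- ctx$setpoint + (bbb$tjp - ctx$setpoint) * exp(-ctx$k_day * dt)

  list(immune = st, bbb = bbb, crossings = crossings)
}

#' Advance the immune state of one patient by one step
#'
#' Single-patient interface to the stochastic disease-layer transition used
#' by the trial engine (which runs the identical kernel vectorised over a
#' cohort). Requires a seeded [rng_stream()]; identical inputs and stream
#' give bit-identical outputs.
#'
#' @param state an [immune_state()] with `n = 1`.
#' @param patient a [generate_patient()] result (or a list with fields
#'   `antigen_rate_multiplier`, `activation_prob`, `adhesion_upregulation`,
#'   `effector_burst_scale`).
#' @param bbb a [bbb_state()] for this patient.
#' @param effects list of [treatment_effect()]s active during the step.
#' @param params a [disease_params()].
#' @param rng a seeded [rng_stream()].
#' @param dt step length in days (default 0.25 = 6 h).
#' @param bbb_pars a [bbb_params()].
#' @param disease RRMS flag (accelerated barrier decline).
#' @return list with updated `state` ([immune_state()]), `bbb`
#'   ([bbb_state()]) and the number of `crossings` during the step.
#' @export
step_immune <- function(state, patient, bbb, effects = list(),
                        params = disease_params(), rng, dt = 0.25,
                        bbb_pars = bbb_params(), disease = TRUE) {
  if (!inherits(state, "immune_state")) stop_bbbms("state must be an immune_state")
  if (missing(rng) || !is_rng_stream(rng)) {
    stop_bbbms("rng must be a seeded rng_stream")
  }
  req <- c("antigen_rate_multiplier", "activation_prob",
           "adhesion_upregulation", "effector_burst_scale")
  if (!all(req %in% names(patient))) {
    stop_bbbms("patient is missing parameters: ",
               paste(setdiff(req, names(patient)), collapse = ", "))
  }
  check_number(dt, "dt", lower = 1e-9)
  validate_bbb_state(bbb)

  eff <- combine_effects(effects)
  u_cap <- bbb$repair_capital + eff$bbb_repair_input * dt
  ctx <- list(
    dc_mult = eff$dc_activation_mult, prolif_mult = eff$lymphocyte_prolif_mult,
    block = eff$infiltration_block, bcell_dep = eff$bcell_depletion_frac,
    lymph_dep = eff$lymphodepletion_frac,
    theta = leak_tightening(bbb_pars, u_cap),
    f_atten = force_attenuation(bbb_pars, u_cap),
    setpoint = tjp_setpoint(bbb_pars, u_cap),
    rexp = eff$bbb_repair_input * dt,
    k_day = bbb_pars$healthy_decline_rate / 365 *
      if (disease) bbb_pars$disease_decline_multiplier else 1
  )
  u <- matrix(rng$unif(4), 1, 4)
  traits <- list(
    antigen_rate_multiplier = patient$antigen_rate_multiplier,
    activation_prob = patient$activation_prob,
    adhesion_upregulation = patient$adhesion_upregulation,
    effector_burst_scale = patient$effector_burst_scale
  )
  res <- immune_kernel(state, list(tjp = bbb$tjp_level, damage = bbb$damage),
                       u, traits, ctx, params, bbb_pars, dt)
  out_bbb <- bbb
  out_bbb$tjp_level <- res$bbb$tjp
  out_bbb$damage <- res$bbb$damage
  out_bbb$repair_capital <- u_cap
  list(state = res$immune, bbb = out_bbb, crossings = res$crossings)
}
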