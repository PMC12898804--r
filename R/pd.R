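#' Pharmacodynamic parameters of NX210c barrier repair
#'
#' Sigmoidal Emax coupling of NX210c concentration onto barrier repair, plus
#' the gains of the in vitro monolayer mode (claudin-5, TEER and dextran
#' permeability fold-changes versus vehicle). Concentrations are in mg/L; for
#' a ~1 kDa peptide 1 mg/L is ~1 uM, so the in vitro micromolar levels are
#' used on the same scale.
#'
#' @param ec50 concentration of half-maximal repair (mg/L ~ uM).
#' @param emax_repair maximal repair input per unit time (dimensionless).
#' @param hill Hill coefficient (>= 1).
#' @param invitro_cl5_gain,invitro_teer_gain,invitro_perm_gain maximal
#'   fractional fold-change amplitudes of the in vitro readouts.
#' @param invitro_tau_hours time constant of in vitro response build-up.
#' @return object of class `pd_params`.
#' @export
pd_params <- function(ec50 = 5, emax_repair = 1, hill = 1,
                      invitro_cl5_gain = 0.8, invitro_teer_gain = 0.5,
                      invitro_perm_gain = 0.7, invitro_tau_hours = 36) {
  check_number(ec50, "ec50", lower = 1e-12)
  check_number(emax_repair, "emax_repair", lower = 0)
  check_number(hill, "hill", lower = 1)
  p <- as.list(environment())
  class(p) <- "pd_params"
  p
}

#' NX210c concentration-to-repair coupling
#'
#' `effect = emax_repair * C^h / (C^h + ec50^h)`: sigmoidal, zero at zero
#' concentration, half-maximal at `ec50`, monotone non-decreasing.
#'
#' @param concentration NX210c concentration (mg/L), >= 0 (vectorised).
#' @param params a [pd_params()].
#' @return repair input in `[0, emax_repair]`.
#' @export
nx210c_effect <- function(concentration, params = pd_params()) {
  if (!is.numeric(concentration) || any(is.na(concentration)) ||
      any(concentration < 0)) {
    stop_bbbms("concentration must be non-negative")
  }
  ch <- concentration^params$hill
  params$emax_repair * ch / (ch + params$ec50^params$hill)
}

#' Daily repair exposure of a regimen
#'
#' Integrates the Emax-transformed NX210c concentration over each dosing day
#' (fine within-day PK grid, summarised to the disease-model step as an
#' exposure in effect-days). With the default elimination half-life the
#' trough is negligible after 24 h, so days are independent and the per-dose
#' exposure is computed once.
#'
#' @param regimen a [dose_regimen()].
#' @param pk a [pk_params()].
#' @param pd a [pd_params()].
#' @param horizon_days length of the returned daily vector.
#' @return numeric vector `horizon_days` long: repair exposure accrued on
#'   each day (0 on non-dosing days).
#' @export
repair_schedule <- function(regimen, pk = pk_params(), pd = pd_params(),
                            horizon_days = 365) {
  check_number(horizon_days, "horizon_days", lower = 1)
  out <- numeric(horizon_days)
  if (regimen$dose == 0) return(out)
  single <- dose_regimen(regimen$compound, regimen$dose,
                         regimen$infusion_duration, cycle_length_weeks = 0)
  pk_day <- simulate_pk(single, pk, grid_min = seq(0, 1440, by = 1))
  eff <- nx210c_effect(pk_day$conc_nx210c, pd)
  per_dose <- trapz(pk_day$time_min / 1440, eff) # effect-days per dose
  dd <- dosing_days(regimen) + 1L
  dd <- dd[dd <= horizon_days]
  out[dd] <- per_dose
  out
}

#' In vitro BMEC monolayer response to NX210c
#'
#' Emulates the mechanism-of-action validation experiment: a mouse brain
#' microvascular endothelial monolayer bathed in NX210c (nominally 0, 1, 10
#' or 100 uM) for 4 h to 5 days, read out as fold-changes versus vehicle of
#' claudin-5 expression, TEER and dextran permeability. The bath
#' concentration is held constant (no pharmacokinetics), and the response
#' builds with first-order kinetics toward its concentration-dependent
#' plateau.
#'
#' @param concentration_um bath concentration in uM (>= 0; vehicle = 0).
#' @param duration_hours exposure duration in `[4, 120]` hours.
#' @param params a [pd_params()].
#' @return list with `claudin5_foldchange`, `teer_foldchange`,
#'   `permeability_foldchange` (all 1 for vehicle).
#' @export
#' @examples
#' simulate_invitro(100, 120) # 5-day high-concentration exposure
simulate_invitro <- function(concentration_um, duration_hours,
                             params = pd_params()) {
  check_number(concentration_um, "concentration_um", lower = 0)
  check_number(duration_hours, "duration_hours")
  if (any(duration_hours < 4) || any(duration_hours > 120)) {
    stop_bbbms("duration_hours outside the supported 4 h to 5 day window")
  }
  fe <- nx210c_effect(concentration_um, params) / params$emax_repair
  g <- 1 - exp(-duration_hours / params$invitro_tau_hours)
  list(
    claudin5_foldchange = 1 + params$invitro_cl5_gain * fe * g,
    teer_foldchange = 1 + params$invitro_teer_gain * fe * g,
    permeability_foldchange = 1 / (1 + params$invitro_perm_gain * fe * g)
  )
}

# --- standard-of-care treatment handles -------------------------------------

soc_drugs <- c("interferon_b1a", "teriflunomide", "natalizumab",
               "ocrelizumab", "cladribine", "nx210c")

#' Treatment effect handle
#'
#' Named multipliers a treatment applies to the immune/BBB parameters at a
#' point in time. Suppressive multipliers lie in `[0, 1]` (1 = no effect);
#' depletion fractions are applied at dosing events and their persistence is
#' carried by the depleted cell pools themselves.
#'
#' @param drug one of interferon_b1a, teriflunomide, natalizumab, ocrelizumab,
#'   cladribine, nx210c.
#' @param dc_activation_mult multiplier on antigen-presentation-driven
#'   activation (interferon beta-1a).
#' @param lymphocyte_prolif_mult multiplier on effector expansion
#'   (teriflunomide).
#' @param infiltration_block fraction of CNS crossings blocked (natalizumab).
#' @param bcell_depletion_frac fraction of B cells removed at a dosing event
#'   (ocrelizumab).
#' @param lymphodepletion_frac fraction of lymphocytes removed per dosing day
#'   (cladribine).
#' @param bbb_repair_input repair exposure per day (NX210c).
#' @param active whether the handle is active at the queried time.
#' @return object of class `treatment_effect`.
#' @export
treatment_effect <- function(drug, dc_activation_mult = 1,
                             lymphocyte_prolif_mult = 1,
                             infiltration_block = 0,
                             bcell_depletion_frac = 0,
                             lymphodepletion_frac = 0,
                             bbb_repair_input = 0,
                             active = TRUE) {
  if (!drug %in% soc_drugs) stop_bbbms("unknown drug '", drug, "'")
  check_fraction(dc_activation_mult, "dc_activation_mult")
  check_fraction(lymphocyte_prolif_mult, "lymphocyte_prolif_mult")
  check_fraction(infiltration_block, "infiltration_block")
  check_fraction(bcell_depletion_frac, "bcell_depletion_frac")
  check_fraction(lymphodepletion_frac, "lymphodepletion_frac")
  check_number(bbb_repair_input, "bbb_repair_input", lower = 0)
  e <- as.list(environment())
  class(e) <- "treatment_effect"
  e
}

identity_effect <- function(drug) treatment_effect(drug, active = FALSE)

#' Registered standard-of-care regimens
#'
#' Fixed published dosing schedules: interferon beta-1a 22 mcg SC three times
#' weekly; teriflunomide 14 mg orally once daily; natalizumab 300 mg IV every
#' 4 weeks; ocrelizumab 600 mg IV every 6 months; cladribine 3.5 mg/kg orally
#' over 2 years, dosed on the first 5 days of months 1, 2, 13 and 14.
#'
#' @param drug standard-of-care drug name.
#' @param horizon_days treatment/observation horizon.
#' @return list describing the schedule (`dose_days`, `effect_window_days`,
#'   label and dose).
#' @export
soc_regimen <- function(drug, horizon_days = 730) {
  switch(drug,
    interferon_b1a = list(
      drug = drug, label = "interferon beta-1a 22 mcg SC tiw",
      dose_days = as.vector(outer(c(0, 2, 4), seq(0, horizon_days, 7), `+`)),
      effect_window_days = 3.5
    ),
    teriflunomide = list(
      drug = drug, label = "teriflunomide 14 mg od",
      dose_days = seq(0, horizon_days), effect_window_days = 1.5
    ),
    natalizumab = list(
      drug = drug, label = "natalizumab 300 mg IV q4w",
      dose_days = seq(0, horizon_days, 28), effect_window_days = 28
    ),
    ocrelizumab = list(
      drug = drug, label = "ocrelizumab 600 mg IV q6m",
      dose_days = seq(0, horizon_days, 183), effect_window_days = 183
    ),
    cladribine = list(
      drug = drug, label = "cladribine 3.5 mg/kg oral, months 1/2/13/14",
      dose_days = as.vector(outer(0:4, c(0, 30, 365, 395), `+`)),
      effect_window_days = 1
    ),
    stop_bbbms("unknown drug '", drug, "'")
  )
}

#' Effect magnitudes of the standard-of-care drugs
#'
#' Free calibration parameters of the treatment layer, constrained by the
#' relative efficacy hierarchy of the five drugs on 2-year relapse counts in
#' the highly active population.
#'
#' @param ifn_dc_mult,teri_prolif_mult suppressive multipliers.
#' @param natalizumab_block blocked fraction of CNS crossings.
#' @param ocrelizumab_depletion B-cell fraction removed per infusion.
#' @param cladribine_daily_depletion lymphocyte fraction removed per dosing day.
#' @return list of magnitudes.
#' @export
soc_params <- function(ifn_dc_mult = 0.5, teri_prolif_mult = 0.65,
                       natalizumab_block = 0.9, ocrelizumab_depletion = 0.95,
                       cladribine_daily_depletion = 0.07) {
  as.list(environment())
}

#' Treatment effect of a standard-of-care drug at a time point
#'
#' Returns the drug's parameter multipliers active at `t_days`, honouring the
#' registered schedule and effect persistence: window-driven suppression for
#' interferon/teriflunomide/natalizumab, and dosing-event depletions for
#' ocrelizumab/cladribine whose persistence (across the 6-month interval, or
#' between the year-1 and year-2 courses) is carried by the slowly
#' reconstituting cell pools in the immune layer.
#'
#' @param drug standard-of-care drug name.
#' @param regimen schedule from [soc_regimen()] (defaults to the registered
#'   one).
#' @param t_days time since treatment start, days.
#' @param magnitudes a [soc_params()] list.
#' @return a [treatment_effect()].
#' @export
#' @examples
#' soc_effect("natalizumab", t_days = 10) # within the 4-week window
soc_effect <- function(drug, regimen = NULL, t_days = 0,
                       magnitudes = soc_params()) {
  if (!drug %in% setdiff(soc_drugs, "nx210c")) {
    stop_bbbms("unknown drug '", drug, "'")
  }
  regimen <- regimen %||% soc_regimen(drug)
  check_number(t_days, "t_days", lower = 0)
  in_window <- any(t_days >= regimen$dose_days &
                     t_days < regimen$dose_days + regimen$effect_window_days)
  if (!in_window && !drug %in% c("ocrelizumab", "cladribine")) {
    return(identity_effect(drug))
  }
  on_dose_day <- any(floor(t_days) == floor(regimen$dose_days))
  switch(drug,
    interferon_b1a = treatment_effect(drug,
      dc_activation_mult = magnitudes$ifn_dc_mult),
    teriflunomide = treatment_effect(drug,
      lymphocyte_prolif_mult = magnitudes$teri_prolif_mult),
    natalizumab = treatment_effect(drug,
      infiltration_block = magnitudes$natalizumab_block),
    ocrelizumab = if (on_dose_day) {
      treatment_effect(drug, bcell_depletion_frac = magnitudes$ocrelizumab_depletion)
    } else identity_effect(drug),
    cladribine = if (on_dose_day) {
      treatment_effect(drug, lymphodepletion_frac = magnitudes$cladribine_daily_depletion)
    } else identity_effect(drug)
  )
}

#' Compose simultaneous treatment effects
#'
#' Multiplies suppressive multipliers, combines infiltration blocks as
#' independent filters (`1 - prod(1 - block_i)`), and adds repair inputs.
#' Composition is commutative and has the identity effect as neutral element,
#' so combination arms apply each mechanism exactly once.
#'
#' @param effects list of [treatment_effect()]s.
#' @return a single combined `treatment_effect` (drug label `"nx210c"` is
#'   kept only if present).
#' @export
combine_effects <- function(effects) {
  if (length(effects) == 0L) return(identity_effect("nx210c"))
  out <- treatment_effect(effects[[1]]$drug)
  for (e in effects) {
    stopifnot(inherits(e, "treatment_effect"))
    out$dc_activation_mult <- out$dc_activation_mult * e$dc_activation_mult
    out$lymphocyte_prolif_mult <- out$lymphocyte_prolif_mult * e$lymphocyte_prolif_mult
    out$infiltration_block <- 1 - (1 - out$infiltration_block) * (1 - e$infiltration_block)
    out$bcell_depletion_frac <- 1 - (1 - out$bcell_depletion_frac) * (1 - e$bcell_depletion_frac)
    out$lymphodepletion_frac <- 1 - (1 - out$lymphodepletion_frac) * (1 - e$lymphodepletion_frac)
    out$bbb_repair_input <- out$bbb_repair_input + e$bbb_repair_input
  }
  out
}
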