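#' Detect and classify relapses in an oligodendrocyte trajectory
#'
#' A relapse event opens when the ODC count falls below
#' `baseline * (1 - subclinical_threshold_frac)` and closes when it recovers
#' above that level; each excursion is one event. An event is clinical when
#' its nadir falls below `baseline * (1 - clinical_threshold_frac)` (42,500
#' cells/uL at the defaults), otherwise subclinical.
#'
#' @param odc numeric ODC series (cells/uL), starting at baseline.
#' @param time_days time stamps (defaults to `0:(length(odc)-1)`).
#' @param baseline ODC baseline, cells/uL (> 0).
#' @param subclinical_threshold_frac minimal detectable fractional dip
#'   (< `clinical_threshold_frac`).
#' @param clinical_threshold_frac clinical relapse threshold (default 0.15).
#' @return data.frame with columns `onset`, `nadir_time`, `nadir_odc`,
#'   `classification` (`"clinical"`/`"subclinical"`); zero rows if no event.
#' @export
#' @examples
#' odc <- c(50000, 48000, 44000, 41000, 45000, 49000, 50000)
#' detect_relapses(odc) # one clinical event
detect_relapses <- function(odc, time_days = seq_along(odc) - 1,
                            baseline = 50000,
                            subclinical_threshold_frac = 0.05,
                            clinical_threshold_frac = 0.15) {
  check_number(baseline, "baseline", lower = 1e-9)
  check_number(odc, "odc", lower = 0)
  if (subclinical_threshold_frac >= clinical_threshold_frac) {
    stop_bbbms("subclinical_threshold_frac must be below the clinical threshold")
  }
  if (length(time_days) != length(odc)) stop_bbbms("time/odc length mismatch")
  thr_open <- baseline * (1 - subclinical_threshold_frac)
  thr_clin <- baseline * (1 - clinical_threshold_frac)
  below <- odc < thr_open
  if (!any(below)) {
    return(data.frame(onset = numeric(0), nadir_time = numeric(0),
                      nadir_odc = numeric(0), classification = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  ev <- lapply(idx, function(k) {
    seg <- starts[k]:ends[k]
    nadir <- seg[which.min(odc[seg])]
    data.frame(
      onset = time_days[starts[k]], nadir_time = time_days[nadir],
      nadir_odc = odc[nadir],
      classification = if (odc[nadir] < thr_clin) "clinical" else "subclinical",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, ev)
}

# ---------------------------------------------------------------------------
# internal: per-arm engine

# treatment context vectors over the step grid for one arm
arm_context <- function(n_steps, dt, horizon_days, nx_regimen, soc_drug,
                        disease, pkp, pdp, bp, socp) {
  steps_per_day <- round(1 / dt)
  day_of_step <- floor((seq_len(n_steps) - 1) * dt) + 1L

  repair_daily <- if (!is.null(nx_regimen)) {
    repair_schedule(nx_regimen, pkp, pdp, horizon_days)
  } else numeric(horizon_days)
  rexp <- repair_daily[day_of_step] * dt
  u_cap <- cumsum(rexp)

  dc_mult <- rep(1, n_steps); prolif_mult <- rep(1, n_steps)
  block <- rep(0, n_steps); bcell_dep <- rep(0, n_steps)
  lymph_dep <- rep(0, n_steps)
  if (!is.null(soc_drug)) {
    reg <- soc_regimen(soc_drug, horizon_days)
    days <- seq_len(horizon_days) - 1L
    eff_day <- lapply(days, function(d) soc_effect(soc_drug, reg, d, socp))
    first_step_of_day <- (seq_len(n_steps) - 1) %% steps_per_day == 0
    for (d in seq_len(horizon_days)) {
      e <- eff_day[[d]]
      sel <- day_of_step == d
      dc_mult[sel] <- e$dc_activation_mult
      prolif_mult[sel] <- e$lymphocyte_prolif_mult
      block[sel] <- e$infiltration_block
      if (e$bcell_depletion_frac > 0 || e$lymphodepletion_frac > 0) {
        sel1 <- sel & first_step_of_day
        bcell_dep[sel1] <- e$bcell_depletion_frac
        lymph_dep[sel1] <- e$lymphodepletion_frac
      }
    }
  }
  list(
    dc_mult = dc_mult, prolif_mult = prolif_mult, block = block,
    bcell_dep = bcell_dep, lymph_dep = lymph_dep, rexp = rexp,
    theta = leak_tightening(bp, u_cap),
    f_atten = force_attenuation(bp, u_cap),
    setpoint = tjp_setpoint(bp, u_cap),
    u_cap = u_cap,
    k_day = bp$healthy_decline_rate / 365 *
      if (disease) bp$disease_decline_multiplier else 1
  )
}

# pre-draw the per-patient uniform streams (4 per step, row-major per step so
# the vectorised engine consumes randomness in the same order as step_immune)
draw_streams <- function(pop, n_steps) {
  n <- nrow(pop)
  U <- array(NA_real_, c(n_steps, 4L, n))
  for (i in seq_len(n)) {
    set.seed(patient_seed(pop$seed[i], 1L, offset = 1L))
    U[, , i] <- matrix(stats::runif(4L * n_steps), ncol = 4L, byrow = TRUE)
  }
  U
}

run_immune_arm <- function(pop, horizon_days, dt, dp, bp, pkp, pdp, socp,
                           nx_regimen = NULL, soc_drug = NULL, disease = TRUE,
                           keep_series = FALSE, force_perm_rel = NULL) {
  n <- nrow(pop)
  n_steps <- as.integer(round(horizon_days / dt))
  ctx_all <- arm_context(n_steps, dt, horizon_days, nx_regimen, soc_drug,
                         disease, pkp, pdp, bp, socp)
  U <- draw_streams(pop, n_steps)

  st <- immune_state(n, dp)
  bbb <- list(tjp = pop$baseline_bbb_integrity, damage = rep(0, n))
  traits <- list(
    antigen_rate_multiplier = pop$antigen_rate_multiplier,
    activation_prob = pop$activation_prob,
    adhesion_upregulation = pop$adhesion_upregulation,
    effector_burst_scale = pop$effector_burst_scale
  )
  bp_run <- bp
  if (!is.null(force_perm_rel)) {
    # diagnostic mode: pin the leak-driven permeability at a fixed relative
    # level (e.g. 1 = healthy baseline) while leaving everything else intact
    bp_run$perm_exponent <- 0
    bp_run$perm_damage_weight <- 0
  }

  odc_mat <- matrix(NA_real_, n_steps + 1L, n)
  odc_mat[1L, ] <- st$odc
  series <- if (keep_series) {
    list(cns_infiltrate = odc_mat, th1 = odc_mat, th17 = odc_mat,
         treg = odc_mat, b_cells = odc_mat)
  } else NULL
  if (keep_series) {
    series$cns_infiltrate[1L, ] <- 0
    series$th1[1L, ] <- st$th1; series$th17[1L, ] <- st$th17
    series$treg[1L, ] <- st$treg; series$b_cells[1L, ] <- st$b_cells
  }
  total_crossings <- rep(0, n)

  for (j in seq_len(n_steps)) {
    ctx <- list(
      dc_mult = ctx_all$dc_mult[j], prolif_mult = ctx_all$prolif_mult[j],
      block = ctx_all$block[j], bcell_dep = ctx_all$bcell_dep[j],
      lymph_dep = ctx_all$lymph_dep[j], rexp = ctx_all$rexp[j],
      theta = ctx_all$theta[j], f_atten = ctx_all$f_atten[j],
      setpoint = ctx_all$setpoint[j], k_day = ctx_all$k_day
    )
    res <- immune_kernel(st, bbb, t(matrix(U[j, , ], nrow = 4L)), traits,
                         ctx, dp, bp_run, dt)
    st <- res$immune
    bbb <- res$bbb
    total_crossings <- total_crossings + res$crossings
    odc_mat[j + 1L, ] <- st$odc
    if (keep_series) {
      series$cns_infiltrate[j + 1L, ] <- st$cns_infiltrate
      series$th1[j + 1L, ] <- st$th1; series$th17[j + 1L, ] <- st$th17
      series$treg[j + 1L, ] <- st$treg; series$b_cells[j + 1L, ] <- st$b_cells
    }
  }
  u_final <- if (n_steps > 0) ctx_all$u_cap[n_steps] else 0
  teer_final <- bp$teer_floor + (bp$teer_baseline - bp$teer_floor) *
    bbb$tjp^bp$teer_alpha
  list(
    time_days = seq(0, n_steps) * dt, odc = odc_mat, series = series,
    tjp_final = bbb$tjp, teer_final = teer_final, damage_final = bbb$damage,
    repair_capital = u_final, total_crossings = total_crossings,
    min_tjp = bbb$tjp # tjp declines monotonically between repair pulses
  )
}

# dose_regimen from an arm spec entry
arm_nx_regimen <- function(arm, horizon_days) {
  if (is.null(arm$nx)) return(NULL)
  if (inherits(arm$nx, "dose_regimen")) return(arm$nx)
  n_cycles <- arm$nx_n_cycles %||% max(1, floor(horizon_days / 183) + 1)
  regimen_preset(arm$nx, n_cycles = n_cycles)
}

#' Run an in silico trial scenario
#'
#' Simulates every arm of a scenario on the same per-profile patient roster
#' (paired design: patient attributes and event-level randomness are reused
#' across arms, so arm contrasts are free of roster noise). Two modes:
#' `"bbb"` runs the barrier module alone at daily resolution (long-horizon
#' marker scenarios), `"full"` runs the coupled immune/disease layer at 6-h
#' resolution and detects relapses.
#'
#' @param config scenario configuration list (see [validate_scenario()] and
#'   [scenario_preset()]).
#' @param master_seed optional override of `config$master_seed`.
#' @return object of class `ms_trial`: per-arm results (`events`, per-patient
#'   `counts`, `tjp_final`, `teer_final`, ...) plus the config.
#' @export
#' @examples
#' \donttest{
#' tr <- run_scenario(scenario_preset("fig6", n_patients = 10))
#' summary(tr)
#' }
run_scenario <- function(config, master_seed = NULL) {
  config <- validate_scenario(config)
  if (!is.null(master_seed)) config$master_seed <- master_seed
  dp <- config$disease_params %||% disease_params()
  bp <- config$bbb_params %||% bbb_params()
  pkp <- config$pk_params %||% pk_params()
  pdp <- config$pd_params %||% pd_params()
  socp <- config$soc_params %||% soc_params()
  horizon_days <- round(config$horizon_years * 365)

  profiles <- unique(vapply(config$arms, `[[`, "", "profile"))
  pops <- stats::setNames(lapply(profiles, function(p) {
    generate_population(config$n_patients, p, config$master_seed,
                        age = config$age_start)
  }), profiles)

  arms <- list()
  for (arm in config$arms) {
    pop <- pops[[arm$profile]]
    disease <- arm$profile != "healthy"
    nx <- arm_nx_regimen(arm, horizon_days)
    if (config$mode == "bbb") {
      repair_daily <- if (!is.null(nx)) {
        repair_schedule(nx, pkp, pdp, horizon_days)
      } else NULL
      sim <- simulate_bbb_cohort(pop$baseline_bbb_integrity, bp,
                                 years = config$horizon_years,
                                 disease = disease,
                                 repair_daily = repair_daily,
                                 dt_days = config$dt_days)
      res <- list(
        name = arm$name, profile = arm$profile,
        tjp_final = sim$tjp_final, teer_final = sim$teer_final,
        time_days = sim$time_days,
        tjp_mean_series = rowMeans(sim$tjp),
        events = NULL, counts = NULL
      )
    } else {
      sim <- run_immune_arm(pop, horizon_days, config$dt_days, dp, bp, pkp,
                            pdp, socp, nx_regimen = nx,
                            soc_drug = arm$soc, disease = disease,
                            keep_series = isTRUE(config$keep_series),
                            force_perm_rel = if (isTRUE(arm$force_healthy_perm)) 1 else NULL)
      ev <- lapply(seq_len(nrow(pop)), function(i) {
        e <- detect_relapses(sim$odc[, i], sim$time_days,
                             baseline = dp$odc_baseline,
                             subclinical_threshold_frac =
                               config$subclinical_threshold_frac)
        if (nrow(e) > 0) e$patient <- pop$id[i] else e$patient <- character(0)
        e
      })
      events <- do.call(rbind, ev)
      counts <- data.frame(
        patient = pop$id,
        clinical = vapply(ev, function(e) sum(e$classification == "clinical"), 0),
        subclinical = vapply(ev, function(e) sum(e$classification == "subclinical"), 0)
      )
      counts$total <- counts$clinical + counts$subclinical
      res <- list(
        name = arm$name, profile = arm$profile, events = events,
        counts = counts,
        mean_clinical = mean(counts$clinical),
        sd_clinical = stats::sd(counts$clinical),
        mean_subclinical = mean(counts$subclinical),
        mean_total = mean(counts$total),
        sd_total = stats::sd(counts$total),
        tjp_final = sim$tjp_final, teer_final = sim$teer_final,
        min_tjp = sim$min_tjp, total_crossings = sim$total_crossings,
        time_days = sim$time_days,
        odc = if (isTRUE(config$keep_series) || isTRUE(config$keep_odc)) sim$odc else NULL,
        series = sim$series
      )
    }
    arms[[arm$name]] <- res
  }
  out <- list(config = config, arms = arms, populations = pops)
  class(out) <- "ms_trial"
  out
}

#' BBB marker endpoint: percent difference between two arms
#'
#' Signed percent difference, population-averaged, of the final tight
#' junction protein level and TEER of an arm versus a comparator arm on the
#' same time grid.
#'
#' @param arm,comparator arm results from a [run_scenario()] trial (elements
#'   of `trial$arms`).
#' @return named vector `c(tjp_pct, teer_pct)`; positive when the arm ends
#'   higher than the comparator.
#' @export
bbb_endpoint <- function(arm, comparator) {
  if (!identical(length(arm$time_days), length(comparator$time_days)) ||
      !isTRUE(all.equal(arm$time_days, comparator$time_days))) {
    stop_bbbms("arm time grids are misaligned")
  }
  c(
    tjp_pct = 100 * (mean(arm$tjp_final) - mean(comparator$tjp_final)) /
      mean(comparator$tjp_final),
    teer_pct = 100 * (mean(arm$teer_final) - mean(comparator$teer_final)) /
      mean(comparator$teer_final)
  )
}

#' Oligodendrocyte trajectory of a single virtual patient
#'
#' Runs the disease layer for one patient and returns the ODC time series
#' (deterministic for a fixed patient seed and configuration).
#'
#' @param patient a [generate_patient()] result.
#' @param horizon_years simulation horizon (> 0).
#' @param nx_regimen optional NX210c [dose_regimen()].
#' @param soc_drug optional standard-of-care drug name.
#' @param dt_days step (default 0.25 = 6 h).
#' @param disease_pars,bbb_pars,pk_pars,pd_pars,soc_pars parameter objects.
#' @return data.frame with `time_days`, `odc`, `cns_infiltrate`, `th1`,
#'   `th17`, `treg`, `b_cells`.
#' @export
odc_trajectory <- function(patient, horizon_years = 2, nx_regimen = NULL,
                           soc_drug = NULL, dt_days = 0.25,
                           disease_pars = disease_params(),
                           bbb_pars = bbb_params(),
                           pk_pars = pk_params(), pd_pars = pd_params(),
                           soc_pars = soc_params()) {
  check_number(horizon_years, "horizon_years", lower = 1e-9)
  pop <- data.frame(
    id = patient$id %||% "pt_1", seed = patient$seed,
    baseline_bbb_integrity = patient$baseline_bbb_integrity,
    antigen_rate_multiplier = patient$antigen_rate_multiplier,
    activation_prob = patient$activation_prob,
    adhesion_upregulation = patient$adhesion_upregulation,
    effector_burst_scale = patient$effector_burst_scale
  )
  sim <- run_immune_arm(pop, round(horizon_years * 365), dt_days,
                        disease_pars, bbb_pars, pk_pars, pd_pars, soc_pars,
                        nx_regimen = nx_regimen, soc_drug = soc_drug,
                        disease = patient$profile %||% "rrms_default" != "healthy",
                        keep_series = TRUE)
  data.frame(
    time_days = sim$time_days, odc = sim$odc[, 1],
    cns_infiltrate = sim$series$cns_infiltrate[, 1],
    th1 = sim$series$th1[, 1], th17 = sim$series$th17[, 1],
    treg = sim$series$treg[, 1], b_cells = sim$series$b_cells[, 1]
  )
}

#' @export
print.ms_trial <- function(x, ...) {
  cat(sprintf("In silico trial '%s': %d arm(s), %d patients/arm, %.3g years\n",
              x$config$name, length(x$arms), x$config$n_patients,
              x$config$horizon_years))
  print(summary(x))
  invisible(x)
}

#' @export
summary.ms_trial <- function(object, ...) {
  ref <- object$arms[[1]]
  rows <- lapply(object$arms, function(a) {
    bb <- bbb_endpoint(a, ref)
    data.frame(
      arm = a$name, profile = a$profile,
      mean_clinical = a$mean_clinical %||% NA_real_,
      mean_subclinical = a$mean_subclinical %||% NA_real_,
      mean_total = a$mean_total %||% NA_real_,
      sd_total = a$sd_total %||% NA_real_,
      tjp_pct_vs_ref = unname(bb["tjp_pct"]),
      teer_pct_vs_ref = unname(bb["teer_pct"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write trial outputs to a directory
#'
#' `summary.json` (per-arm endpoints), `events.csv` (patient, onset, nadir,
#' classification) and optionally `series/<patient>.csv`.
#'
#' @param trial an `ms_trial`.
#' @param dir output directory (created if needed).
#' @param write_series write per-patient ODC series CSVs.
#' @export
write_trial_outputs <- function(trial, dir, write_series = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    summary(trial), file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  ev <- do.call(rbind, lapply(trial$arms, function(a) {
    if (is.null(a$events) || nrow(a$events) == 0) return(NULL)
    cbind(arm = a$name, a$events)
  }))
  if (!is.null(ev)) {
    utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  }
  if (write_series) {
    sdir <- file.path(dir, "series")
    dir.create(sdir, showWarnings = FALSE)
    for (a in trial$arms) {
      if (is.null(a$odc)) next
      for (i in seq_len(ncol(a$odc))) {
        utils::write.csv(
          data.frame(time_days = a$time_days, odc = a$odc[, i]),
          file.path(sdir, sprintf("%s_%s.csv", a$name, colnames(a$odc)[i] %||% i)),
          row.names = FALSE
        )
      }
    }
  }
  invisible(dir)
}
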