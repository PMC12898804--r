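#' Validate a scenario configuration
#'
#' Checks the scenario schema and fills defaults. A configuration is a list
#' with fields: `name`, `mode` ("bbb" or "full"), `n_patients`,
#' `horizon_years`, `dt_days`, `age_start` (optional), `master_seed`,
#' `subclinical_threshold_frac`, and `arms` — a list of
#' `list(name, profile, nx = <regimen preset or dose_regimen or NULL>,
#' nx_n_cycles, soc = <drug name or NULL>)`. All schema violations are
#' reported together.
#'
#' @param config scenario list.
#' @return the validated configuration with defaults filled.
#' @export
validate_scenario <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!is.list(config)) stop_bbbms("config must be a list")

  config$name <- config$name %||% "scenario"
  config$mode <- config$mode %||% "full"
  if (!config$mode %in% c("bbb", "full")) add("mode must be 'bbb' or 'full'")
  config$n_patients <- config$n_patients %||% 100
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    add("n_patients must be >= 1")
  }
  if (is.null(config$horizon_years) || !is.numeric(config$horizon_years) ||
      config$horizon_years <= 0) {
    add("horizon_years must be a positive number")
  }
  config$dt_days <- config$dt_days %||% if (config$mode == "bbb") 1 else 0.25
  if (!is.numeric(config$dt_days) || config$dt_days <= 0) {
    add("dt_days must be positive")
  }
  config$master_seed <- config$master_seed %||% 1L
  config$subclinical_threshold_frac <- config$subclinical_threshold_frac %||% 0.05
  if (config$subclinical_threshold_frac >= 0.15) {
    add("subclinical_threshold_frac must be below the 0.15 clinical threshold")
  }
  if (is.null(config$arms) || length(config$arms) == 0) {
    add("at least one arm is required")
  } else {
    for (i in seq_along(config$arms)) {
      a <- config$arms[[i]]
      if (is.null(a$name)) add(sprintf("arm %d: missing name", i))
      if (is.null(a$profile)) {
        add(sprintf("arm %d: missing profile", i))
      } else if (!a$profile %in% c("healthy", "rrms_default", "rrms_highly_active")) {
        add(sprintf("arm %d: unknown profile '%s'", i, a$profile))
      }
      if (!is.null(a$soc) &&
          !a$soc %in% c("interferon_b1a", "teriflunomide", "natalizumab",
                        "ocrelizumab", "cladribine")) {
        add(sprintf("arm %d: unknown soc drug '%s'", i, a$soc))
      }
      if (!is.null(a$nx) && !inherits(a$nx, "dose_regimen")) {
        ok <- tryCatch({ regimen_preset(a$nx); TRUE },
                       error = function(e) FALSE)
        if (!ok) add(sprintf("arm %d: unknown regimen preset '%s'", i, a$nx))
      }
    }
  }
  if (length(errs) > 0) {
    stop_bbbms("invalid scenario configuration:\n  - ",
               paste(errs, collapse = "\n  - "))
  }
  config
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_bbbms("config file not found: ", path)
  validate_scenario(yaml::read_yaml(path))
}

#' Reference scenario presets
#'
#' Named, seed-fixed configurations of the four reference simulation
#' studies:
#' \describe{
#'   \item{fig5}{BBB-only aging study: healthy and RRMS cohorts at age 40
#'     simulated untreated or with one 4-week NX210c cycle (5 or 10 mg/kg;
#'     plus a linear NX210 arm) and followed for 30 years at daily steps.}
#'   \item{fig6}{100 default-profile RRMS patients, 2 years, arms untreated
#'     vs one 4-week cycle at 5 and 10 mg/kg.}
#'   \item{fig7}{100 highly active RRMS patients, 10 years, untreated vs
#'     repeated 10 mg/kg cycles every 6 months.}
#'   \item{fig8}{100 highly active RRMS patients, 2 years: untreated, NX210c
#'     single and repeated cycles, the five standard-of-care drugs alone and
#'     each combined with repeated NX210c cycles.}
#' }
#'
#' @param name preset name.
#' @param n_patients cohort size per profile (default 100).
#' @param master_seed override of the preset's fixed seed.
#' @return scenario configuration list.
#' @export
scenario_preset <- function(name = c("fig5", "fig6", "fig7", "fig8"),
                            n_patients = 100, master_seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    fig5 = list(
      name = "fig5", mode = "bbb", horizon_years = 30, dt_days = 1,
      age_start = 40, master_seed = 105, n_patients = n_patients,
      arms = list(
        list(name = "healthy_untreated", profile = "healthy"),
        list(name = "healthy_nx210c_10", profile = "healthy",
             nx = "nx210c_10mgkg_cycle"),
        list(name = "rrms_untreated", profile = "rrms_default"),
        list(name = "rrms_nx210c_5", profile = "rrms_default",
             nx = "nx210c_5mgkg_cycle"),
        list(name = "rrms_nx210c_10", profile = "rrms_default",
             nx = "nx210c_10mgkg_cycle"),
        list(name = "rrms_nx210_10", profile = "rrms_default",
             nx = "nx210_10mgkg_cycle")
      )
    ),
    fig6 = list(
      name = "fig6", mode = "full", horizon_years = 2, dt_days = 0.25,
      master_seed = 106, n_patients = n_patients,
      arms = list(
        list(name = "untreated", profile = "rrms_default"),
        list(name = "nx210c_5", profile = "rrms_default",
             nx = "nx210c_5mgkg_cycle"),
        list(name = "nx210c_10", profile = "rrms_default",
             nx = "nx210c_10mgkg_cycle")
      )
    ),
    fig7 = list(
      name = "fig7", mode = "full", horizon_years = 10, dt_days = 0.25,
      master_seed = 107, n_patients = n_patients,
      arms = list(
        list(name = "untreated", profile = "rrms_highly_active"),
        list(name = "nx210c_10_repeat", profile = "rrms_highly_active",
             nx = "nx210c_10mgkg_repeat6mo", nx_n_cycles = 20)
      )
    ),
    fig8 = {
      soc <- c("interferon_b1a", "teriflunomide", "natalizumab",
               "ocrelizumab", "cladribine")
      arms <- c(
        list(
          list(name = "untreated", profile = "rrms_highly_active"),
          list(name = "nx210c_10_single", profile = "rrms_highly_active",
               nx = "nx210c_10mgkg_cycle"),
          list(name = "nx210c_10_repeat", profile = "rrms_highly_active",
               nx = "nx210c_10mgkg_repeat6mo", nx_n_cycles = 4)
        ),
        lapply(soc, function(d) {
          list(name = d, profile = "rrms_highly_active", soc = d)
        }),
        lapply(soc, function(d) {
          list(name = paste0(d, "_nx210c"), profile = "rrms_highly_active",
               soc = d, nx = "nx210c_10mgkg_repeat6mo", nx_n_cycles = 4)
        })
      )
      list(name = "fig8", mode = "full", horizon_years = 2, dt_days = 0.25,
           master_seed = 108, n_patients = n_patients, arms = arms)
    }
  )
  if (!is.null(master_seed)) cfg$master_seed <- master_seed
  validate_scenario(cfg)
}
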