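#' Virtual-patient population profiles
#'
#' Distributional definitions of the three cohort profiles. Heterogeneity
#' covers the immune repertoire (binary HLA strings per MHC-I locus A/B/C and
#' MHC-II locus DM/DO/DP/DQ/DR), thymic output, autoimmune activation
#' propensity, antigen-challenge frequency, baseline barrier integrity, and
#' two trafficking traits (adhesion upregulation and effector burst scale).
#' The highly active profile shifts activation propensity and antigen
#' frequency up and thymic efficiency down, and is dominated by
#' adhesion-driven (forced) CNS entry, which makes its relapses less limited
#' by passive barrier leak.
#'
#' @param profile `"healthy"`, `"rrms_default"` or `"rrms_highly_active"`.
#' @return list of distribution parameters.
#' @export
population_profile <- function(profile = c("rrms_default", "rrms_highly_active",
                                           "healthy")) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    age_range = c(18, 55), weight_mean = 70, weight_sd = 12,
    weight_range = c(50, 100), prop_female = 0.72,
    hla_bits_per_locus = 16,
    # thymus_efficiency ~ Beta, activation_prob ~ Beta (x HLA DQ/DR factor),
    # antigen_rate_multiplier ~ LogNormal, baseline_bbb ~ truncated Normal,
    # adhesion/burst ~ LogNormal
    thymus_shape = c(7, 3),
    activation_shape = c(6, 4),
    antigen_meanlog = -0.045, antigen_sdlog = 0.3,
    bbb_mean = 0.95, bbb_sd = 0.03, bbb_range = c(0.85, 1),
    adhesion_meanlog = log(1.05) - 0.35^2 / 2, adhesion_sdlog = 0.35,
    burst_meanlog = -0.25^2 / 2, burst_sdlog = 0.25
  )
  if (profile == "rrms_highly_active") {
    base$thymus_shape <- c(4.5, 5.5)
    base$activation_shape <- c(8, 2)
    base$antigen_meanlog <- log(1.5) - 0.045
    base$bbb_mean <- 0.93
    base$bbb_range <- c(0.8, 1)
    base$adhesion_meanlog <- log(4) - 0.3^2 / 2
    base$adhesion_sdlog <- 0.3
    base$burst_meanlog <- log(0.62) - 0.25^2 / 2
  }
  if (profile == "healthy") {
    base$bbb_mean <- 1
    base$bbb_sd <- 0
    base$bbb_range <- c(1, 1)
    base$adhesion_meanlog <- 0
    base$adhesion_sdlog <- 0
  }
  base
}

rtruncnorm1 <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' HLA-DQ/DR modulation of activation propensity
#'
#' Deterministic factor in `[0.85, 1.15]` computed from the bit content of
#' the DQ and DR locus strings, so that the MHC-II loci linked to disease
#' risk have a reproducible effect on autoimmune activation while the MHC-I
#' loci (A, B, C) do not enter disease dynamics.
#'
#' @param hla named list of locus bit vectors (needs `DQ`, `DR`).
#' @return scalar factor.
#' @export
hla_activation_factor <- function(hla) {
  bits <- c(hla$DQ, hla$DR)
  0.85 + 0.3 * mean(bits)
}

sample_hla <- function(bits_per_locus) {
  loci <- c("A", "B", "C", "DM", "DO", "DP", "DQ", "DR")
  stats::setNames(
    lapply(loci, function(l) stats::rbinom(bits_per_locus, 1, 0.5)), loci
  )
}

#' Generate one virtual patient
#'
#' Deterministic for a fixed `(profile, seed)` pair. Healthy subjects have
#' `antigen_rate_multiplier = 0` (no autoimmune triggering) and intact
#' baseline barrier integrity.
#'
#' @param profile cohort profile name (see [population_profile()]).
#' @param seed integer seed for this patient.
#' @param id patient identifier.
#' @param age optional fixed age in years (sampled if `NULL`).
#' @return object of class `virtual_patient` (a named list).
#' @export
#' @examples
#' generate_patient("rrms_default", seed = 42)
generate_patient <- function(profile, seed, id = "pt_1", age = NULL) {
  prof <- population_profile(profile)
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  hla <- sample_hla(prof$hla_bits_per_locus)
  act_raw <- stats::rbeta(1, prof$activation_shape[1], prof$activation_shape[2])
  pt <- list(
    id = id, profile = profile, seed = as.integer(seed),
    age = if (is.null(age)) round(stats::runif(1, prof$age_range[1], prof$age_range[2])) else age,
    sex = if (stats::runif(1) < prof$prop_female) "F" else "M",
    weight = rtruncnorm1(1, prof$weight_mean, prof$weight_sd, prof$weight_range),
    hla = hla,
    thymus_efficiency = stats::rbeta(1, prof$thymus_shape[1], prof$thymus_shape[2]),
    activation_prob = min(1, act_raw * hla_activation_factor(hla)),
    antigen_rate_multiplier = if (profile == "healthy") 0 else
      stats::rlnorm(1, prof$antigen_meanlog, prof$antigen_sdlog),
    baseline_bbb_integrity = rtruncnorm1(1, prof$bbb_mean, prof$bbb_sd, prof$bbb_range),
    adhesion_upregulation = stats::rlnorm(1, prof$adhesion_meanlog, prof$adhesion_sdlog),
    effector_burst_scale = stats::rlnorm(1, prof$burst_meanlog, prof$burst_sdlog)
  )
  if (pt$thymus_efficiency <= 0) pt$thymus_efficiency <- 1e-6
  class(pt) <- "virtual_patient"
  pt
}

#' Generate a virtual-patient population
#'
#' Per-patient seeds derive deterministically from the master seed (see
#' [patient_seed()]), so the roster is stable across runs and populations
#' generated from the same master seed with different `n` share a common
#' prefix of patients.
#'
#' @param n number of patients (>= 1).
#' @param profile cohort profile name.
#' @param master_seed integer master seed.
#' @param age optional fixed age for all patients.
#' @return object of class `virtual_population`: a data.frame with one row
#'   per patient (HLA strings encoded as e.g. `"0110..."`), carrying the
#'   patient list in attribute `"patients"`.
#' @export
generate_population <- function(n, profile, master_seed, age = NULL) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  seeds <- patient_seed(master_seed, seq_len(n))
  pts <- lapply(seq_len(n), function(i) {
    generate_patient(profile, seeds[i], id = sprintf("pt_%03d", i), age = age)
  })
  df <- do.call(rbind, lapply(pts, function(p) {
    data.frame(
      id = p$id, profile = p$profile, seed = p$seed, age = p$age, sex = p$sex,
      weight = p$weight,
      thymus_efficiency = p$thymus_efficiency,
      activation_prob = p$activation_prob,
      antigen_rate_multiplier = p$antigen_rate_multiplier,
      baseline_bbb_integrity = p$baseline_bbb_integrity,
      adhesion_upregulation = p$adhesion_upregulation,
      effector_burst_scale = p$effector_burst_scale,
      hla_dq = paste(p$hla$DQ, collapse = ""),
      hla_dr = paste(p$hla$DR, collapse = ""),
      stringsAsFactors = FALSE
    )
  }))
  attr(df, "patients") <- pts
  attr(df, "master_seed") <- master_seed
  class(df) <- c("virtual_population", "data.frame")
  df
}

#' @export
print.virtual_population <- function(x, ...) {
  cat(sprintf("Virtual population: %d patients, profile '%s'\n",
              nrow(x), x$profile[1]))
  cat(sprintf("  activation_prob median %.3f, antigen rate multiplier median %.3f\n",
              stats::median(x$activation_prob),
              stats::median(x$antigen_rate_multiplier)))
  invisible(x)
}

#' Export / import a population roster
#'
#' @param population a [generate_population()] result.
#' @param path CSV path.
#' @export
write_roster <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(hla_dq = "character", hla_dr = "character"))
  class(df) <- c("virtual_population", "data.frame")
  df
}
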