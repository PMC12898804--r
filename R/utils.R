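#' @keywords internal
"_PACKAGE"

# Scalar/vector validation helpers. All user-facing operations validate their
# inputs and raise classed errors ("bbbms_error") rather than silently
# clipping: an out-of-range state is a calibration bug we want surfaced.

stop_bbbms <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("bbbms_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0L)) {
    stop_bbbms(name, " must be numeric")
  }
  if (any(!is.finite(x))) stop_bbbms(name, " contains non-finite values")
  if (any(x < lower) || any(x > upper)) {
    stop_bbbms(name, " must lie in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_bbbms(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic per-patient substream seed
#'
#' Derives a 31-bit seed for patient `index` from a master seed. The mapping is
#' a fixed affine hash, so a roster generated from the same master seed shares
#' a common prefix when only `n` changes, and arm comparisons can replay the
#' same patient-level randomness (paired virtual-trial design).
#'
#' @param master_seed integer master seed.
#' @param index 1-based patient index (vectorised).
#' @param offset stream offset; distinct offsets give independent substreams
#'   (0 = patient attributes, 1 = within-simulation event stream).
#' @return integer vector of seeds in `[1, 2^31 - 2]`.
#' @export
patient_seed <- function(master_seed, index, offset = 0L) {
  check_number(master_seed, "master_seed")
  check_number(index, "index", lower = 1)
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  s <- (abs(master_seed) %% m + index * 1000003 + offset * 97711) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Seeded uniform random stream
#'
#' Small closure-based RNG stream used by [step_immune()]. Created from an
#' explicit seed; an unseeded stream cannot be constructed, which enforces the
#' determinism contract of the stochastic immune layer.
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream` with a `$unif(k)` member.
#' @export
rng_stream <- function(seed) {
  check_number(seed, "seed")
  env <- new.env(parent = emptyenv())
  local_seed <- as.integer(seed)
  env$unif <- function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    set.seed(local_seed)
    u <- stats::runif(k + env$used)
    env$used <- env$used + k
    u[seq.int(env$used - k + 1L, env$used)]
  }
  env$used <- 0L
  class(env) <- "rng_stream"
  env
}

is_rng_stream <- function(x) inherits(x, "rng_stream")

# trapezoidal integral; time strictly increasing enforced by callers
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
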