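# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting: child seeds for replicate/fold loops are a
#' pure function of the master seed and an index, kept below 2^31.
#' @keywords internal
#' @noRd
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483563 + 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Elementwise integer power of a correlation parameter
#'
#' `rho^D` for an integer-valued exponent matrix, safe at `rho = 0`
#' (0^0 = 1 by convention here).
#' @keywords internal
#' @noRd
pow_int <- function(rho, D) {
  if (abs(rho) < 1e-300) {
    out <- D
    out[] <- as.numeric(D == 0)
    return(out)
  }
  rho^D
}
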