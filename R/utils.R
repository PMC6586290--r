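# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows through named streams derived from a
#' single master seed, so that e.g. inner-loop EVPPI sampling is independent
#' across outer iterations yet fully reproducible. The derivation is a simple
#' polynomial string hash over the label parts, kept inside 32-bit integer
#' range.
#'
#' @param master Integer master seed.
#' @param ... Label parts (coerced to character) identifying the stream.
#' @return A positive integer seed suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "psa", 10)
derive_seed <- function(master, ...) {
  modulus <- 2147483629 # largest prime < 2^31, keeps seeds in integer range
  parts <- c(as.character(master), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 131 + ch) %% modulus
  }
  as.integer(h) + 1L
}

# Round half away from zero (base round() is banker's rounding); used only at
# reporting boundaries for population counts.
round_half_up <- function(x) floor(x + 0.5)

# Stop with a field-path-labelled message; used by evidence validation so a
# schema violation names the offending entry.
fail_field <- function(path, msg) {
  stop(sprintf("evidence schema violation at '%s': %s", path, msg),
       call. = FALSE)
}

# Beta shape parameters from mean and standard deviation (method of moments).
# Rejects infeasible (mean, sd) rather than clipping.
beta_from_moments <- function(mean, sd, path = "utility") {
  if (any(mean <= 0 | mean >= 1)) {
    fail_field(path, "beta mean must lie strictly inside (0, 1)")
  }
  if (any(sd <= 0)) fail_field(path, "beta sd must be positive")
  nu <- mean * (1 - mean) / sd^2 - 1
  if (any(nu <= 0)) {
    fail_field(path, "sd too large for a beta distribution with this mean")
  }
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

# Gamma shape/rate from mean and coefficient of variation.
gamma_from_mean_cv <- function(mean, cv, path = "resource") {
  if (any(mean < 0)) fail_field(path, "gamma mean must be non-negative")
  if (any(cv <= 0)) fail_field(path, "gamma cv must be positive")
  shape <- rep(1 / cv^2, length.out = length(mean))
  rate <- ifelse(mean > 0, shape / mean, Inf) # mean 0 -> degenerate at 0
  list(shape = shape, rate = rate)
}

# Dirichlet sampling via normalized gammas; alpha entries equal to zero give
# structural zeros (the standard counts-as-alphas construction).
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(0, n, k)
  pos <- alpha > 0
  g[, pos] <- matrix(
    rgamma(n * sum(pos), shape = rep(alpha[pos], each = n), rate = 1),
    n, sum(pos)
  )
  g / rowSums(g)
}
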