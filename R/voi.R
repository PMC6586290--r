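# Value of information: per-patient EVPI (single-loop) and grouped EVPPI
# (two-level nested Monte Carlo) with stepwise convergence escalation.
#
# The estimator cores (evpi_from_nmb, evppi_from_nmb) are pure functions of
# net-monetary-benefit arrays, so they can be run in exact/enumeration mode:
# feeding them the complete discrete support of a toy model (equal weights)
# makes the Monte Carlo estimator coincide with full enumeration.

#' EVPI from a net-monetary-benefit matrix
#'
#' `E_theta[max_j NMB_j] - max_j E_theta[NMB_j]`: the expected payoff of
#' deciding with perfect information minus the payoff of the best decision
#' under current information. Rows are parameter realizations (equally
#' weighted), columns are decision options.
#'
#' @param nmb Numeric matrix, draws x arms.
#' @return Per-patient EVPI, EUR (non-negative up to floating-point error).
#' @export
#' @examples
#' evpi_from_nmb(rbind(c(0, 10), c(0, -10))) # enumeration: 5
evpi_from_nmb <- function(nmb) {
  mean(do.call(pmax, asplit(nmb, 2))) - max(colMeans(nmb))
}

#' Grouped EVPPI from a nested net-monetary-benefit array
#'
#' Two-level estimator: for each outer realization `k` of the parameter
#' group of interest, the inner dimension `j` averages net benefit over the
#' remaining parameters; the value with partial perfect information is the
#' outer mean of the per-`k` best arm, and the baseline `max_j E[NMB]` is
#' taken from the pooled `K x J` evaluations, so the estimator is
#' self-consistent at small sizes. With `J = 1` the estimator reduces
#' algebraically to the single-loop EVPI on the `K` outer draws.
#'
#' @param nmb Numeric array, outer `K` x inner `J` x arms.
#' @return Per-patient EVPPI, EUR.
#' @export
evppi_from_nmb <- function(nmb) {
  stopifnot(length(dim(nmb)) == 3L)
  inner_means <- apply(nmb, c(1, 3), mean) # K x arms
  if (is.null(dim(inner_means))) inner_means <- matrix(inner_means, nrow = 1)
  term_perfect <- mean(do.call(pmax, asplit(inner_means, 2)))
  baseline <- max(apply(nmb, 3, mean))
  term_perfect - baseline
}

#' Per-patient EVPI from a probabilistic sensitivity analysis
#'
#' Single-loop estimator: the mean over PSA draws of the per-draw maximal
#' net monetary benefit, minus the maximal mean net monetary benefit.
#'
#' @param psa An `hfvoi_psa`.
#' @param lambda Willingness-to-pay threshold(s), EUR/QALY; vectorized.
#' @return Numeric vector of per-patient EVPI values (EUR), one per
#'   threshold.
#' @export
#' @examples
#' ev <- generate_evidence(seed = 1)
#' psa <- run_psa(ev, n_draws = 200, seed = 7)
#' evpi_per_patient(psa, 20000)
evpi_per_patient <- function(psa, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  vapply(lambda, function(l) evpi_from_nmb(nmb(psa, l)), numeric(1))
}

# One full two-level EVPPI evaluation. Returns per-k inner-mean incremental
# costs/effects and pooled means, from which the EVPPI at any threshold is
# an affine transformation -- a whole WTP grid costs one set of K x J model
# evaluations.
evppi_components <- function(evidence, group, J, K, seed,
                             settings = model_settings()) {
  stopifnot(J >= 1L, K >= 1L)
  group_label <- paste(group, collapse = "+")
  mE <- mC <- matrix(0, K, 3L)
  for (k in seq_len(K)) {
    outer_draw <- sample_draw(
      evidence, seed = derive_seed(seed, "evppi", group_label, k, "outer"))
    fixed <- extract_group(outer_draw, group)
    inner <- sample_conditional_draws(
      evidence, fixed, n = J,
      seed = derive_seed(seed, "evppi", group_label, k, "inner"))
    out <- outcomes_batch(inner, settings)
    mE[k, ] <- colMeans(out$effects - out$effects[, "UC"])
    mC[k, ] <- colMeans(out$costs - out$costs[, "UC"])
  }
  list(mE = mE, mC = mC, J = as.integer(J), K = as.integer(K))
}

# Evaluate the EVPPI estimator at thresholds `lambda` from stored
# components.
evppi_value <- function(comp, lambda) {
  vapply(lambda, function(l) {
    inner_nmb <- l * comp$mE - comp$mC # K x arms, inner means
    mean(do.call(pmax, asplit(inner_nmb, 2))) -
      max(l * colMeans(comp$mE) - colMeans(comp$mC))
  }, numeric(1))
}

#' Per-patient EVPPI for one parameter group (two-level Monte Carlo)
#'
#' Outer loop `k = 1..K`: sample the group of interest from its marginal.
#' Inner loop `j = 1..J`: sample the remaining parameters conditionally
#' (fresh draws for every `k`), run the cohort model, and average net
#' benefit per arm. The EVPPI is the outer mean of the per-`k` best arm
#' minus the overall best arm, the latter computed from the pooled `K x J`
#' evaluations. Deterministic given `seed`.
#'
#' @param evidence An `hfvoi_evidence`.
#' @param group One of `r paste(HF_GROUPS, collapse = ", ")` (or several,
#'   treated jointly; the pseudo-group `"FEES"` may be added for diagnostic
#'   full conditioning).
#' @param lambda Threshold(s), EUR/QALY; the whole vector is evaluated from
#'   the same `K x J` model evaluations.
#' @param J,K Inner and outer loop sizes.
#' @param seed Integer master seed.
#' @param settings From [model_settings()].
#' @return Numeric vector of per-patient EVPPI values (EUR), one per
#'   threshold.
#' @export
evppi_per_patient <- function(evidence, group, lambda, J = 500L, K = 500L,
                              seed = 1L, settings = model_settings()) {
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  group_fields(group) # validates labels
  comp <- evppi_components(evidence, group, J, K, seed, settings)
  evppi_value(comp, lambda)
}

# Stopping rule shared by evppi_converged: successive escalation steps are
# compared pairwise at 1% relative tolerance, with an absolute floor for
# near-zero values.
voi_step_converged <- function(prev, new, rel_tol = 0.01, abs_floor = 1) {
  if (abs(prev) < abs_floor) return(abs(new) < abs_floor)
  abs(new - prev) < rel_tol * abs(prev)
}

#' EVPPI with stepwise convergence escalation
#'
#' Evaluates the two-level EVPPI estimator at loop sizes
#' `J = K = step, 2 * step, ...`, stopping when successive values at the
#' reference threshold differ by less than `rel_tol` (relative), with an
#' absolute floor of `abs_floor` EUR for near-zero values. Escalation is
#' capped at `cap`; hitting the cap without convergence is flagged, not an
#' error. Defaults follow the standard escalation rule: steps of 500 up to
#' 2,500.
#'
#' @inheritParams evppi_per_patient
#' @param lambda Threshold(s); the convergence rule is assessed at
#'   `ref_lambda`, and the returned values cover the whole vector.
#' @param ref_lambda Threshold at which convergence is judged (default
#'   20,000 EUR/QALY if present in `lambda`, else the first element).
#' @param step,cap Escalation step and cap for `J = K`.
#' @param rel_tol,abs_floor Stopping tolerances.
#' @return A list of class `hfvoi_evppi`: `value` (per threshold, at the
#'   final loop sizes), `lambda`, `J`, `K`, `converged`, and `trail` (a data
#'   frame of loop sizes and reference-threshold values per escalation
#'   step).
#' @export
evppi_converged <- function(evidence, group, lambda = 20000, seed = 1L,
                            settings = model_settings(),
                            ref_lambda = NULL, step = 500L, cap = 2500L,
                            rel_tol = 0.01, abs_floor = 1) {
  if (is.null(ref_lambda)) {
    ref_lambda <- if (20000 %in% lambda) 20000 else lambda[1]
  }
  sizes <- seq(step, cap, by = step)
  trail <- data.frame(J = integer(0), K = integer(0), value = numeric(0))
  values <- NULL
  converged <- FALSE
  prev_ref <- NULL
  for (size in sizes) {
    comp <- evppi_components(evidence, group, J = size, K = size,
                             seed = derive_seed(seed, "escalation", size),
                             settings = settings)
    ref_value <- evppi_value(comp, ref_lambda)
    trail <- rbind(trail, data.frame(J = size, K = size, value = ref_value))
    values <- evppi_value(comp, lambda)
    if (!is.null(prev_ref) &&
        voi_step_converged(prev_ref, ref_value, rel_tol, abs_floor)) {
      converged <- TRUE
      break
    }
    prev_ref <- ref_value
  }
  structure(list(
    group = group, value = values, lambda = lambda,
    J = trail$J[nrow(trail)], K = trail$K[nrow(trail)],
    converged = converged, ref_lambda = ref_lambda, trail = trail
  ), class = "hfvoi_evppi")
}

#' @export
print.hfvoi_evppi <- function(x, ...) {
  cat("<hfvoi_evppi>", paste(x$group, collapse = "+"),
      sprintf("(J=K=%d, %s)\n", x$J,
              if (x$converged) "converged" else "cap reached"))
  cat(sprintf("  EVPPI at lambda=%s: EUR %.2f\n",
              format(x$ref_lambda, big.mark = ","),
              x$value[match(x$ref_lambda, x$lambda)]))
  invisible(x)
}

#' EVPI and grouped EVPPI curves over a willingness-to-pay grid
#'
#' EVPI comes from one shared PSA; EVPPI per parameter group from the
#' two-level estimator with convergence escalation, judged at the reference
#' threshold and evaluated over the whole grid. Per-group escalation caps
#' default to 2,500 for the transition-probability group and 1,000 for the
#' others.
#'
#' @param evidence An `hfvoi_evidence`.
#' @param lambdas Grid for the EVPI curve.
#' @param evppi_lambdas Grid for the EVPPI curves (default: every 10,000
#'   EUR/QALY point of `lambdas`).
#' @param n_psa PSA size for the EVPI curve (default 2,500).
#' @param groups Parameter groups to analyze (default all five).
#' @param caps Named per-group escalation caps.
#' @param step Escalation step for `J = K`.
#' @param seed Integer master seed.
#' @param settings From [model_settings()].
#' @return A list of class `hfvoi_voi`: `evpi` (data frame `lambda`,
#'   `evpi`), `evppi` (data frame `group`, `lambda`, `value`, `J`, `K`,
#'   `converged`), and the shared `psa`.
#' @export
voi_curves <- function(evidence, lambdas = wtp_grid(),
                       evppi_lambdas = NULL, n_psa = 2500L,
                       groups = HF_GROUPS,
                       caps = c(TRANSITIONS = 2500L), step = 500L,
                       seed = 1L, settings = model_settings()) {
  validate_wtp(lambdas)
  if (is.null(evppi_lambdas)) {
    evppi_lambdas <- lambdas[lambdas %% 10000 == 0]
    if (!length(evppi_lambdas)) evppi_lambdas <- lambdas
  }
  psa <- run_psa(evidence, n_draws = n_psa, seed = derive_seed(seed, "voi"),
                 settings = settings)
  evpi <- data.frame(lambda = lambdas,
                     evpi = evpi_per_patient(psa, lambdas))
  evppi <- do.call(rbind, lapply(groups, function(g) {
    cap <- if (g %in% names(caps)) caps[[g]] else 1000L
    res <- evppi_converged(evidence, g, lambda = evppi_lambdas,
                           seed = derive_seed(seed, "voi", g),
                           settings = settings, step = step, cap = cap)
    data.frame(group = g, lambda = evppi_lambdas, value = res$value,
               J = res$J, K = res$K, converged = res$converged)
  }))
  structure(list(evpi = evpi, evppi = evppi, n_psa = as.integer(n_psa),
                 seed = as.integer(seed), psa = psa),
            class = "hfvoi_voi")
}

#' @export
print.hfvoi_voi <- function(x, ...) {
  cat("<hfvoi_voi> EVPI over", nrow(x$evpi), "thresholds;",
      length(unique(x$evppi$group)), "EVPPI groups\n")
  at20 <- x$evpi$evpi[x$evpi$lambda == 20000]
  if (length(at20)) {
    cat(sprintf("  per-patient EVPI at lambda=20,000: EUR %.2f\n", at20))
  }
  invisible(x)
}
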