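# Probabilistic sensitivity analysis and cost-effectiveness summaries:
# net monetary benefit, acceptability curves, frontier, ICERs.

#' Willingness-to-pay grid
#'
#' Strictly ascending EUR/QALY thresholds. The default grid spans
#' 0-100,000 in 1,000 steps, covering every threshold of practical interest
#' including the informal Dutch threshold of 20,000 EUR/QALY.
#'
#' @param from,to,by Grid limits and step, EUR/QALY.
#' @return Numeric vector of thresholds.
#' @export
wtp_grid <- function(from = 0, to = 100000, by = 1000) {
  grid <- seq(from, to, by = by)
  validate_wtp(grid)
  grid
}

validate_wtp <- function(grid) {
  if (!length(grid)) stop("empty willingness-to-pay grid", call. = FALSE)
  if (any(grid < 0)) stop("willingness-to-pay must be non-negative",
                          call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("willingness-to-pay grid must be strictly ascending", call. = FALSE)
  }
  invisible(grid)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter realizations from the evidence base and
#' runs the cohort model for all three arms under each, giving per-draw
#' discounted cost and QALY totals (second-order Monte Carlo).
#'
#' @param evidence An `hfvoi_evidence` object.
#' @param n_draws Number of parameter draws (default 2,500).
#' @param seed Integer master seed.
#' @param settings From [model_settings()].
#' @return An object of class `hfvoi_psa`: `costs` and `effects` are
#'   `n_draws` x 3 matrices with arms ordered (UC, NTS, HTM), plus seed and
#'   settings metadata.
#' @export
#' @examples
#' ev <- generate_evidence(seed = 1)
#' psa <- run_psa(ev, n_draws = 100, seed = 7)
#' colMeans(psa$effects)
run_psa <- function(evidence, n_draws = 2500L, seed = 1L,
                    settings = model_settings()) {
  stopifnot(n_draws >= 1L)
  batch <- sample_draws(evidence, n_draws, seed = derive_seed(seed, "psa"))
  out <- outcomes_batch(batch, settings)
  structure(list(
    n_draws = as.integer(n_draws), seed = as.integer(seed),
    settings = settings, costs = out$costs, effects = out$effects
  ), class = "hfvoi_psa")
}

#' @export
print.hfvoi_psa <- function(x, ...) {
  cat("<hfvoi_psa>", x$n_draws, "draws (seed", paste0(x$seed, ")"), "\n")
  cat("  mean costs  :",
      paste(sprintf("%s=%.0f", HF_ARMS, colMeans(x$costs)), collapse = " "),
      "EUR\n")
  cat("  mean QALYs  :",
      paste(sprintf("%s=%.3f", HF_ARMS, colMeans(x$effects)),
            collapse = " "), "\n")
  invisible(x)
}

#' Net monetary benefit per draw and arm
#'
#' `NMB_j = lambda * (E_j - E_UC) - (C_j - C_UC)` with usual care as the
#' baseline, so the UC column is identically zero.
#'
#' @param psa An `hfvoi_psa`.
#' @param lambda Willingness-to-pay threshold, EUR/QALY (scalar, >= 0).
#' @return An `n_draws` x 3 matrix of net monetary benefits, EUR.
#' @export
nmb <- function(psa, lambda) {
  if (length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a non-negative scalar", call. = FALSE)
  }
  lambda * (psa$effects - psa$effects[, "UC"]) -
    (psa$costs - psa$costs[, "UC"])
}

#' Cost-effectiveness acceptability curves
#'
#' For each threshold, the probability that each arm attains the maximal net
#' monetary benefit across the PSA draws. Ties are awarded to the
#' lowest-index arm (UC first), which makes the degenerate identical-arms
#' case deterministic.
#'
#' @param psa An `hfvoi_psa`.
#' @param lambdas Willingness-to-pay grid from [wtp_grid()].
#' @return A data frame of class `hfvoi_ceac` with columns `lambda`, `arm`,
#'   `probability`; the three probabilities sum to 1 at every threshold.
#' @export
ceac <- function(psa, lambdas = wtp_grid()) {
  validate_wtp(lambdas)
  rows <- lapply(lambdas, function(l) {
    winner <- max.col(nmb(psa, l), ties.method = "first")
    data.frame(lambda = l, arm = HF_ARMS,
               probability = tabulate(winner, nbins = 3L) / psa$n_draws)
  })
  structure(do.call(rbind, rows), class = c("hfvoi_ceac", "data.frame"))
}

#' Cost-effectiveness frontier
#'
#' The arm with maximal expected (mean) net monetary benefit at each
#' threshold; ties go to the lowest-index arm.
#'
#' @inheritParams ceac
#' @return A data frame with columns `lambda`, `arm`, `mean_nmb`.
#' @export
frontier <- function(psa, lambdas = wtp_grid()) {
  validate_wtp(lambdas)
  d_eff <- colMeans(psa$effects - psa$effects[, "UC"])
  d_cost <- colMeans(psa$costs - psa$costs[, "UC"])
  rows <- lapply(lambdas, function(l) {
    m <- l * d_eff - d_cost
    best <- which.max(m) # first maximum = lowest arm index on ties
    data.frame(lambda = l, arm = HF_ARMS[best], mean_nmb = m[best])
  })
  do.call(rbind, rows)
}

#' Pairwise incremental cost-effectiveness summaries
#'
#' Mean incremental cost and effect of each telehealth arm versus usual
#' care, with the ICER computed on mean increments (consistent with frontier
#' switch points). Degenerate cases are flagged rather than raised:
#' `"dominant"` (cheaper and more effective), `"dominated"` (costlier and
#' less effective, no ratio reported), `"undefined"` (zero mean incremental
#' effect).
#'
#' @param psa An `hfvoi_psa`.
#' @return A data frame with columns `arm`, `comparator`, `delta_cost`,
#'   `delta_effect`, `icer`, `status`.
#' @export
icer_table <- function(psa) {
  rows <- lapply(c("NTS", "HTM"), function(arm) {
    dc <- mean(psa$costs[, arm] - psa$costs[, "UC"])
    de <- mean(psa$effects[, arm] - psa$effects[, "UC"])
    status <- if (de == 0) {
      "undefined"
    } else if (dc < 0 && de > 0) {
      "dominant"
    } else if (dc > 0 && de < 0) {
      "dominated"
    } else {
      "icer"
    }
    data.frame(arm = arm, comparator = "UC", delta_cost = dc,
               delta_effect = de,
               icer = if (status == "icer") dc / de else NA_real_,
               status = status)
  })
  do.call(rbind, rows)
}
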