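# Cohort Markov model: five states (NYHA I-IV + death), 4-month cycles over
# a 20-year horizon, trial-phase transition matrices followed by the last
# phase held constant, discounted cost and QALY accumulation.

#' Model settings for the cohort Markov model
#'
#' @param horizon_years Time horizon in years (default 20, a lifetime
#'   horizon for a chronic heart failure cohort).
#' @param cycles_per_year Cycles per year (default 3: 4-month cycles).
#' @param discount_cost_annual Annual discount rate for costs (default 4\%,
#'   the Dutch guideline rate).
#' @param discount_effect_annual Annual discount rate for effects (default
#'   1.5\%).
#' @param replacement_interval_years Telemonitoring equipment replacement
#'   interval; the install fee recurs at the start of every interval
#'   (default 5 years).
#' @param half_cycle_correction If `TRUE`, rewards accrue on the average of
#'   cycle-start and cycle-end occupancy instead of cycle-start occupancy
#'   (default `FALSE`).
#' @return A list of class `hfvoi_settings`.
#' @export
model_settings <- function(horizon_years = 20, cycles_per_year = 3L,
                           discount_cost_annual = 0.04,
                           discount_effect_annual = 0.015,
                           replacement_interval_years = 5,
                           half_cycle_correction = FALSE) {
  n_cycles <- horizon_years * cycles_per_year
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("horizon_years x cycles_per_year must be an integer number of ",
         "cycles", call. = FALSE)
  }
  for (r in c(discount_cost_annual, discount_effect_annual)) {
    if (r < 0 || r >= 1) stop("discount rates must lie in [0, 1)",
                              call. = FALSE)
  }
  structure(list(
    horizon_years = horizon_years,
    cycles_per_year = as.integer(cycles_per_year),
    n_cycles = as.integer(round(n_cycles)),
    discount_cost_annual = discount_cost_annual,
    discount_effect_annual = discount_effect_annual,
    replacement_interval_years = replacement_interval_years,
    half_cycle_correction = isTRUE(half_cycle_correction)
  ), class = "hfvoi_settings")
}

#' Per-cycle discount factor
#'
#' Compound discounting at an annual rate, applied per cycle:
#' `(1 + rate)^(-cycle_index / cycles_per_year)`.
#'
#' @param annual_rate Annual discount rate in `[0, 1)`.
#' @param cycle_index Non-negative cycle index (0 = model start).
#' @param cycles_per_year Cycles per year.
#' @return The dimensionless discount factor.
#' @export
#' @examples
#' discount_factor(0.04, 3, 3)  # one year: 1 / 1.04
discount_factor <- function(annual_rate, cycle_index, cycles_per_year = 3L) {
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative",
                                 call. = FALSE)
  if (annual_rate < 0 || annual_rate >= 1) {
    stop("annual_rate must lie in [0, 1)", call. = FALSE)
  }
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

# Batch engine: discounted cost and QALY totals for every draw and arm.
outcomes_batch <- function(batch, settings = model_settings()) {
  cyc <- seq_len(settings$n_cycles) - 1L
  disc_c <- discount_factor(settings$discount_cost_annual, cyc,
                            settings$cycles_per_year)
  disc_e <- discount_factor(settings$discount_effect_annual, cyc,
                            settings$cycles_per_year)
  repl_cycles <- as.integer(round(batch$replacement_interval_years *
                                    settings$cycles_per_year))
  out <- cohort_batch_cpp(
    batch$transitions, batch$n_phases, batch$n,
    batch$utilities, batch$hosp_er, batch$contacts,
    dim(batch$hosp_er)[1], batch$unit_costs,
    batch$install_fee, batch$service_fee, batch$nts_cost,
    repl_cycles, batch$initial, disc_c, disc_e,
    settings$n_cycles, 1 / settings$cycles_per_year,
    settings$half_cycle_correction
  )
  colnames(out$costs) <- HF_ARMS
  colnames(out$effects) <- HF_ARMS
  out
}

#' Run the cohort model for one arm and one parameter draw
#'
#' Propagates the cohort occupancy by left-multiplication with the arm's
#' phase-appropriate transition matrix each 4-month cycle (trial-phase
#' matrices for the first `n_phases` cycles, the last trial-phase matrix
#' thereafter). Per-cycle QALYs are occupancy-weighted utilities times the
#' cycle length in years, discounted at the effect rate; per-cycle costs are
#' occupancy-weighted state costs (resource use times unit costs) plus
#' arm-specific fees weighted by the alive fraction, discounted at the cost
#' rate. The telemonitoring install fee is charged at cycle 0 and at the
#' start of every replacement interval.
#'
#' @param draw An `hfvoi_draw` from [sample_draw()].
#' @param arm One of `"UC"`, `"NTS"`, `"HTM"`.
#' @param settings From [model_settings()].
#' @param keep_trace If `TRUE` (default) the returned outcome carries the
#'   full cohort trace.
#' @return A list of class `hfvoi_outcome`: `discounted_cost` (EUR),
#'   `discounted_qalys`, and optionally `trace` (a data frame with one row
#'   per cycle: occupancy by state, undiscounted cycle cost and QALYs).
#' @export
run_cohort <- function(draw, arm, settings = model_settings(),
                       keep_trace = TRUE) {
  arm <- match.arg(arm, HF_ARMS)
  a <- match(arm, HF_ARMS)
  n_cycles <- settings$n_cycles
  np <- draw$n_phases
  u <- draw$utilities[HF_LIVING]
  if (any(u < 0)) stop("negative utility", call. = FALSE)

  n_res_arms <- dim(draw$hosp_er)[1]
  ra <- if (n_res_arms == 3L) a else 1L
  ru <- cbind(matrix(draw$hosp_er[ra, , ], 4L, 2L),
              matrix(draw$contacts[ra, , ], 4L, 5L))
  state_cost <- as.numeric(ru %*% draw$unit_costs)

  repl_cycles <- as.integer(round(draw$replacement_interval_years *
                                    settings$cycles_per_year))
  cycle_years <- 1 / settings$cycles_per_year

  occ <- matrix(0, n_cycles + 1L, 5L, dimnames = list(NULL, HF_STATES))
  occ[1L, ] <- c(draw$initial, 0)
  cycle_cost <- cycle_qaly <- numeric(n_cycles)
  disc_cost <- disc_qaly <- 0

  for (cyc in seq_len(n_cycles)) {
    c0 <- cyc - 1L # cycle index, 0-based
    p <- min(c0 + 1L, np)
    P <- matrix(draw$transitions[, , p, a], 4L, 5L)
    if (any(abs(rowSums(P) - 1) > 1e-9)) {
      stop("non-stochastic transition row", call. = FALSE)
    }
    nxt <- as.numeric(occ[cyc, HF_LIVING] %*% P)
    nxt[5L] <- nxt[5L] + occ[cyc, "DEAD"]
    occ[cyc + 1L, ] <- nxt

    w <- if (settings$half_cycle_correction) {
      (occ[cyc, ] + occ[cyc + 1L, ]) / 2
    } else {
      occ[cyc, ]
    }
    alive <- sum(w[HF_LIVING])
    q <- sum(w[HF_LIVING] * u) * cycle_years
    cost <- sum(w[HF_LIVING] * state_cost)
    if (arm == "NTS") cost <- cost + draw$nts_cost * alive
    if (arm == "HTM") {
      cost <- cost + draw$service_fee * alive
      if (c0 %% repl_cycles == 0) cost <- cost + draw$install_fee * alive
    }
    cycle_cost[cyc] <- cost
    cycle_qaly[cyc] <- q
    disc_cost <- disc_cost +
      cost * discount_factor(settings$discount_cost_annual, c0,
                             settings$cycles_per_year)
    disc_qaly <- disc_qaly +
      q * discount_factor(settings$discount_effect_annual, c0,
                          settings$cycles_per_year)
  }

  out <- list(arm = arm, discounted_cost = disc_cost,
              discounted_qalys = disc_qaly)
  if (keep_trace) {
    out$trace <- data.frame(cycle = 0:n_cycles, occ,
                            cycle_cost = c(cycle_cost, NA),
                            cycle_qaly = c(cycle_qaly, NA))
  }
  structure(out, class = "hfvoi_outcome")
}

#' Discounted outcomes for all three arms under one parameter draw
#'
#' @param draw An `hfvoi_draw`.
#' @param settings From [model_settings()].
#' @return A data frame with one row per arm (ordered UC, NTS, HTM) and
#'   columns `arm`, `cost`, `qalys`.
#' @export
arm_outcomes <- function(draw, settings = model_settings()) {
  out <- outcomes_batch(draw_to_batch(draw), settings)
  data.frame(arm = HF_ARMS, cost = as.numeric(out$costs[1L, ]),
             qalys = as.numeric(out$effects[1L, ]))
}

#' @export
print.hfvoi_outcome <- function(x, ...) {
  cat(sprintf("<hfvoi_outcome> %s: cost EUR %.2f, QALYs %.4f\n",
              x$arm, x$discounted_cost, x$discounted_qalys))
  invisible(x)
}
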