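# Shared fixtures: small evidence bases, hand-built draws, and an
# independent loop-based reimplementation of the cohort model used as the
# oracle for the discounted totals.

small_evidence <- function(seed = 1, ...) {
  generate_evidence(default_generator_config(...), seed = seed)
}

# Evidence in which the three arms are exactly exchangeable: no treatment
# effect, no intervention fees. Every draw then yields identical outcomes
# across arms and all incremental net benefits are exactly zero.
null_effect_evidence <- function(seed = 1, ...) {
  generate_evidence(
    default_generator_config(
      effect_nts = 0, effect_htm = 0, arm_shared_transitions = TRUE,
      htm_install_fee_bounds = c(0, 0), htm_service_fee_bounds = c(0, 0),
      nts_cost_per_cycle = 0, ...),
    seed = seed)
}

# Build an hfvoi_draw by hand. `P` is a single 4x5 matrix (replicated over
# phases and arms) or a list of three per-arm matrices. Resources and fees
# default to zero so QALY arithmetic can be checked in isolation.
make_draw <- function(P, utilities = c(1, 1, 1, 1),
                      initial = c(1, 0, 0, 0),
                      n_phases = 1L,
                      unit_costs = rep(0, 7),
                      hosp_er = array(0, c(1, 4, 2)),
                      contacts = array(0, c(1, 4, 5)),
                      install_fee = 0, service_fee = 0, nts_cost = 0,
                      replacement_interval_years = 5) {
  trans <- array(0, c(4, 5, n_phases, 3))
  for (a in 1:3) {
    Pa <- if (is.list(P)) P[[a]] else P
    for (p in seq_len(n_phases)) trans[, , p, a] <- Pa
  }
  structure(list(
    n_phases = n_phases, treatment_specific = FALSE,
    transitions = trans,
    utilities = setNames(c(utilities, 0), HF_STATES),
    hosp_er = hosp_er, contacts = contacts,
    unit_costs = setNames(unit_costs, HF_RESOURCES),
    install_fee = install_fee, service_fee = service_fee,
    nts_cost = nts_cost,
    replacement_interval_years = replacement_interval_years,
    initial = setNames(initial, HF_LIVING)
  ), class = "hfvoi_draw")
}

# A 4x5 row-stochastic matrix where every living state transitions
# somewhere sensible; used as a generic valid matrix.
example_matrix <- function() {
  matrix(c(
    0.7, 0.2, 0.05, 0.02, 0.03,
    0.1, 0.6, 0.2, 0.05, 0.05,
    0.02, 0.1, 0.6, 0.18, 0.1,
    0.01, 0.04, 0.15, 0.55, 0.25
  ), 4, 5, byrow = TRUE)
}

# Independent oracle for the discounted totals: explicit scalar loops over
# cycles and states, no matrix products, written directly from the model
# definition. Deliberately structured differently from the package engine.
oracle_outcomes <- function(draw, arm, settings = model_settings()) {
  a <- match(arm, HF_ARMS)
  cpy <- settings$cycles_per_year
  n_cycles <- settings$n_cycles
  repl <- round(draw$replacement_interval_years * cpy)
  nra <- dim(draw$hosp_er)[1]
  ra <- if (nra == 3) a else 1

  state_cost <- numeric(4)
  for (s in 1:4) {
    acc <- 0
    for (t in 1:2) acc <- acc + draw$hosp_er[ra, s, t] * draw$unit_costs[t]
    for (t in 1:5) acc <- acc + draw$contacts[ra, s, t] * draw$unit_costs[2 + t]
    state_cost[s] <- acc
  }

  occ <- c(draw$initial, 0)
  total_cost <- 0
  total_qaly <- 0
  for (cyc in 0:(n_cycles - 1)) {
    p <- min(cyc + 1, draw$n_phases)
    dc <- (1 + settings$discount_cost_annual)^(-cyc / cpy)
    de <- (1 + settings$discount_effect_annual)^(-cyc / cpy)

    nxt <- numeric(5)
    for (to in 1:5) {
      for (from in 1:4) {
        nxt[to] <- nxt[to] + occ[from] * draw$transitions[from, to, p, a]
      }
    }
    nxt[5] <- nxt[5] + occ[5]

    w <- if (settings$half_cycle_correction) (occ + nxt) / 2 else occ
    alive <- 0
    q <- 0
    cost <- 0
    for (s in 1:4) {
      q <- q + w[s] * draw$utilities[s]
      cost <- cost + w[s] * state_cost[s]
      alive <- alive + w[s]
    }
    if (arm == "NTS") cost <- cost + draw$nts_cost * alive
    if (arm == "HTM") {
      cost <- cost + draw$service_fee * alive
      if (cyc %% repl == 0) cost <- cost + draw$install_fee * alive
    }
    total_qaly <- total_qaly + q / cpy * de
    total_cost <- total_cost + cost * dc
    occ <- nxt
  }
  list(cost = unname(total_cost), qalys = unname(total_qaly))
}

# Build an hfvoi_psa object directly from enumerated outcomes (exact /
# enumeration mode: each row is one equally weighted joint outcome).
psa_from_outcomes <- function(costs, effects, seed = 0L) {
  colnames(costs) <- HF_ARMS
  colnames(effects) <- HF_ARMS
  structure(list(n_draws = nrow(costs), seed = seed,
                 settings = model_settings(), costs = costs,
                 effects = effects),
            class = "hfvoi_psa")
}

# Discrete toy: group phi and complement psi each take two equally likely
# values; net benefits are hand-assigned per (phi, psi, arm). The enumeration
# oracle computes EVPI and EVPPI by summing over all four joint outcomes
# with explicit loops.
toy_nmb <- function() {
  nmb <- array(0, c(2, 2, 3)) # (phi, psi, arm); arm 1 is the baseline
  nmb[1, 1, ] <- c(0, 20, -5)
  nmb[1, 2, ] <- c(0, -10, 5)
  nmb[2, 1, ] <- c(0, 5, 30)
  nmb[2, 2, ] <- c(0, -15, -10)
  nmb
}

enumerate_voi <- function(nmb) {
  # EVPI: mean over the 4 outcomes of the best arm, minus best mean arm
  e_max <- 0
  for (i in 1:2) for (j in 1:2) e_max <- e_max + max(nmb[i, j, ]) / 4
  arm_means <- numeric(3)
  for (a in 1:3) arm_means[a] <- sum(nmb[, , a]) / 4
  evpi <- e_max - max(arm_means)
  # EVPPI(phi): mean over phi of the best psi-averaged arm, minus baseline
  outer_term <- 0
  for (i in 1:2) {
    cond_means <- numeric(3)
    for (a in 1:3) cond_means[a] <- (nmb[i, 1, a] + nmb[i, 2, a]) / 2
    outer_term <- outer_term + max(cond_means) / 2
  }
  list(evpi = evpi, evppi = outer_term - max(arm_means))
}
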