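# Cohort model: discounting, reward conventions, conservation, oracle
# agreement between the batch engine, the R trace path and an independent
# loop-based reimplementation.

no_discount <- function() {
  model_settings(discount_cost_annual = 0, discount_effect_annual = 0)
}

test_that("discount factors match closed forms", {
  expect_equal(discount_factor(0, 17, 3), 1)
  expect_equal(discount_factor(0.04, 3, 3), 1 / 1.04, tolerance = 1e-12)
  expect_equal(discount_factor(0.04, 60, 3), 1.04^-20, tolerance = 1e-12)
  expect_error(discount_factor(0.04, -1, 3), "non-negative")
  expect_error(discount_factor(1.2, 0, 3), "\\[0, 1\\)")
})

test_that("identity transitions with utility 1 give the full horizon in QALYs", {
  P <- cbind(diag(4), 0)
  d <- make_draw(P, utilities = c(1, 1, 1, 1), initial = c(1, 0, 0, 0))
  out <- arm_outcomes(d, no_discount())
  expect_equal(out$qalys, rep(20, 3), tolerance = 1e-12)
  expect_equal(out$cost, c(0, 0, 0)) # zero resources, zero fees
})

test_that("immediate death leaves only the first cycle-start occupancy", {
  P <- matrix(0, 4, 5)
  P[, 5] <- 1 # every living state dies within one cycle
  d <- make_draw(P, utilities = c(1, 1, 1, 1))
  out <- arm_outcomes(d, no_discount())
  expect_equal(out$qalys, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("occupancy is conserved and death is absorbing on random draws", {
  ev <- small_evidence()
  for (i in 1:5) {
    d <- sample_draw(ev, seed = 100 + i)
    tr <- run_cohort(d, sample(HF_ARMS, 1))$trace
    occ <- as.matrix(tr[, HF_STATES])
    expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-10)
    expect_true(all(diff(tr$DEAD) >= -1e-12))
  }
})

test_that("batch engine, R trace and the independent oracle agree", {
  ev <- small_evidence()
  set.seed(42)
  for (i in 1:100) {
    d <- sample_draw(ev)
    settings <- model_settings(
      half_cycle_correction = (i %% 4 == 0)
    )
    out <- arm_outcomes(d, settings)
    arm <- HF_ARMS[(i %% 3) + 1]
    a <- match(arm, HF_ARMS)
    orc <- oracle_outcomes(d, arm, settings)
    expect_equal(out$cost[a], orc$cost, tolerance = 1e-9)
    expect_equal(out$qalys[a], orc$qalys, tolerance = 1e-9)
    rc <- run_cohort(d, arm, settings, keep_trace = FALSE)
    expect_equal(rc$discounted_cost, orc$cost, tolerance = 1e-9)
    expect_equal(rc$discounted_qalys, orc$qalys, tolerance = 1e-9)
  }
})

test_that("telemonitoring fees recur at every replacement interval", {
  P <- cbind(diag(4), 0) # nobody dies: alive fraction 1 throughout
  d <- make_draw(P, install_fee = 1000, service_fee = 100)
  out <- arm_outcomes(d, no_discount())
  # install at cycles 0, 15, 30, 45 plus service fee in all 60 cycles
  expect_equal(out$cost[3], 4 * 1000 + 60 * 100, tolerance = 1e-9)
  expect_equal(out$cost[1], 0)
  d2 <- make_draw(P, nts_cost = 50)
  expect_equal(arm_outcomes(d2, no_discount())$cost[2], 60 * 50,
               tolerance = 1e-9)
})

test_that("raising a utility or a unit cost weakly raises the outcome", {
  ev <- small_evidence()
  d <- sample_draw(ev, seed = 9)
  base <- arm_outcomes(d)
  for (s in 1:4) {
    d_up <- d
    d_up$utilities[s] <- min(1, d$utilities[s] + 0.05)
    up <- arm_outcomes(d_up)
    expect_true(all(up$qalys >= base$qalys - 1e-12))
    expect_equal(up$cost, base$cost)
  }
  for (t in 1:7) {
    d_up <- d
    d_up$unit_costs[t] <- d$unit_costs[t] + 10
    up <- arm_outcomes(d_up)
    expect_true(all(up$cost >= base$cost - 1e-12))
    expect_equal(up$qalys, base$qalys)
  }
})

test_that("undiscounted QALYs match the matrix-power closed form", {
  ev <- generate_evidence(default_generator_config(n_trial_phases = 1))
  d <- sample_draw(ev, seed = 12)
  P5 <- rbind(d$transitions[, , 1, 1], c(0, 0, 0, 0, 1))
  pi0 <- c(d$initial, 0)
  u <- d$utilities
  expected <- 0
  Pc <- diag(5)
  for (cyc in 0:59) {
    expected <- expected + sum((pi0 %*% Pc) * u) / 3
    Pc <- Pc %*% P5
  }
  out <- arm_outcomes(d, no_discount())
  expect_equal(out$qalys[1], expected, tolerance = 1e-9)
})

test_that("stochastically better transitions with equal costs give more QALYs", {
  worse <- example_matrix()
  better <- worse
  # shift mass from death and severe states toward staying milder
  for (s in 1:4) {
    moved <- 0.5 * better[s, 5]
    better[s, 5] <- better[s, 5] - moved
    better[s, s] <- better[s, s] + moved
  }
  d <- make_draw(list(worse, worse, better),
                 utilities = c(0.9, 0.7, 0.5, 0.3),
                 initial = c(0.25, 0.25, 0.25, 0.25))
  out <- arm_outcomes(d)
  expect_gte(out$qalys[3], out$qalys[1])
  expect_equal(out$cost, rep(0, 3))
})

test_that("arm symmetry: identical parameters give identical outcomes", {
  ev <- null_effect_evidence()
  d <- sample_draw(ev, seed = 77)
  out <- arm_outcomes(d)
  expect_equal(out$cost[2:3], rep(out$cost[1], 2), tolerance = 1e-12)
  expect_equal(out$qalys[2:3], rep(out$qalys[1], 2), tolerance = 1e-12)
})

test_that("invalid model settings are rejected", {
  expect_error(model_settings(horizon_years = 20.5, cycles_per_year = 3),
               "integer number of cycles")
  expect_error(model_settings(discount_cost_annual = 1), "\\[0, 1\\)")
})
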