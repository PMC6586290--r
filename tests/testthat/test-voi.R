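# EVPI and EVPPI: enumeration-mode exactness, estimator identities, and the
# convergence escalation rule.

test_that("enumeration-mode estimators equal brute-force enumeration", {
  nmb <- toy_nmb()
  oracle <- enumerate_voi(nmb)
  # frozen values computed from the enumeration oracle by hand:
  # maxima 20, 5, 30, 0 -> 13.75; arm means (0, 0, 5) -> EVPI 8.75
  # phi-conditional means: (0, 5, 0) -> 5 and (0, -5, 10) -> 10 -> 7.5
  expect_equal(oracle$evpi, 8.75)
  expect_equal(oracle$evppi, 2.5)

  flat <- rbind(nmb[1, 1, ], nmb[1, 2, ], nmb[2, 1, ], nmb[2, 2, ])
  expect_equal(evpi_from_nmb(flat), oracle$evpi, tolerance = 1e-12)
  expect_equal(evppi_from_nmb(nmb), oracle$evppi, tolerance = 1e-12)
  expect_lte(evppi_from_nmb(nmb), evpi_from_nmb(flat)) # exact ordering
})

test_that("EVPPI with an inner loop of one reduces to single-loop EVPI", {
  set.seed(31)
  k <- 40
  nmb_flat <- cbind(0, matrix(rnorm(2 * k, sd = 50), k, 2))
  nmb_nested <- array(nmb_flat, c(k, 1, 3))
  expect_equal(evppi_from_nmb(nmb_nested), evpi_from_nmb(nmb_flat),
               tolerance = 1e-12)
})

test_that("EVPI on a two-outcome toy equals its enumerated value", {
  psa <- psa_from_outcomes(rbind(c(0, 0, 0), c(0, 0, 0)),
                           rbind(c(1, 1.001, 1), c(1, 0.999, 1)))
  # NMBs at lambda 10,000: (0, +10, 0) and (0, -10, 0) -> EVPI 5
  expect_equal(evpi_per_patient(psa, 10000), 5, tolerance = 1e-9)
})

test_that("EVPI is zero when one arm dominates every draw", {
  costs <- rbind(c(10, 5, 20), c(12, 6, 25))
  effects <- rbind(c(1, 1.5, 0.9), c(1, 1.4, 0.8))
  psa <- psa_from_outcomes(costs, effects)
  expect_equal(evpi_per_patient(psa, 20000), 0)
  # lambda 0 with equal costs in every draw: degenerate payoff
  eq <- psa_from_outcomes(rbind(c(7, 7, 7)), rbind(c(1, 2, 3)))
  expect_equal(evpi_per_patient(eq, 0), 0)
})

test_that("EVPI is invariant to a per-draw constant added to all arms", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 150, seed = 17)
  for (l in c(0, 15000, 40000)) {
    m <- nmb(psa, l)
    shift <- matrix(rnorm(nrow(m), sd = 1000), nrow(m), 3)
    expect_equal(evpi_from_nmb(m + shift), evpi_from_nmb(m),
                 tolerance = 1e-9)
  }
})

test_that("EVPI is invariant to the baseline arm of the net benefit", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 150, seed = 19)
  m <- nmb(psa, 20000)
  rebased <- m - m[, "HTM"] # NMB against HTM instead of UC
  expect_equal(evpi_from_nmb(rebased), evpi_from_nmb(m), tolerance = 1e-9)
})

test_that("EVPI is non-negative across thresholds on sampled evidence", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 400, seed = 23)
  expect_true(all(evpi_per_patient(psa, seq(0, 100000, 20000)) >= 0))
})

test_that("an uninformative group has near-zero EVPPI", {
  # all arms identical and feeless: no draw changes the decision, so
  # partial perfect information on any group is worthless
  ev <- null_effect_evidence()
  v <- evppi_per_patient(ev, "INITIAL_DIST", lambda = 20000, J = 30, K = 30,
                         seed = 41)
  expect_equal(v, 0, tolerance = 1e-9)
})

test_that("nested estimates are reproducible and respond to loop size", {
  ev <- small_evidence()
  v1 <- evppi_per_patient(ev, "UTILITIES", lambda = 20000, J = 20, K = 25,
                          seed = 7)
  v2 <- evppi_per_patient(ev, "UTILITIES", lambda = 20000, J = 20, K = 25,
                          seed = 7)
  expect_identical(v1, v2)
  # |EVPPI - EVPI| shrinks as J grows for a weak group (finite-J bias)
  psa <- run_psa(ev, n_draws = 2500, seed = 7)
  evpi <- evpi_per_patient(psa, 20000)
  v_small <- evppi_per_patient(ev, "UTILITIES", 20000, J = 10, K = 60,
                               seed = 11)
  v_large <- evppi_per_patient(ev, "UTILITIES", 20000, J = 160, K = 60,
                               seed = 11)
  expect_lt(abs(v_large), abs(v_small))
  expect_error(evppi_per_patient(ev, "NOPE", 20000, 10, 10), "unknown")
})

test_that("the escalation rule steps, stops and caps as specified", {
  expect_true(hfvoi:::voi_step_converged(100, 100.9))
  expect_false(hfvoi:::voi_step_converged(100, 102))
  expect_true(hfvoi:::voi_step_converged(0, 0.5)) # absolute floor
  expect_false(hfvoi:::voi_step_converged(0.2, 5))

  # strong-signal toy at tiny sizes: exercises escalation and the trail
  ev <- small_evidence()
  res <- evppi_converged(ev, "TRANSITIONS", lambda = c(10000, 20000),
                         seed = 3, step = 20L, cap = 100L)
  expect_true(all(res$trail$J %% 20 == 0))
  expect_true(all(res$trail$J <= 100))
  expect_identical(res$trail$J, res$trail$K)
  expect_length(res$value, 2)
  if (res$converged) {
    n <- nrow(res$trail)
    expect_true(hfvoi:::voi_step_converged(res$trail$value[n - 1],
                                           res$trail$value[n]))
  } else {
    expect_equal(res$J, 100L)
  }
})

test_that("voi_curves tabulates EVPI and per-group EVPPI", {
  ev <- small_evidence()
  res <- voi_curves(ev, lambdas = seq(0, 40000, 10000),
                    evppi_lambdas = c(0, 20000), n_psa = 100,
                    groups = c("TRANSITIONS", "UTILITIES"),
                    caps = c(TRANSITIONS = 40L, UTILITIES = 40L),
                    step = 20L, seed = 2)
  expect_equal(nrow(res$evpi), 5)
  expect_true(all(res$evpi$evpi >= 0))
  expect_setequal(unique(res$evppi$group), c("TRANSITIONS", "UTILITIES"))
  expect_equal(nrow(res$evppi), 4) # 2 groups x 2 thresholds
})

test_that("degenerate point-mass evidence yields an EVPI curve of zero", {
  # huge pseudo-sample sizes and tiny moment spreads: parameter
  # distributions collapse, so there is no decision uncertainty left
  cfg <- default_generator_config(
    pseudo_n = 1e9, initial_pseudo_n = 1e9,
    utility_sd = rep(1e-6, 4), resource_cv = 1e-6, unit_cost_cv = 1e-6,
    htm_install_fee_bounds = c(2000, 2000),
    htm_service_fee_bounds = c(400, 400))
  ev <- generate_evidence(cfg)
  psa <- run_psa(ev, n_draws = 60, seed = 5)
  evpi <- evpi_per_patient(psa, c(0, 20000, 60000))
  expect_equal(evpi, rep(0, 3), tolerance = 0.01)
})
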