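# PSA, net monetary benefit, acceptability curves, frontier and ICERs.

test_that("a one-draw PSA equals a direct model evaluation on the same stream", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 1, seed = 13)
  d <- sample_draw(ev, seed = derive_seed(13, "psa"))
  out <- arm_outcomes(d)
  expect_equal(as.numeric(psa$costs[1, ]), out$cost, tolerance = 1e-12)
  expect_equal(as.numeric(psa$effects[1, ]), out$qalys, tolerance = 1e-12)
})

test_that("the PSA is reproducible and arm-symmetric under a null effect", {
  ev <- null_effect_evidence()
  p1 <- run_psa(ev, n_draws = 50, seed = 3)
  p2 <- run_psa(ev, n_draws = 50, seed = 3)
  expect_identical(p1$costs, p2$costs)
  expect_identical(p1$effects, p2$effects)
  expect_equal(p1$costs[, "NTS"], p1$costs[, "UC"], tolerance = 1e-12)
  expect_equal(p1$costs[, "HTM"], p1$costs[, "UC"], tolerance = 1e-12)
  expect_equal(p1$effects[, "HTM"], p1$effects[, "UC"], tolerance = 1e-12)
})

test_that("net monetary benefit follows the incremental formula", {
  costs <- rbind(c(10000, 12000, 13000))
  effects <- rbind(c(2.0, 2.5, 2.2))
  psa <- psa_from_outcomes(costs, effects)
  m <- nmb(psa, 20000)
  expect_equal(unname(m[1, ]), c(0, 20000 * 0.5 - 2000, 20000 * 0.2 - 3000))
  expect_equal(unname(m[1, "NTS"]), 8000)
  # lambda = 0: minus incremental cost
  expect_equal(unname(nmb(psa, 0)[1, ]), c(0, -2000, -3000))
  expect_error(nmb(psa, -1), "non-negative")
})

test_that("net monetary benefit is affine in the threshold", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 40, seed = 5)
  d_eff <- psa$effects - psa$effects[, "UC"]
  expect_equal(nmb(psa, 30000) - nmb(psa, 12000), (30000 - 12000) * d_eff,
               tolerance = 1e-9)
})

test_that("acceptability probabilities partition the draws", {
  ev <- small_evidence()
  psa <- run_psa(ev, n_draws = 200, seed = 8)
  cc <- ceac(psa, wtp_grid(0, 50000, 10000))
  sums <- tapply(cc$probability, cc$lambda, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)

  one <- ceac(run_psa(ev, n_draws = 1, seed = 8), wtp_grid(0, 20000, 20000))
  expect_true(all(one$probability %in% c(0, 1)))
})

test_that("acceptability counts match a hand-enumerated toy", {
  # at lambda = 20,000: NTS wins draws 1-3, UC wins draw 4
  costs <- rbind(c(0, 1000, 9000),
                 c(0, 2000, 9000),
                 c(0, 500, 9000),
                 c(0, 4000, 9000))
  effects <- rbind(c(1, 1.2, 1.1),
                   c(1, 1.3, 1.1),
                   c(1, 1.1, 1.1),
                   c(1, 1.1, 1.1))
  psa <- psa_from_outcomes(costs, effects)
  cc <- ceac(psa, c(20000))
  expect_equal(cc$probability[cc$arm == "NTS"], 0.75)
  expect_equal(cc$probability[cc$arm == "UC"], 0.25)
})

test_that("the frontier switches at the incremental cost-effectiveness ratio", {
  # two effective arms: NTS with dC 1000, dE 0.25 (exactly representable,
  # so the switch threshold of 4,000 is an exact tie); HTM identical to UC
  costs <- rbind(c(5000, 6000, 5000), c(5000, 6000, 5000))
  effects <- rbind(c(1, 1.25, 1), c(1, 1.25, 1))
  psa <- psa_from_outcomes(costs, effects)
  fr <- frontier(psa, c(0, 3000, 4000, 5000, 50000))
  expect_equal(fr$arm[fr$lambda == 0], "UC") # lowest mean cost
  expect_equal(fr$arm[fr$lambda == 3000], "UC")
  expect_equal(fr$arm[fr$lambda == 4000], "UC") # tie goes to UC
  expect_equal(fr$arm[fr$lambda == 5000], "NTS")
  expect_equal(fr$arm[fr$lambda == 50000], "NTS")
})

test_that("identical arms resolve to usual care by the tie rule", {
  costs <- rbind(c(100, 100, 100))
  effects <- rbind(c(1, 1, 1))
  psa <- psa_from_outcomes(costs, effects)
  expect_true(all(frontier(psa, wtp_grid(0, 40000, 10000))$arm == "UC"))
  cc <- ceac(psa, c(0, 20000))
  expect_equal(cc$probability[cc$arm == "UC"], c(1, 1))
})

test_that("ICERs are mean-increment ratios with dominance flags", {
  costs <- rbind(c(0, 50, 0), c(0, 150, 0))
  effects <- rbind(c(1, 1.01, 1), c(1, 1.03, 1))
  psa <- psa_from_outcomes(costs, effects)
  it <- icer_table(psa)
  expect_equal(it$icer[it$arm == "NTS"], 100 / 0.02, tolerance = 1e-9)
  expect_equal(it$status[it$arm == "NTS"], "icer")
  expect_equal(it$status[it$arm == "HTM"], "undefined")

  dom <- psa_from_outcomes(rbind(c(100, 50, 200)), rbind(c(1, 1.1, 0.9)))
  dt <- icer_table(dom)
  expect_equal(dt$status, c("dominant", "dominated"))
  expect_true(all(is.na(dt$icer)))
})

test_that("willingness-to-pay grids are validated", {
  expect_error(ceac(psa_from_outcomes(rbind(c(0, 0, 0)),
                                      rbind(c(1, 1, 1))), numeric(0)),
               "empty")
  expect_error(ceac(psa_from_outcomes(rbind(c(0, 0, 0)),
                                      rbind(c(1, 1, 1))), c(10000, 5000)),
               "ascending")
  expect_true(20000 %in% wtp_grid())
})
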