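test_that("the hypertension mortality product matches the printed values", {
  expect_equal(hypertension_mortality(), 0.0812)
  expect_equal(attributable_mortality_fraction(), 64.93)
  expect_equal(hypertension_mortality(mortality_inputs(p_ir = 0)), 0)
  expect_error(mortality_inputs(hyp_death_rate = 3, cvd_death_rate = 2),
               "exceed")
  expect_error(mortality_inputs(cvd_death_rate = 0), "positive")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  set.seed(301)
  for (i in 1:50) {
    p <- random_markov_params()
    M <- build_transition_matrix(p)
    expect_equal(unname(rowSums(M)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["dead", ]), c(0, 0, 1))
  }
  # no deaths and certain control: everyone is well after one cycle
  p <- markov_params("ipc", control_prob = 1, mort_poor = 0, mort_well = 0)
  tr <- run_markov_cohort(p)
  expect_equal(unname(unlist(tr[2, c("poor", "well", "dead")])), c(0, 1, 0))
  expect_error(markov_params("ipc", control_prob = 1.2), "\\[0, 1\\]")
})

test_that("cycle-1 counts reproduce the published anchors of both arms", {
  tr_ipc <- run_markov_cohort(markov_params("ipc"))
  tr_none <- run_markov_cohort(markov_params("none"))
  expect_equal(unname(unlist(tr_ipc[2, c("n_poor", "n_well", "n_dead")])),
               c(25, 63, 8))
  expect_equal(unname(unlist(tr_none[2, c("n_poor", "n_well", "n_dead")])),
               c(78, 10, 8))
})

test_that("terminal occupancy reproduces the published 28-cycle state", {
  tr <- run_markov_cohort(markov_params("ipc"))
  last <- tr[nrow(tr), ]
  expect_equal(unname(unlist(last[c("n_poor", "n_well", "n_dead")])),
               c(11, 30, 55))
  expect_equal(100 * last$poor, 11.92, tolerance = 0.25 / 11.92)
  expect_equal(100 * last$well, 31.06, tolerance = 0.25 / 31.06)
  expect_equal(100 * last$dead, 57.02, tolerance = 0.25 / 57.02)
  trn <- run_markov_cohort(markov_params("none"))
  expect_equal(unname(unlist(trn[nrow(trn), c("n_poor", "n_well", "n_dead")])),
               c(12, 5, 79))
})

test_that("traces agree with the matrix-power oracle and keep their invariants", {
  set.seed(302)
  for (i in 1:20) {
    p <- random_markov_params()
    tr <- run_markov_cohort(p)
    M <- build_transition_matrix(p)
    or <- matrix_power_trace(M, p$horizon)
    expect_lt(max(abs(as.matrix(tr[c("poor", "well", "dead")]) - or)), 1e-12)
    expect_equal(tr$poor + tr$well + tr$dead, rep(1, p$horizon + 1),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(tr$n_poor + tr$n_well + tr$n_dead == p$cohort_size))
  }
})

test_that("life years respond monotonically to mortality and control", {
  ly <- function(c_, dp, dw)
    life_years(run_markov_cohort(markov_params("ipc", control_prob = c_,
                                               mort_poor = dp,
                                               mort_well = dw)))
  base <- ly(0.7, 0.08, 0.01)
  expect_lt(ly(0.7, 0.12, 0.01), base)  # higher poor mortality
  expect_lt(ly(0.7, 0.08, 0.05), base)  # higher well mortality
  expect_gt(ly(0.9, 0.08, 0.01), base)  # more control when d_w < d_p
})

test_that("cycle-accounting conventions behave as defined", {
  p0 <- markov_params("ipc", mort_poor = 0, mort_well = 0)
  tr0 <- run_markov_cohort(p0)
  for (cv in c("begin-of-cycle", "end-of-cycle"))
    expect_equal(life_years(tr0, cv), 28)
  expect_equal(life_years(tr0, "include-cycle-0"), 29)
  expect_equal(life_years(tr0, "half-cycle"), 28)
  expect_error(life_years(tr0, "whenever"))
})

test_that("the calibrated convention reproduces the published survival pair", {
  cal <- calibrate_cycle_convention()
  expect_equal(cal$convention[1], "begin-of-cycle")
  tr_ipc <- run_markov_cohort(markov_params("ipc"))
  tr_none <- run_markov_cohort(markov_params("none"))
  expect_equal(life_years(tr_ipc), 18.62, tolerance = 0.5 / 18.62)
  expect_equal(life_years(tr_none), 13.22, tolerance = 0.5 / 13.22)
  # frozen regression values for the default parameterisation
  expect_equal(life_years(tr_ipc), 18.63661, tolerance = 1e-6)
  expect_equal(life_years(tr_none), 13.22741, tolerance = 1e-6)
  expect_equal(incremental_qaly(tr_ipc, tr_none), 5.40, tolerance = 0.1 / 5.4)
})

test_that("QALYs reduce to life years at unit utilities and scale with them", {
  tr <- run_markov_cohort(markov_params("ipc"))
  expect_equal(qaly(tr, 1, 1), life_years(tr))
  expect_equal(qaly(tr, 0, 0), 0)
  expect_lt(qaly(tr, 0.8, 0.95), life_years(tr))
  expect_error(qaly(tr, 1.2, 1), "\\[0, 1\\]")
})

test_that("costs accrue linearly and respect the rule", {
  tr <- run_markov_cohort(markov_params("ipc"))
  expect_equal(cumulative_cost(tr, cost_rule(annual_cost_per_patient = 0)), 0)
  c1 <- cumulative_cost(tr, cost_rule(annual_cost_per_patient = 77.80))
  c2 <- cumulative_cost(tr, cost_rule(annual_cost_per_patient = 155.60))
  expect_equal(c2, 2 * c1)
  # +/-20% cost scenarios bracket the base case symmetrically
  lo <- cumulative_cost(tr, cost_rule(annual_cost_per_patient = 77.80 * 0.8))
  hi <- cumulative_cost(tr, cost_rule(annual_cost_per_patient = 77.80 * 1.2))
  expect_equal((lo + hi) / 2, c1, tolerance = 1e-12)
  expect_error(cost_rule(annual_cost_per_patient = -1), "nonnegative")
})

test_that("the cost-effectiveness ratio follows the printed arithmetic", {
  expect_equal(cer(470.37, 5.40), 87.10, tolerance = 0.011 / 87.10)
  expect_equal(cer(0, 3), 0)
  expect_error(cer(100, 0), "dominated")
  expect_true(wtp_check(cer(470.37, 5.40)))
  expect_true(wtp_check(57700, 57700))   # boundary passes
  expect_false(wtp_check(57701, 57700))
  # homogeneity: doubling cost doubles the ratio
  expect_equal(cer(940.74, 5.40), 2 * cer(470.37, 5.40), tolerance = 1e-3)
})

test_that("one-way sensitivity on the control probability moves deaths as published", {
  p <- markov_params("ipc")
  s <- one_way_sensitivity(p, "control_prob", shifts = c(-0.10, 0, 0.10))
  expect_equal(s$deaths, c(57, 55, 52))
  base <- run_markov_cohort(p)
  expect_equal(s$life_years[2], life_years(base))      # identity at no shift
  expect_warning(one_way_sensitivity(p, "control_prob", shifts = 0.5),
                 "clipped")
  sm <- one_way_sensitivity(p, "annual_cost_per_patient",
                            multipliers = c(0.8, 1.2))
  expect_equal(sm$cost[2] / sm$cost[1], 1.5, tolerance = 1e-12)
})
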