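test_that("discounting and inflation primitives", {
  expect_equal(discount_factor(0, 0.04), 1.0)
  expect_equal(discount_factor(1, 0.04), 1 / 1.04)
  expect_equal(discount_factor(1, 0.04), 0.96154, tolerance = 1e-5)
  expect_equal(discount_factor(10, 0.015), 1.015^-10)
  expect_equal(discount_factor(10, 0.015), 0.86167, tolerance = 1e-5)
  expect_error(discount_factor(1, -1), "exceed -1")
})

test_that("acute costs with overhead on published prices", {
  p <- raw_params()
  # CTP-arm patient with IVT
  expect_equal(acute_cost("ctp", missed = FALSE, ivt = TRUE, p),
               (251.40 + 9924.50 + 950.82) * 1.42, tolerance = 1e-9)
  expect_equal(acute_cost("ctp", missed = FALSE, ivt = TRUE, p),
               15799.94, tolerance = 1e-2)
  # control-arm missed patient without IVT incurs nothing
  expect_equal(acute_cost("control", missed = TRUE, ivt = FALSE, p), 0)
  expect_equal(acute_cost("control", missed = FALSE, ivt = TRUE, p),
               (9924.50 + 950.82) * 1.42)
  p1 <- raw_params(overhead_factor = 1.0)
  expect_equal(acute_cost("ctp", FALSE, TRUE, p1), 251.40 + 9924.50 + 950.82)
  # optional exemption of CTP from the overhead factor
  p2 <- raw_params(overhead_applies_to_ctp = FALSE)
  expect_equal(acute_cost("ctp", FALSE, FALSE, p2),
               9924.50 * 1.42 + 251.40)
})

test_that("NNI screening cost per detected LVO", {
  expect_equal(screening_cost_per_lvo(8.3, 251.40, 1.42), 7.3 * 251.40 * 1.42)
  expect_equal(screening_cost_per_lvo(8.3, 251.40, 1.42), 2606.01, tolerance = 1e-2)
  expect_equal(screening_cost_per_lvo(1, 251.40, 1.42), 0)
  expect_equal(screening_cost_per_lvo(8.3, 251.40, 1.42) -
               screening_cost_per_lvo(4.3, 251.40, 1.42),
               4.0 * 251.40 * 1.42, tolerance = 1e-9)
  expect_error(screening_cost_per_lvo(0.9, 251.40, 1.42), ">= 1")
})

test_that("mRS-keyed yearly cost and utility lookups", {
  p <- raw_params()
  expect_equal(annual_cost(3, 1, p), 82452)
  expect_equal(annual_cost(3, 2, p), 19235)
  expect_equal(annual_cost(3, 7, p), 16276) # year 3 onward
  expect_equal(annual_cost(6, 4, p, post_death = TRUE), 0)
  expect_equal(annual_cost(0, 2, p), annual_cost(1, 2, p))
  expect_equal(annual_qaly(0, p), annual_qaly(1, p))
  expect_equal(annual_qaly(6, p), 0)
  expect_equal(annual_qaly(4, p), 0.39)
})

test_that("accumulation over a constant trajectory matches the geometric series", {
  p <- raw_params(horizon_years = 5L)
  states <- matrix(0L, 1, 6)
  acc <- accumulate_states(states, p)
  expect_equal(acc$qalys, 0.94 * sum(1.04^-(0:4)), tolerance = 1e-10)
  expect_equal(acc$qalys, 4.35210, tolerance = 1e-4)
  d <- 1.015^-(0:4)
  expect_equal(acc$followup_costs,
               33402 * d[1] + 5934 * d[2] + 3633 * sum(d[3:5]), tolerance = 1e-9)

  p0 <- p
  p0$discount_rate_qaly <- 0
  p0$discount_rate_cost <- 0
  acc0 <- accumulate_states(states, p0)
  expect_equal(acc0$qalys, 0.94 * 5)
  expect_equal(acc0$followup_costs, 33402 + 5934 + 3 * 3633)
  # discounted totals never exceed undiscounted ones
  expect_lte(acc$qalys, acc0$qalys)
  expect_lte(acc$followup_costs, acc0$followup_costs)
})

test_that("death-year accounting: one mRS-6 charge, nothing after", {
  p <- raw_params(horizon_years = 4L)
  # dead at 90 days: zero QALYs, one year-1 mRS-6 charge
  dead <- matrix(6L, 1, 5)
  acc <- accumulate_states(dead, p)
  expect_equal(acc$qalys, 0)
  expect_equal(acc$followup_costs, 21112)

  cohort <- manual_cohort(6L)
  econ <- arm_economics(dead, cohort, missed = FALSE, "ctp", p)
  expect_equal(econ$discounted_costs,
               acute_cost("ctp", FALSE, TRUE, p) +
               screening_cost_per_lvo(8.3, 251.40, 1.42) + 21112)

  # death during year 2: year 1 keyed to the 90-day state, year 2 the
  # mRS-6 charge, nothing afterwards
  traj <- matrix(c(2L, 2L, 6L, 6L, 6L), 1, 5)
  acc2 <- accumulate_states(traj, p)
  expect_equal(acc2$followup_costs, 52804 + 423 * 1.015^-1, tolerance = 1e-9)
  expect_equal(acc2$qalys, 0.80)
})

test_that("per-patient deltas satisfy the NMB identity", {
  cohort <- synthesize_cohort(150, seed = 91)
  p <- raw_params(horizon_years = 3L)
  arms <- build_arms(cohort, p, seed = 1)
  sim <- simulate_arms(cohort, arms, p, seed = 2)
  tre <- arm_economics(sim$treated$states, cohort, arms$missed, "ctp", p)
  ctl <- arm_economics(sim$control$states, cohort, arms$missed, "control", p)
  expect_true(all(tre$discounted_qalys <= p$horizon_years + 1))
  expect_true(all(tre$discounted_costs >= 0))

  d <- delta_outcomes(tre, ctl, wtp = 80000)
  expect_equal(d$per_patient$nmb,
               80000 * d$per_patient$delta_qalys - d$per_patient$delta_costs,
               tolerance = 1e-9)
  d0 <- delta_outcomes(tre, ctl, wtp = 0)
  expect_equal(d0$per_patient$nmb, -d0$per_patient$delta_costs)

  bad <- ctl[-1, ]
  expect_error(delta_outcomes(tre, bad, 80000), "paired")

  # worked example: NMB = 80000 x 0.073 + 2671 when costs fall by 2671
  tiny_t <- data.frame(id = 1, discounted_costs = 1000, discounted_qalys = 1.073)
  tiny_c <- data.frame(id = 1, discounted_costs = 3671, discounted_qalys = 1.000)
  dd <- delta_outcomes(tiny_t, tiny_c, 80000)
  expect_equal(dd$per_patient$nmb, 80000 * 0.073 + 2671, tolerance = 1e-9)
})
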