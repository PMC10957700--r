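test_that("annual death probability: HR inflation, cap, merged mRS 0-1", {
  lt <- flat_life_table(q = 0.02)
  p <- raw_params()
  expect_equal(annual_death_prob(72, "male", 2023, 5, lt, p$hr_mortality),
               0.02 * 6.55)
  expect_equal(annual_death_prob(72, "male", 2023, 4, flat_life_table(0.5),
                                 p$hr_mortality), 1.0)
  expect_equal(annual_death_prob(70, "female", 2023, 0, lt, p$hr_mortality),
               annual_death_prob(70, "female", 2023, 1, lt, p$hr_mortality))
  expect_error(annual_death_prob(72, "male", 2023, 6, lt, p$hr_mortality))
})

test_that("annual recurrence probability: baseline, HR, cap, monotone in mRS", {
  p <- raw_params()
  # age 70 sits in the unit-factor band; mRS 0-1 HR is 1
  expect_equal(annual_recurrence_prob(1, 70, 0, p), 0.04)
  p2 <- p
  p2$hr_recurrence$hr <- 30
  expect_equal(annual_recurrence_prob(1, 70, 4, p2), 1.0)
  expect_gte(annual_recurrence_prob(3, 80, 4, p), annual_recurrence_prob(3, 80, 0, p))
})

test_that("recurrence redistribution truncates and preserves the mean", {
  dist <- rep(1 / 7, 7)
  set.seed(5)
  out <- apply_recurrence(rep(5L, 2000), dist)
  expect_true(all(out %in% 5:6))

  shifted <- shift_distribution_by_or(rep(1 / 7, 7), 1.67)
  set.seed(6)
  draws <- apply_recurrence(rep(0L, 2e5), shifted)
  expect_equal(mean(draws), sum(0:6 * shifted), tolerance = 0.01)

  # degenerate: all mass below the current state
  low <- c(1, 0, 0, 0, 0, 0, 0)
  expect_identical(apply_recurrence(c(3L, 4L), low, u = c(0.2, 0.9)), c(3L, 4L))
})

test_that("trajectories: absorbing death, inert limit, monotone worsening", {
  cohort <- synthesize_cohort(300, seed = 51)
  p <- raw_params(horizon_years = 8L)
  arms <- build_arms(cohort, p, seed = 1)
  sim <- simulate_arms(cohort, arms, p, seed = 2)
  for (arm in c("treated", "control")) {
    st <- sim[[arm]]$states
    expect_equal(ncol(st), 9)
    # states never improve in this deterioration-only long-term model
    expect_true(all(st[, -1] >= st[, -ncol(st)]))
    dead90 <- arms[[paste0("mrs90_", if (arm == "treated") "treated" else "control")]] == 6
    expect_true(all(st[dead90, ] == 6))
  }

  inert <- inert_params(horizon = 6)
  sim0 <- simulate_arms(cohort, build_arms(cohort, inert, seed = 1), inert, seed = 3)
  expect_true(all(sim0$treated$states == sim0$treated$states[, 1]))
})

test_that("common random numbers make identical arms identical", {
  cohort <- synthesize_cohort(200, seed = 61)
  p <- raw_params()
  p$sens_diff[] <- 0
  arms <- build_arms(cohort, p, seed = 1)
  sim <- simulate_arms(cohort, arms, p, seed = 7)
  expect_identical(sim$treated$states, sim$control$states)
  expect_identical(sim$treated$death_year, sim$control$death_year)

  sim2 <- simulate_arms(cohort, arms, p, seed = 7)
  expect_identical(sim$treated$states, sim2$treated$states)
})

test_that("mortality-only survival matches the analytic life-table product", {
  n <- 2e4
  cohort <- manual_cohort(rep(2L, n), age = 70, sex = "male")
  p <- raw_params(horizon_years = 5L)
  p$recurrence_baseline$prob <- 0
  p$life_table <- flat_life_table(q = 0.03)
  arms <- data.frame(id = cohort$id, missed = FALSE,
                     mrs90_treated = cohort$mrs90_treated,
                     mrs90_control = cohort$mrs90_treated)
  sim <- simulate_arms(cohort, arms, p, seed = 8)
  surv5 <- mean(sim$treated$states[, 6] < 6)
  analytic <- (1 - min(1, 0.03 * 2.17))^5
  expect_equal(surv5, analytic, tolerance = 0.01)

  # with unit HRs and no recurrence, survival matches the raw life table
  p1 <- p
  p1$hr_mortality[] <- 1
  sim1 <- simulate_arms(cohort, arms, p1, seed = 8)
  expect_equal(mean(sim1$treated$states[, 6] < 6), (1 - 0.03)^5, tolerance = 0.01)
})

test_that("raising a mortality hazard ratio weakly decreases life-years", {
  cohort <- synthesize_cohort(500, seed = 71)
  p <- raw_params(horizon_years = 10L)
  arms <- build_arms(cohort, p, seed = 1)
  py <- function(params) {
    sim <- simulate_arms(cohort, arms, params, seed = 9)
    sum(sim$treated$states[, -1] < 6)
  }
  base <- py(p)
  p_hi <- p
  p_hi$hr_mortality[] <- p$hr_mortality * 2
  expect_lte(py(p_hi), base)
})

test_that("single-patient wrapper and horizon edge cases", {
  pat <- manual_cohort(3L)
  p <- raw_params(horizon_years = 4L)
  tr6 <- simulate_trajectory(pat, 6L, p, seed = 1)
  expect_equal(tr6$mrs_by_year, rep(6L, 5))
  expect_length(tr6$recurrence_years, 0)

  p0 <- raw_params(horizon_years = 0L)
  tr <- simulate_trajectory(pat, 2L, p0, seed = 1)
  expect_equal(tr$mrs_by_year, 2L)

  cohort <- synthesize_cohort(50, seed = 81)
  arms <- build_arms(cohort, p0, seed = 1)
  sim <- simulate_arms(cohort, arms, p0, seed = 1)
  expect_equal(ncol(sim$treated$states), 1)
  long <- trajectories_long(sim, cohort$id)
  expect_equal(nrow(long), 100)
  expect_setequal(unique(long$arm), c("treated", "control"))
})
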