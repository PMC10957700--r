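test_that("baseline run: determinism and null-benefit limits", {
  cohort <- synthesize_cohort(200, seed = 101)
  p <- raw_params(horizon_years = 3L)

  a <- run_baseline(cohort, p, seed = 4, n_streams = 3)
  b <- run_baseline(cohort, p, seed = 4, n_streams = 3)
  expect_identical(a, b)

  p0 <- p
  p0$sens_diff[] <- 0
  null <- run_baseline(cohort, p0, seed = 4, n_streams = 3)
  expect_equal(null$delta_qalys, 0)
  ctp_spend <- screening_cost_per_lvo(p$nni, p$cost_ctp, p$overhead_factor) +
    p$cost_ctp * p$overhead_factor
  expect_equal(null$delta_costs, ctp_spend, tolerance = 1e-9)
  expect_equal(null$nmb, -ctp_spend, tolerance = 1e-9)

  pw <- p
  pw$wtp <- 0
  w0 <- run_baseline(cohort, pw, seed = 4, n_streams = 3)
  expect_equal(w0$nmb, -w0$delta_costs)

  p1 <- p
  p1$or_evt[["median"]] <- 1
  p1$or_evt[["ci_low"]] <- 1
  or1 <- run_baseline(cohort, p1, seed = 4, n_streams = 3)
  expect_equal(or1$delta_qalys, 0) # null treatment effect: no health difference
  expect_gt(or1$delta_costs, 0)   # but CTP spending and EVT costs remain
})

test_that("tornado analysis: influence, directions, ranking", {
  p <- raw_params(horizon_years = 3L)
  # a cohort that can never occupy mRS 5: outcomes only 0 or 6, and the
  # redistribution distribution inherits that support
  never5 <- manual_cohort(rep(c(0L, 6L), 40), latent_u = stats::runif(80))
  tor5 <- one_way_sensitivity(never5, p, parameters = c("cost_y1_mrs5", "utility_mrs5"),
                              seed = 2, n_streams = 2)
  expect_equal(tor5$swing, c(0, 0))

  cohort <- synthesize_cohort(250, seed = 111)
  tor <- one_way_sensitivity(cohort, p,
                             parameters = c("utility_mrs01", "cost_ctp", "cost_evt"),
                             seed = 2, n_streams = 2)
  u01 <- tor[tor$parameter == "utility_mrs01", ]
  expect_gt(u01$nmb_high, u01$nmb_low) # more QALYs in the healthy states help
  ctp <- tor[tor$parameter == "cost_ctp", ]
  expect_lt(ctp$nmb_high, ctp$nmb_low) # dearer CTP hurts the CTP arm
  expect_true(!is.unsorted(rev(tor$swing)))
  expect_type(attr(tor, "baseline_nmb"), "double")

  expect_error(one_way_sensitivity(cohort, p, parameters = "sens_diff"),
               "not a scalar tornado parameter")
})

test_that("PSA draws: degenerate spread recovers the means, OR quantiles match", {
  p <- raw_params()
  p$or_evt <- c(median = 1.67, ci_low = 1.67, ci_high = 1.67)
  p$hr_mortality_ci_factor <- 1
  p$hr_recurrence_sdlog <- 0
  p$utility_sd[] <- 0
  p$costs_y1_sd[] <- 0
  p$costs_y2_sd[] <- 0
  p$costs_y3plus_sd[] <- 0
  set.seed(1)
  drawn <- draw_psa_parameters(p)
  expect_equal(drawn$or_evt[["median"]], 1.67)
  expect_equal(drawn$utility_mean, p$utility_mean)
  expect_equal(drawn$costs_y1_mean, p$costs_y1_mean)
  expect_equal(drawn$hr_mortality, p$hr_mortality)
  expect_equal(drawn$hr_recurrence$hr, p$hr_recurrence$hr)

  pd <- raw_params()
  dists <- prepare_psa_dists(pd)
  set.seed(2)
  ors <- dist_draw(dists$or_evt, 1e5)
  expect_equal(unname(stats::quantile(ors, 0.025)), 1.21, tolerance = 0.02)
  expect_equal(unname(stats::quantile(ors, 0.975)), 2.30, tolerance = 0.02)

  set.seed(3)
  for (i in 1:5) {
    u <- dist_draw(dists$utilities[[i]], 1e4)
    expect_true(all(u >= 0 & u <= 1))
  }
  # mRS-6 utility never drawn away from 0
  set.seed(4)
  many <- replicate(50, draw_psa_parameters(pd, dists)$utility_mean[["mrs6"]])
  expect_true(all(many == 0))
})

test_that("PSA mechanics: single replicate, nulls, determinism, fraction", {
  cohort <- synthesize_cohort(150, seed = 121)
  p <- raw_params(horizon_years = 3L)

  one <- run_psa(cohort, p, n_reps = 1, seed = 5)
  expect_equal(one$summary$median[one$summary$quantity == "nmb"],
               one$replicates$nmb[1])

  p0 <- p
  p0$sens_diff[] <- 0
  null <- run_psa(cohort, p0, n_reps = 15, seed = 5)
  ctp_spend <- screening_cost_per_lvo(p$nni, p$cost_ctp, p$overhead_factor) +
    p$cost_ctp * p$overhead_factor
  expect_true(all(null$replicates$delta_qalys == 0))
  expect_true(all(abs(null$replicates$nmb + ctp_spend) < 1e-9))
  expect_equal(null$fraction_cost_effective, 0)

  again <- run_psa(cohort, p0, n_reps = 15, seed = 5)
  expect_identical(null$replicates, again$replicates)

  psa <- run_psa(cohort, p, n_reps = 30, seed = 6)
  expect_equal(psa$fraction_cost_effective, mean(psa$replicates$nmb > 0))
  expect_true(all(psa$replicates$delta_qalys >= 0))
})

test_that("delta QALYs are invariant to NNI under a shared seed schedule", {
  cohort <- synthesize_cohort(200, seed = 131)
  p <- raw_params(horizon_years = 5L)
  p83 <- p
  p43 <- p
  p43$nni <- 4.3
  a <- run_psa(cohort, p83, n_reps = 25, seed = 7)
  b <- run_psa(cohort, p43, n_reps = 25, seed = 7)
  expect_identical(a$replicates$delta_qalys, b$replicates$delta_qalys)
  shift <- screening_cost_per_lvo(8.3, p$cost_ctp, p$overhead_factor) -
    screening_cost_per_lvo(4.3, p$cost_ctp, p$overhead_factor)
  expect_equal(a$replicates$delta_costs - b$replicates$delta_costs,
               rep(shift, 25), tolerance = 1e-9)
})

test_that("scenario grid: shape and monotone structure with shared seeds", {
  cohort <- synthesize_cohort(200, seed = 141)
  p <- raw_params()
  grid <- scenario_grid(cohort, p, horizons = c(5, 10), nni_values = c(4.3, 8.3),
                        sens_offsets = c(0.08, -0.08), n_reps = 40, seed = 8)
  expect_equal(nrow(grid), 8)

  # NMB rises with the sensitivity offset at fixed horizon and NNI
  for (h in c(5, 10)) for (nni in c(4.3, 8.3)) {
    sub <- grid[grid$horizon_years == h & grid$nni == nni, ]
    expect_gt(sub$nmb_median[sub$sens_offset == 0.08],
              sub$nmb_median[sub$sens_offset == -0.08])
  }
  # NMB falls with NNI (pure extra screening cost) at fixed horizon and offset
  for (h in c(5, 10)) for (off in c(0.08, -0.08)) {
    sub <- grid[grid$horizon_years == h & grid$sens_offset == off, ]
    expect_lt(sub$nmb_median[sub$nni == 8.3], sub$nmb_median[sub$nni == 4.3])
    # identical seed schedule: health gain unaffected by NNI
    expect_equal(sub$delta_qalys_median[sub$nni == 8.3],
                 sub$delta_qalys_median[sub$nni == 4.3])
  }
})
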