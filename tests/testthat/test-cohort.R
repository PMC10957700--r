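binom_band99 <- function(n, p) {
  c(n * p - 2.576 * sqrt(n * p * (1 - p)), n * p + 2.576 * sqrt(n * p * (1 - p)))
}

test_that("synthesis is seed-reproducible and handles edge sizes", {
  a <- synthesize_cohort(200, seed = 5)
  b <- synthesize_cohort(200, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- synthesize_cohort(200, seed = 6)
  expect_false(identical(a$mrs90_treated, c$mrs90_treated))

  empty <- synthesize_cohort(0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(synthesize_cohort(-1), "nonnegative")
})

test_that("a default 701-patient cohort matches the study's descriptives", {
  cohort <- synthesize_cohort(701, seed = 2)
  tab <- table(factor(cohort$occlusion, levels = c("ICA", "M1", "M2")))
  for (s in c(ICA = 168, M1 = 367, M2 = 166)) NULL
  targets <- c(ICA = 168, M1 = 367, M2 = 166)
  for (nm in names(targets)) {
    band <- binom_band99(701, targets[[nm]] / 701)
    expect_gte(tab[[nm]], band[1])
    expect_lte(tab[[nm]], band[2])
  }
  # overall 90-day death fraction near 142/645 = 22.0%
  p6 <- mean(cohort$mrs90_treated == 6)
  band <- binom_band99(701, 0.2202) / 701
  expect_gte(p6, band[1])
  expect_lte(p6, band[2])
  expect_true(all(cohort$latent_u > 0 & cohort$latent_u < 1))
  expect_true(all(cohort$age >= 18 & cohort$age <= 100))
})

test_that("large samples concentrate on the calibrated demographics", {
  cohort <- synthesize_cohort(1e5, seed = 3)
  expect_gte(median(cohort$age), 71)
  expect_lte(median(cohort$age), 73)
  expect_gte(mean(cohort$sex == "male"), 0.546)
  expect_lte(mean(cohort$sex == "male"), 0.566)
})

test_that("per-stratum mRS distributions converge to the specification", {
  spec <- default_cohort_spec()
  cohort <- synthesize_cohort(1e6, seed = 4)
  for (s in c("ICA", "M1", "M2")) {
    emp <- table(factor(cohort$mrs90_treated[cohort$occlusion == s], levels = 0:6))
    emp <- as.numeric(emp) / sum(emp)
    tv <- sum(abs(emp - spec$mrs90_dist_by_stratum[s, ])) / 2
    expect_lt(tv, 0.01)
  }
})

test_that("cohort CSV round-trips and flags bad input", {
  cohort <- synthesize_cohort(701, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12,
               ignore_attr = TRUE)

  writeLines(c("id,age,sex,occlusion,mrs90_treated,ivt,latent_u",
               "1,72,male,M1,3,true,0.4"), path)
  one <- read_cohort(path)
  expect_equal(nrow(one), 1)
  expect_identical(one$mrs90_treated, 3L)
  expect_true(one$ivt)

  # missing 90-day outcomes are dropped with a warning stating the count
  df <- as.data.frame(cohort)
  df$mrs90_treated[1:56] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(kept <- read_cohort(path), "56 row")
  expect_equal(nrow(kept), 645)

  # absent latent_u column gets fresh uniforms
  utils::write.csv(df[57:60, setdiff(names(df), "latent_u")], path, row.names = FALSE)
  expect_warning(fresh <- read_cohort(path), "latent_u")
  expect_true(all(fresh$latent_u > 0 & fresh$latent_u < 1))

  writeLines(c("id,age,sex,occlusion,mrs90_treated,ivt,latent_u",
               "1,72,male,M1,3,true,0.4",
               "2,70,male,BASILAR,2,true,0.2"), path)
  expect_error(read_cohort(path), "line 3")
})

test_that("cohort summary reports published-style percentages", {
  # the 645 patients with known outcome and the published mRS counts
  mrs <- rep(0:6, times = c(47, 115, 154, 69, 76, 42, 142))
  cohort <- manual_cohort(mrs)
  s <- summarize_cohort(cohort)
  expect_equal(s$mrs$pct[s$mrs$mrs == 0], 7.3)
  expect_equal(s$mrs$pct[s$mrs$mrs == 6], 22.0)
  expect_equal(s$n, 645)

  single <- summarize_cohort(manual_cohort(3))
  expect_equal(single$mrs$pct[single$mrs$mrs == 3], 100)
  expect_error(summarize_cohort(synthesize_cohort(0)), "empty")

  big <- summarize_cohort(synthesize_cohort(701, seed = 10))
  band <- binom_band99(701, 367 / 701)
  expect_gte(big$strata$n[big$strata$occlusion == "M1"], band[1])
  expect_lte(big$strata$n[big$strata$occlusion == "M1"], band[2])
})
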