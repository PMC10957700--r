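# Shared fixtures: parameter sets at the raw (reference-year) price level for
# arithmetic checks, and small deterministic building blocks.

raw_params <- function(...) {
  p <- default_parameters()
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Life table with a constant annual death probability for closed-form checks.
flat_life_table <- function(q = 0.02, min_age = 18, max_age = 110) {
  ages <- min_age:max_age
  out <- rbind(data.frame(age = ages, sex = "female", qx = q),
               data.frame(age = ages, sex = "male", qx = q))
  out
}

# Parameters with all long-term transitions switched off.
inert_params <- function(horizon = 5L) {
  p <- raw_params(horizon_years = as.integer(horizon))
  p$hr_mortality[] <- 0
  p$recurrence_baseline$prob <- 0
  p
}

# A cohort with hand-set columns.
manual_cohort <- function(mrs, occlusion = "M1", age = 72, sex = "male",
                          ivt = TRUE, latent_u = NULL) {
  n <- length(mrs)
  if (is.null(latent_u)) latent_u <- rep(0.5, n)
  df <- data.frame(id = seq_len(n),
                   age = rep_len(age, n), sex = rep_len(sex, n),
                   occlusion = rep_len(occlusion, n),
                   mrs90_treated = as.integer(mrs),
                   ivt = rep_len(ivt, n), latent_u = latent_u)
  class(df) <- c("ctp_cohort", "data.frame")
  attr(df, "provenance") <- "synthetic"
  df
}

# Random 7-cell probability vectors for property checks.
random_dists <- function(k, seed = 7) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    x <- stats::rgamma(7, shape = 1)
    x / sum(x)
  })
}
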