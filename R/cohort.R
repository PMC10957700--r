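#' Specification of the synthetic EVT-treated cohort
#'
#' Defaults emulate the descriptive statistics of the 701-patient Dutch
#' EVT-treated registry cohort: occlusion strata ICA/M1/M2 of 168/367/166
#' patients; per-stratum 90-day mRS distributions from the published counts
#' (ICA 7/21/35/20/20/11/38 of 152 with known outcome, M1
#' 28/61/87/35/43/20/65 of 339, M2 12/33/32/14/13/11/39 of 154); age from a
#' truncated normal (mean 71.5, sd 13.5, bounds 18-100) with per-stratum
#' shifts of -2/0/+1 years mimicking the stratum medians 70/72/73, calibrated
#' so the overall median is about 72 with IQR about 62-81; 55.6\% male and
#' 67.3\% IVT, both independent Bernoulli.
#'
#' @param n_strata Stratum sizes used to derive the stratum weights.
#' @return A list of class `ctp_cohort_spec`.
#' @export
default_cohort_spec <- function(n_strata = c(ICA = 168, M1 = 367, M2 = 166)) {
  mrs_counts <- rbind(
    ICA = c(7, 21, 35, 20, 20, 11, 38),
    M1  = c(28, 61, 87, 35, 43, 20, 65),
    M2  = c(12, 33, 32, 14, 13, 11, 39)
  )
  colnames(mrs_counts) <- paste0("mrs", 0:6)
  spec <- list(
    strata_weights = n_strata / sum(n_strata),
    mrs90_dist_by_stratum = mrs_counts / rowSums(mrs_counts),
    age_mean = 71.5,
    age_sd = 13.5,
    age_bounds = c(18, 100),
    age_shift_by_stratum = c(ICA = -2, M1 = 0, M2 = 1),
    male_fraction = 0.556,
    ivt_fraction = 0.673
  )
  class(spec) <- "ctp_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (any(spec$strata_weights < 0)) stop("strata_weights must be nonnegative")
  if (abs(sum(spec$strata_weights) - 1) > 1e-9) stop("strata_weights must sum to 1")
  if (any(abs(rowSums(spec$mrs90_dist_by_stratum) - 1) > 1e-9)) {
    stop("each stratum mRS distribution must sum to 1")
  }
  if (any(spec$mrs90_dist_by_stratum < 0)) stop("mRS probabilities must be nonnegative")
  for (f in c("male_fraction", "ivt_fraction")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  invisible(spec)
}

#' Synthesize a patient cohort
#'
#' Draws a reproducible synthetic cohort from a [default_cohort_spec()]-style
#' specification: occlusion site from the stratum weights, 90-day mRS with
#' EVT from the per-stratum distribution, age from the shifted truncated
#' normal (rounded to whole years), sex and IVT as independent Bernoulli
#' draws, and a latent uniform deviate per patient used later for
#' rank-preserving counterfactual mapping.
#'
#' @param n Number of patients (default 701, the study cohort size).
#' @param spec Cohort specification.
#' @param seed Integer seed; same seed, same cohort.
#' @return A `data.frame` of class `ctp_cohort` with columns `id`, `age`,
#'   `sex`, `occlusion`, `mrs90_treated`, `ivt`, `latent_u`.
#' @export
synthesize_cohort <- function(n = 701L, spec = default_cohort_spec(), seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be a nonnegative count")
  validate_cohort_spec(spec)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  sites <- names(spec$strata_weights)
  if (n == 0L) {
    out <- data.frame(id = integer(), age = integer(), sex = character(),
                      occlusion = character(), mrs90_treated = integer(),
                      ivt = logical(), latent_u = numeric())
    return(as_ctp_cohort(out, provenance = "synthetic", seed = seed))
  }
  occ_idx <- sample.int(length(sites), n, replace = TRUE, prob = spec$strata_weights)
  mrs <- integer(n)
  for (s in seq_along(sites)) {
    i <- which(occ_idx == s)
    if (length(i)) {
      mrs[i] <- sample(0:6, length(i), replace = TRUE,
                       prob = spec$mrs90_dist_by_stratum[s, ])
    }
  }
  mu <- spec$age_mean + spec$age_shift_by_stratum[occ_idx]
  lo <- stats::pnorm(spec$age_bounds[1], mu, spec$age_sd)
  hi <- stats::pnorm(spec$age_bounds[2], mu, spec$age_sd)
  age <- round(stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, spec$age_sd))
  age <- pmin(pmax(age, spec$age_bounds[1]), spec$age_bounds[2])
  out <- data.frame(
    id = seq_len(n),
    age = as.integer(age),
    sex = ifelse(stats::runif(n) < spec$male_fraction, "male", "female"),
    occlusion = sites[occ_idx],
    mrs90_treated = mrs,
    ivt = stats::runif(n) < spec$ivt_fraction,
    latent_u = stats::runif(n)
  )
  as_ctp_cohort(out, provenance = "synthetic", seed = seed)
}

as_ctp_cohort <- function(df, provenance, seed = NA_integer_) {
  class(df) <- c("ctp_cohort", "data.frame")
  attr(df, "provenance") <- provenance
  attr(df, "seed") <- seed
  df
}

validate_cohort <- function(cohort) {
  need <- c("id", "age", "sex", "occlusion", "mrs90_treated", "ivt", "latent_u")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique")
  bad <- which(!(cohort$age >= 18 & cohort$age <= 110) |
               !(cohort$sex %in% c("male", "female")) |
               !(cohort$occlusion %in% occlusion_sites) |
               !(cohort$mrs90_treated %in% 0:6) |
               !(cohort$latent_u > 0 & cohort$latent_u < 1))
  if (length(bad)) stop("invalid cohort row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The CSV carries columns `id,age,sex,occlusion,mrs90_treated,ivt` and
#' optionally `latent_u`. On read, rows with a missing 90-day mRS are dropped
#' with a warning stating the count (mirroring a registry in which outcome is
#' unavailable for some patients); a missing `latent_u` column is replaced by
#' freshly drawn uniforms with a warning. Malformed rows raise an error
#' naming the first offending line.
#'
#' @param path CSV file path.
#' @return A `ctp_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "occlusion", "mrs90_treated", "ivt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  drop <- is.na(df$mrs90_treated)
  if (any(drop)) {
    warning(sprintf("dropped %d row(s) with missing 90-day mRS", sum(drop)))
    df <- df[!drop, , drop = FALSE]
  }
  if (!"latent_u" %in% names(df) || all(is.na(df$latent_u))) {
    warning("cohort CSV has no latent_u column; drawing fresh uniform deviates")
    df$latent_u <- stats::runif(nrow(df))
  }
  if (is.character(df$ivt)) df$ivt <- tolower(df$ivt) %in% c("true", "t", "1", "yes")
  bad <- which(!(df$sex %in% c("male", "female")) |
               !(df$occlusion %in% occlusion_sites) |
               !(df$mrs90_treated %in% 0:6) |
               is.na(df$age))
  if (length(bad)) {
    stop(sprintf("malformed cohort row at line %d of %s", bad[1] + 1L, path))
  }
  df <- df[, c(need[1:5], "ivt", "latent_u")]
  out <- as_ctp_cohort(df, provenance = "file")
  validate_cohort(out)
  out
}

#' @rdname read_cohort
#' @param cohort A `ctp_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive summary of a cohort
#'
#' Counts and percentages by occlusion stratum and 90-day mRS (denominators
#' over non-missing values), age median and IQR, male and IVT fractions.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @return A list with elements `n`, `strata` (data frame of counts and
#'   percentages), `mrs` (counts and percentages by mRS, total and per
#'   stratum), `age_median`, `age_iqr`, `male_pct`, `ivt_pct`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cannot summarise an empty cohort")
  n <- nrow(cohort)
  strata_counts <- table(factor(cohort$occlusion, levels = occlusion_sites))
  strata <- data.frame(occlusion = names(strata_counts),
                       n = as.integer(strata_counts),
                       pct = round(100 * as.integer(strata_counts) / n, 1))
  mrs_tab <- table(factor(cohort$mrs90_treated, levels = 0:6))
  mrs <- data.frame(mrs = 0:6, n = as.integer(mrs_tab),
                    pct = round(100 * as.integer(mrs_tab) / sum(mrs_tab), 1))
  for (s in occlusion_sites) {
    sub <- cohort$mrs90_treated[cohort$occlusion == s]
    cnt <- as.integer(table(factor(sub, levels = 0:6)))
    mrs[[paste0("n_", s)]] <- cnt
    mrs[[paste0("pct_", s)]] <- if (length(sub)) round(100 * cnt / length(sub), 1) else NA_real_
  }
  list(
    n = n,
    strata = strata,
    mrs = mrs,
    age_median = stats::median(cohort$age),
    age_iqr = unname(stats::quantile(cohort$age, c(0.25, 0.75))),
    male_pct = round(100 * mean(cohort$sex == "male"), 1),
    ivt_pct = round(100 * mean(cohort$ivt), 1)
  )
}
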