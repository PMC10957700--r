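#' Shift an mRS distribution by a common odds ratio
#'
#' Removes (or applies) a proportional-odds treatment effect on the 7-level
#' 90-day mRS distribution: at every cutpoint `k` in 0..5 the cumulative
#' probability `C(k) = P(mRS <= k)` is moved on the log-odds scale,
#' `C'(k) = logistic(logit(C(k)) - log(or))`, and the shifted distribution is
#' recovered as first differences of `C'`. With `or > 1` this transfers mass
#' toward worse outcomes, representing withdrawal of the EVT benefit
#' summarised by its adjusted common odds ratio. Degenerate cutpoints
#' (`C(k)` equal to 0 or 1) map to themselves.
#'
#' The operation composes multiplicatively: shifting by `or1` then `or2`
#' equals shifting by `or1 * or2`.
#'
#' @param dist Length-7 probability vector over mRS 0..6 summing to 1.
#' @param or_evt Positive common odds ratio.
#' @return Length-7 probability vector.
#' @export
shift_distribution_by_or <- function(dist, or_evt) {
  if (length(dist) != 7L || any(!is.finite(dist)) || any(dist < 0)) {
    stop("dist must be 7 nonnegative probabilities over mRS 0..6")
  }
  if (abs(sum(dist) - 1) > 1e-9) stop("dist must sum to 1 within 1e-9")
  if (!is.finite(or_evt) || or_evt <= 0) stop("or_evt must be positive")
  cc <- cumsum(dist)[1:6]
  shifted <- cc
  interior <- cc > 0 & cc < 1
  shifted[interior] <- stats::plogis(stats::qlogis(cc[interior]) - log(or_evt))
  shifted <- cummax(shifted) # guard against floating-point non-monotonicity
  diff(c(0, shifted, 1))
}

#' Counterfactual 90-day mRS without EVT
#'
#' Maps each patient's observed (EVT-treated) 90-day mRS to a counterfactual
#' no-EVT mRS through a rank-preserving latent-uniform coupling: the
#' patient's latent deviate is re-anchored uniformly within the treated CDF
#' cell of the observed state, and the counterfactual state is the inverse
#' CDF of the odds-shifted distribution at that point. With `or_evt >= 1`
#' the coupling guarantees the counterfactual mRS is never better than the
#' observed one; marginally the counterfactual states follow
#' [shift_distribution_by_or()] exactly.
#'
#' @param mrs90_treated Integer vector of observed mRS (0..6).
#' @param latent_u Uniform deviates in (0, 1), one per patient.
#' @param treated_dist The patients' stratum 90-day mRS distribution under
#'   EVT (length 7).
#' @param or_evt Common EVT odds ratio to remove.
#' @return Integer vector of counterfactual mRS values.
#' @export
counterfactual_mrs <- function(mrs90_treated, latent_u, treated_dist, or_evt) {
  stopifnot(length(mrs90_treated) == length(latent_u),
            all(mrs90_treated %in% 0:6),
            all(latent_u > 0 & latent_u < 1))
  ct <- c(0, cumsum(treated_dist))
  ct[8] <- 1
  lo <- ct[mrs90_treated + 1L]
  hi <- ct[mrs90_treated + 2L]
  u <- lo + latent_u * (hi - lo)
  cs <- cumsum(shift_distribution_by_or(treated_dist, or_evt))
  cs[7] <- 1
  new <- findInterval(u, cs, left.open = TRUE)
  as.integer(pmin(new, 6L))
}

#' Select patients whose LVO the control strategy would miss
#'
#' Independent Bernoulli draw per patient with the occlusion-site-specific
#' sensitivity difference as success probability.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param sens_diff Named fractions per occlusion site (`ICA`, `M1`, `M2`).
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return Integer vector of missed patient ids.
#' @export
select_missed <- function(cohort, sens_diff, seed = NULL) {
  if (any(sens_diff < 0 | sens_diff > 1)) {
    stop("sensitivity differences must lie in [0, 1]")
  }
  if (!all(unique(cohort$occlusion) %in% names(sens_diff))) {
    stop("sens_diff must be named by occlusion site (ICA, M1, M2)")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- sens_diff[cohort$occlusion]
  cohort$id[stats::runif(nrow(cohort)) < p]
}

#' Empirical per-stratum 90-day mRS distributions
#'
#' @param cohort A `ctp_cohort` data frame.
#' @return 3 x 7 matrix of probabilities, rows `ICA`, `M1`, `M2`.
#' @export
stratum_mrs_dists <- function(cohort) {
  out <- matrix(NA_real_, nrow = 3, ncol = 7,
                dimnames = list(occlusion_sites, paste0("mrs", 0:6)))
  for (s in occlusion_sites) {
    sub <- cohort$mrs90_treated[cohort$occlusion == s]
    if (length(sub)) {
      out[s, ] <- as.integer(table(factor(sub, levels = 0:6))) / length(sub)
    }
  }
  out
}

# Cumulative no-EVT (odds-shifted) distributions per stratum; strata absent
# from the cohort keep NA rows (never indexed by the engine).
no_evt_redistribution <- function(dists, or) {
  out <- matrix(NA_real_, nrow(dists), 7, dimnames = dimnames(dists))
  for (s in rownames(dists)) {
    if (!anyNA(dists[s, ])) {
      out[s, ] <- cumsum(shift_distribution_by_or(dists[s, ], or))
    }
  }
  out
}

#' Build treated and control arm assignments
#'
#' The CTP (NCCT+CTA+CTP) arm keeps every patient's observed 90-day mRS. In
#' the control (NCCT+CTA) arm, patients selected as missed receive a
#' counterfactual no-EVT mRS via [counterfactual_mrs()], using their
#' stratum's empirical mRS distribution computed from the input cohort and
#' the common EVT odds ratio in `params`; all other patients keep their
#' observed state. The CTP-screened population without an LVO contributes
#' screening costs only and is not simulated.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param params A `ctp_params` object.
#' @param seed Seed for the missed-selection Bernoulli draws; `NULL` uses the
#'   current RNG state.
#' @return `data.frame` with columns `id`, `missed`, `mrs90_treated`,
#'   `mrs90_control`.
#' @export
build_arms <- function(cohort, params, seed = NULL) {
  validate_cohort(cohort)
  missed_ids <- select_missed(cohort, params$sens_diff, seed)
  missed <- cohort$id %in% missed_ids
  ctrl <- cohort$mrs90_treated
  dists <- stratum_mrs_dists(cohort)
  or <- params$or_evt[["median"]]
  for (s in occlusion_sites) {
    i <- which(missed & cohort$occlusion == s)
    if (length(i)) {
      ctrl[i] <- counterfactual_mrs(cohort$mrs90_treated[i], cohort$latent_u[i],
                                    dists[s, ], or)
    }
  }
  data.frame(id = cohort$id, missed = missed,
             mrs90_treated = cohort$mrs90_treated, mrs90_control = ctrl)
}
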