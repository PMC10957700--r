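#' Default model parameters
#'
#' All quantities of the published input-parameter table, with their
#' distribution metadata, plus the fixture tables (life table, inflation
#' series, recurrence baseline and hazard ratios). Costs are stored at the
#' 2015 reference-year price level; [load_parameters()] inflates them to the
#' simulation start year.
#'
#' Key defaults: willingness to pay 80,000 EUR/QALY; discount rates 4\%/year
#' (QALYs) and 1.5\%/year (costs); 42\% acute-care overhead; number needed to
#' image (NNI) 8.3; sensitivity difference of CTP-based occlusion detection
#' 8\% (ICA) and 16\% (M1, M2); common EVT odds ratio 1.67 (95\% CI
#' 1.21-2.30); EVT/IVT/CTP unit prices 9924.50/950.82/251.40 EUR; mortality
#' hazard ratios by mRS 1.54/2.17/3.18/4.55/6.55; mRS-keyed yearly follow-up
#' costs (gamma) and utilities (beta).
#'
#' @return An object of class `ctp_params` (a named list).
#' @export
default_parameters <- function() {
  p <- list(
    wtp = 80000,
    horizon_years = 5L,
    start_year = 2022L,
    cost_reference_year = 2015L,
    discount_rate_qaly = 0.04,
    discount_rate_cost = 0.015,
    overhead_factor = 1.42,
    overhead_applies_to_ctp = TRUE,
    nni = 8.3,
    sens_diff = c(ICA = 0.08, M1 = 0.16, M2 = 0.16),
    or_evt = c(median = 1.67, ci_low = 1.21, ci_high = 2.30),
    cost_evt = 9924.50,
    cost_ivt = 950.82,
    cost_ctp = 251.40,
    cost_ncct_cta = 0,
    utility_mean = stats::setNames(c(0.94, 0.80, 0.68, 0.39, 0.24, 0), mrs_levels),
    utility_sd   = stats::setNames(c(0.09, 0.17, 0.24, 0.26, 0.25, 0.01), mrs_levels),
    costs_y1_mean = stats::setNames(c(33402, 52804, 82452, 112414, 96640, 21112), mrs_levels),
    costs_y1_sd   = stats::setNames(c(31930, 23571, 35333, 35786, 30463, 17350), mrs_levels),
    costs_y2_mean = stats::setNames(c(5934, 8543, 19235, 43193, 56425, 423), mrs_levels),
    costs_y2_sd   = stats::setNames(c(15918, 14844, 15999, 45640, 24252, 3196), mrs_levels),
    costs_y3plus_mean = stats::setNames(c(3633, 7318, 16276, 31037, 54997, 374), mrs_levels),
    costs_y3plus_sd   = stats::setNames(c(9087, 13770, 11753, 19928, 24874, 3118), mrs_levels),
    hr_mortality = stats::setNames(c(1.54, 2.17, 3.18, 4.55, 6.55), mrs_levels[1:5]),
    # The mortality HR source reports log-normal uncertainty but the CIs are
    # not printed; stand-in 95% CI of HR/1.3 .. HR*1.3 for PSA draws.
    hr_mortality_ci_factor = 1.3,
    hr_recurrence_sdlog = 0.15,
    n_psa = 1000L,
    costs_inflated = FALSE
  )
  p$life_table <- make_life_table()
  p$inflation <- default_inflation_series()
  p$recurrence_baseline <- default_recurrence_baseline()
  p$hr_recurrence <- default_hr_recurrence()
  class(p) <- "ctp_params"
  p
}

# Scalar/vector fields that a YAML configuration may override.
config_keys <- function() {
  c("wtp", "horizon_years", "start_year", "cost_reference_year",
    "discount_rate_qaly", "discount_rate_cost", "overhead_factor",
    "overhead_applies_to_ctp", "nni", "sens_diff", "or_evt",
    "cost_evt", "cost_ivt", "cost_ctp", "cost_ncct_cta",
    "utility_mean", "utility_sd",
    "costs_y1_mean", "costs_y1_sd", "costs_y2_mean", "costs_y2_sd",
    "costs_y3plus_mean", "costs_y3plus_sd",
    "hr_mortality", "hr_mortality_ci_factor", "hr_recurrence_sdlog",
    "n_psa", "costs_inflated")
}

fixture_keys <- function() {
  c("life_table_csv", "inflation_csv", "recurrence_csv")
}

#' Load and validate model parameters
#'
#' Builds the default parameter set, applies overrides from a flat-key YAML
#' configuration (unknown keys are rejected), loads any fixture CSV overrides
#' (`life_table_csv`, `inflation_csv`, `recurrence_csv`; paths resolved
#' relative to the configuration file), validates every invariant, and
#' inflates all reference-year costs to the simulation start year using the
#' inflation series (skipped when the configuration marks costs as already
#' inflated).
#'
#' @param config_path Optional YAML file path.
#' @param inflate_costs Inflate 2015 reference costs to `start_year`
#'   (default `TRUE`).
#' @return A validated `ctp_params` object.
#' @export
load_parameters <- function(config_path = NULL, inflate_costs = TRUE) {
  p <- default_parameters()
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) stop("configuration file not found: ", config_path)
    cfg <- yaml::read_yaml(config_path)
    if (length(cfg)) {
      unknown <- setdiff(names(cfg), c(config_keys(), fixture_keys()))
      if (length(unknown)) {
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
      }
      for (key in intersect(names(cfg), config_keys())) {
        val <- cfg[[key]]
        tmpl <- p[[key]]
        if (is.list(val)) val <- unlist(val)
        if (length(tmpl) > 1L) {
          if (is.null(names(val))) {
            if (length(val) != length(tmpl)) {
              stop("configuration key ", key, " must have length ", length(tmpl))
            }
            names(val) <- names(tmpl)
          }
          missing_names <- setdiff(names(val), names(tmpl))
          if (length(missing_names)) {
            stop("configuration key ", key, " has unknown element(s): ",
                 paste(missing_names, collapse = ", "))
          }
          tmpl[names(val)] <- val
          p[[key]] <- tmpl
        } else {
          p[[key]] <- if (is.integer(tmpl)) as.integer(val) else val
        }
      }
      cfg_dir <- dirname(normalizePath(config_path))
      resolve <- function(f) if (file.exists(f)) f else file.path(cfg_dir, f)
      if (!is.null(cfg$life_table_csv)) p$life_table <- read_life_table(resolve(cfg$life_table_csv))
      if (!is.null(cfg$inflation_csv)) p$inflation <- read_inflation_series(resolve(cfg$inflation_csv))
      if (!is.null(cfg$recurrence_csv)) p$recurrence_baseline <- read_recurrence_baseline(resolve(cfg$recurrence_csv))
    }
  }
  validate_parameters(p)
  if (inflate_costs && !isTRUE(p$costs_inflated)) {
    p <- inflate_parameter_costs(p)
  }
  p
}

# Inflate all reference-year cost fields (means and sds) to the start year.
inflate_parameter_costs <- function(p) {
  f <- inflate_cost(1, p$cost_reference_year, p$start_year, p$inflation)
  for (key in c("cost_evt", "cost_ivt", "cost_ctp", "cost_ncct_cta",
                "costs_y1_mean", "costs_y1_sd", "costs_y2_mean", "costs_y2_sd",
                "costs_y3plus_mean", "costs_y3plus_sd")) {
    p[[key]] <- p[[key]] * f
  }
  p$costs_inflated <- TRUE
  attr(p, "inflation_factor") <- f
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant (probabilities in `[0, 1]`, nonnegative
#' costs, utilities in `[-0.1, 1]` with the mRS-6 utility fixed at 0,
#' nonnegative hazard ratios, NNI at least 1) and stops with the offending
#' field name on violation.
#'
#' @param p A `ctp_params` object.
#' @return `p`, invisibly.
#' @export
validate_parameters <- function(p) {
  fail <- function(field, why) stop("invalid parameter ", field, ": ", why, call. = FALSE)
  chk_prob <- function(field) {
    v <- p[[field]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) fail(field, "must lie in [0, 1]")
  }
  chk_nonneg <- function(field) {
    if (any(!is.finite(p[[field]])) || any(p[[field]] < 0)) fail(field, "must be >= 0")
  }
  for (f in c("discount_rate_qaly", "discount_rate_cost", "sens_diff")) chk_prob(f)
  for (f in c("wtp", "cost_evt", "cost_ivt", "cost_ctp", "cost_ncct_cta",
              "costs_y1_mean", "costs_y1_sd", "costs_y2_mean", "costs_y2_sd",
              "costs_y3plus_mean", "costs_y3plus_sd", "hr_mortality",
              "utility_sd")) chk_nonneg(f)
  if (any(p$utility_mean < -0.1 | p$utility_mean > 1)) {
    fail("utility_mean", "utilities must lie in [-0.1, 1]")
  }
  if (p$utility_mean[["mrs6"]] != 0) fail("utility_mean", "mRS-6 utility must be 0")
  if (p$nni < 1) fail("nni", "number needed to image must be >= 1")
  if (p$horizon_years < 0) fail("horizon_years", "must be >= 0")
  if (p$overhead_factor < 1) fail("overhead_factor", "must be >= 1")
  or <- p$or_evt
  if (any(or <= 0) || !(or[["ci_low"]] <= or[["median"]] && or[["median"]] <= or[["ci_high"]])) {
    fail("or_evt", "requires 0 < ci_low <= median <= ci_high")
  }
  if (!setequal(names(p$sens_diff), occlusion_sites)) {
    fail("sens_diff", "must be named ICA, M1, M2")
  }
  if (any(p$recurrence_baseline$prob < 0 | p$recurrence_baseline$prob > 1)) {
    fail("recurrence_baseline", "probabilities must lie in [0, 1]")
  }
  if (any(p$hr_recurrence$hr < 0)) fail("hr_recurrence", "must be >= 0")
  if (any(p$life_table$qx < 0 | p$life_table$qx > 1)) fail("life_table", "qx outside [0, 1]")
  needed <- p$cost_reference_year:(p$start_year + p$horizon_years)
  if (!all(needed %in% p$inflation$year)) {
    fail("inflation", paste("series must cover years",
                            min(needed), "to", max(needed)))
  }
  invisible(p)
}

#' Write parameters to a YAML configuration
#'
#' Writes all scalar and vector fields; fixture tables are not serialised
#' (they are deterministic defaults or referenced by CSV path). A written
#' configuration reloads to an equal parameter set: the `costs_inflated` flag
#' is preserved so inflation is not applied twice.
#'
#' @param p A `ctp_params` object.
#' @param path Output YAML path.
#' @export
write_parameters <- function(p, path) {
  out <- lapply(config_keys(), function(k) {
    v <- p[[k]]
    if (!is.null(names(v))) as.list(v) else v
  })
  names(out) <- config_keys()
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Number needed to image from prevalence figures
#'
#' The number of suspected-stroke patients that must be screened with CTP to
#' detect one EVT-eligible LVO: the reciprocal of the product of the share of
#' suspected-stroke presentations that are acute ischemic stroke and the
#' share of those with a large vessel occlusion. With the most conservative
#' literature values (50\% AIS, 24\% LVO) this gives 8.3.
#'
#' @param ais_share Fraction of suspected-stroke patients with AIS.
#' @param lvo_share Fraction of AIS patients with an EVT-eligible LVO.
#' @return The NNI.
#' @export
nni_from_prevalence <- function(ais_share, lvo_share) {
  if (any(ais_share <= 0 | ais_share > 1) || any(lvo_share <= 0 | lvo_share > 1)) {
    stop("shares must lie in (0, 1]")
  }
  1 / (ais_share * lvo_share)
}

#' Sensitivity difference of occlusion detection
#'
#' Gain in LVO-detection sensitivity from adding CTP, expressed relative to
#' the sensitivity of the full NCCT+CTA+CTP protocol:
#' `(sens_with_ctp - sens_without_ctp) / sens_with_ctp`. Inputs may be on the
#' fraction or percent scale; the result is the corresponding fraction of
#' `sens_with_ctp`.
#'
#' @param sens_with_ctp Sensitivity of NCCT+CTA+CTP detection.
#' @param sens_without_ctp Sensitivity of NCCT+CTA detection.
#' @return Fractional sensitivity difference.
#' @export
sensitivity_difference <- function(sens_with_ctp, sens_without_ctp) {
  if (any(sens_with_ctp <= 0)) stop("sens_with_ctp must be positive")
  if (any(sens_without_ctp > sens_with_ctp)) {
    stop("sens_without_ctp cannot exceed sens_with_ctp")
  }
  (sens_with_ctp - sens_without_ctp) / sens_with_ctp
}

#' Suspected-stroke screening population counts
#'
#' Emergency-ward counts of acute ischemic stroke versus transient ischemic
#' attack or stroke mimic among suspected-stroke presentations, from one
#' Dutch trial region and one ambulance-service region; used to compute the
#' AIS share entering the NNI.
#'
#' @return `data.frame` with columns `region`, `year`, `ais`, `non_ais`.
#' @export
screening_population_counts <- function() {
  path <- system.file("extdata", "screening_population.csv", package = "ctpcea",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.ctp_params <- function(x, ...) {
  cat("<ctp_params>\n")
  cat(sprintf("  horizon %d y from %d; WTP %s EUR/QALY; NNI %.1f\n",
              x$horizon_years, x$start_year, format(x$wtp, big.mark = ","), x$nni))
  cat(sprintf("  sens diff ICA/M1/M2: %.0f%%/%.0f%%/%.0f%%; EVT OR %.2f (%.2f-%.2f)\n",
              100 * x$sens_diff[["ICA"]], 100 * x$sens_diff[["M1"]],
              100 * x$sens_diff[["M2"]], x$or_evt[["median"]],
              x$or_evt[["ci_low"]], x$or_evt[["ci_high"]]))
  cat(sprintf("  costs %s at %d price level\n",
              if (isTRUE(x$costs_inflated)) "inflated to start year" else "at reference year",
              if (isTRUE(x$costs_inflated)) x$start_year else x$cost_reference_year))
  invisible(x)
}
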