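#' Scalar parameters eligible for one-way sensitivity analysis
#'
#' Registry of the scalar inputs varied by plus/minus 10 percent in the
#' tornado analysis: mRS-level utilities (mRS 6 fixed at 0), yearly cost
#' table entries, unit prices, mortality hazard ratios and discount rates.
#' NNI, the sensitivity differences and the EVT effect are deliberately
#' excluded (they get dedicated scenario analyses instead).
#'
#' @return Named list mapping parameter labels to `(field, index)` accessors.
#' @export
ow_parameter_registry <- function() {
  reg <- list()
  for (i in 1:5) reg[[paste0("utility_", mrs_levels[i])]] <-
    list(field = "utility_mean", index = i)
  for (tab in c("costs_y1_mean", "costs_y2_mean", "costs_y3plus_mean")) {
    lab <- sub("costs_(y[0-9a-z]+)_mean", "cost_\\1", tab)
    for (i in 1:6) reg[[paste0(lab, "_", mrs_levels[i])]] <-
      list(field = tab, index = i)
  }
  for (f in c("cost_ctp", "cost_evt", "cost_ivt")) reg[[f]] <- list(field = f, index = 1L)
  for (i in 1:5) reg[[paste0("hr_mortality_", mrs_levels[i])]] <-
    list(field = "hr_mortality", index = i)
  reg$discount_rate_qaly <- list(field = "discount_rate_qaly", index = 1L)
  reg$discount_rate_cost <- list(field = "discount_rate_cost", index = 1L)
  reg
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic baseline with each listed scalar parameter at
#' 0.9x and 1.1x its mean, all else fixed and with identical event-stream
#' seeds, and reports the resulting mean NMB at each end together with the
#' swing (absolute difference), sorted descending.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param params A `ctp_params` object.
#' @param parameters Character vector of registry labels
#'   (default: all of [ow_parameter_registry()]).
#' @param seed Seed shared by every run.
#' @param n_streams Event-stream replications per run.
#' @return `data.frame` with columns `parameter`, `nmb_low` (0.9x),
#'   `nmb_high` (1.1x), `swing`, sorted by swing; the unperturbed baseline
#'   NMB is attached as attribute `baseline_nmb`.
#' @export
one_way_sensitivity <- function(cohort, params,
                                parameters = names(ow_parameter_registry()),
                                seed = 1L, n_streams = 5L) {
  reg <- ow_parameter_registry()
  unknown <- setdiff(parameters, names(reg))
  if (length(unknown)) {
    stop("not a scalar tornado parameter: ", paste(unknown, collapse = ", "))
  }
  base <- run_baseline(cohort, params, seed = seed, n_streams = n_streams)
  run_at <- function(entry, mult) {
    p2 <- params
    p2[[entry$field]][entry$index] <- p2[[entry$field]][entry$index] * mult
    run_baseline(cohort, p2, seed = seed, n_streams = n_streams)$nmb
  }
  rows <- lapply(parameters, function(nm) {
    e <- reg[[nm]]
    lo <- run_at(e, 0.9)
    hi <- run_at(e, 1.1)
    data.frame(parameter = nm, nmb_low = lo, nmb_high = hi,
               swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "baseline_nmb") <- base$nmb
  out
}

#' Prepare PSA distribution specifications
#'
#' Builds the distribution objects once per analysis: log-normal for the EVT
#' odds ratio (from its 95\% CI) and the mortality hazard ratios (stand-in
#' CI factor), a single log-normal multiplier for the recurrence hazard-ratio
#' table, gamma for every yearly cost entry and beta for every utility
#' (mRS 6 fixed at 0). Unit prices, NNI, sensitivity differences and rates
#' are fixed.
#'
#' @param params A `ctp_params` object.
#' @return Named list of `ctp_dist` objects (and lists thereof).
#' @export
prepare_psa_dists <- function(params) {
  f <- params$hr_mortality_ci_factor
  list(
    or_evt = dist_lognormal_from_ci(params$or_evt[["median"]],
                                    params$or_evt[["ci_low"]],
                                    params$or_evt[["ci_high"]]),
    hr_mortality = lapply(params$hr_mortality,
                          function(h) dist_lognormal_from_ci(h, h / f, h * f)),
    hr_recurrence_mult = structure(list(family = "lognormal", meanlog = 0,
                                        sdlog = params$hr_recurrence_sdlog),
                                   class = "ctp_dist"),
    utilities = mapply(dist_beta_from_mean_sd, params$utility_mean,
                       params$utility_sd, SIMPLIFY = FALSE),
    costs_y1 = mapply(dist_gamma_from_mean_sd, params$costs_y1_mean,
                      params$costs_y1_sd, SIMPLIFY = FALSE),
    costs_y2 = mapply(dist_gamma_from_mean_sd, params$costs_y2_mean,
                      params$costs_y2_sd, SIMPLIFY = FALSE),
    costs_y3plus = mapply(dist_gamma_from_mean_sd, params$costs_y3plus_mean,
                          params$costs_y3plus_sd, SIMPLIFY = FALSE)
  )
}

#' Draw one PSA parameter set
#'
#' Replaces the uncertain parameter values by draws from their prepared
#' distributions, using the current RNG state. The drawn EVT odds ratio
#' becomes the working median; the mRS-6 utility stays 0.
#'
#' @param params A `ctp_params` object.
#' @param dists Output of [prepare_psa_dists()] (rebuilt when omitted).
#' @return A `ctp_params` object with drawn values.
#' @export
draw_psa_parameters <- function(params, dists = prepare_psa_dists(params)) {
  p <- params
  p$or_evt[["median"]] <- dist_draw(dists$or_evt)
  p$hr_mortality[] <- vapply(dists$hr_mortality, dist_draw, numeric(1))
  p$hr_recurrence$hr <- params$hr_recurrence$hr * dist_draw(dists$hr_recurrence_mult)
  p$utility_mean[] <- vapply(dists$utilities, dist_draw, numeric(1))
  p$utility_mean[["mrs6"]] <- 0
  p$costs_y1_mean[] <- vapply(dists$costs_y1, dist_draw, numeric(1))
  p$costs_y2_mean[] <- vapply(dists$costs_y2, dist_draw, numeric(1))
  p$costs_y3plus_mean[] <- vapply(dists$costs_y3plus, dist_draw, numeric(1))
  p
}

#' Probabilistic sensitivity analysis
#'
#' Per replicate: the cohort is bootstrapped with replacement (same size,
#' whole patients so stratum labels are preserved), one parameter set is
#' drawn, arms are rebuilt (Bernoulli missed-selection and odds-shifted
#' counterfactual under the drawn odds ratio), both arms are simulated on
#' common random numbers, and the cohort-mean `delta_costs`, `delta_qalys`
#' and NMB are recorded, together with per-stratum means excluding the CTP
#' screening cost (for ICER-plane panels per occlusion site). The
#' per-replicate seed schedule is derived once from the master seed, so a
#' change in NNI (which only shifts the deterministic screening cost) leaves
#' `delta_qalys` bit-identical.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param params A `ctp_params` object.
#' @param n_reps Number of replicates (study default 1000).
#' @param seed Master seed.
#' @return An object of class `ctp_psa`: list with `replicates` (data
#'   frame), `summary` (median and IQR of each outcome),
#'   `fraction_cost_effective` (share of replicates with NMB > 0) and
#'   `settings`.
#' @export
run_psa <- function(cohort, params, n_reps = params$n_psa, seed = 1L) {
  validate_cohort(cohort)
  stopifnot(n_reps >= 1)
  n <- nrow(cohort)
  dists <- prepare_psa_dists(params)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  screening <- screening_cost_per_lvo(params$nni, params$cost_ctp,
                                      params$overhead_factor)
  cols <- c("delta_costs", "delta_qalys", "nmb",
            paste0("delta_costs_nosc_", occlusion_sites),
            paste0("delta_qalys_", occlusion_sites))
  out <- matrix(NA_real_, n_reps, length(cols), dimnames = list(NULL, cols))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    boot$id <- seq_len(n)
    drawn <- draw_psa_parameters(params, dists)
    arms <- build_arms(boot, drawn)
    sim <- simulate_arms(boot, arms, drawn)
    tre <- arm_economics(sim$treated$states, boot, arms$missed, "ctp", drawn)
    ctl <- arm_economics(sim$control$states, boot, arms$missed, "control", drawn)
    dc <- tre$discounted_costs - ctl$discounted_costs
    dq <- tre$discounted_qalys - ctl$discounted_qalys
    out[r, "delta_costs"] <- mean(dc)
    out[r, "delta_qalys"] <- mean(dq)
    out[r, "nmb"] <- params$wtp * mean(dq) - mean(dc)
    for (s in occlusion_sites) {
      i <- boot$occlusion == s
      out[r, paste0("delta_costs_nosc_", s)] <- mean(dc[i]) - screening
      out[r, paste0("delta_qalys_", s)] <- mean(dq[i])
    }
  }
  replicates <- as.data.frame(out)
  replicates$rep <- seq_len(n_reps)
  qs <- function(x) c(median = stats::median(x),
                      q25 = unname(stats::quantile(x, 0.25)),
                      q75 = unname(stats::quantile(x, 0.75)))
  summary <- as.data.frame(t(vapply(replicates[c("delta_costs", "delta_qalys", "nmb")],
                                    qs, numeric(3))))
  summary$quantity <- rownames(summary)
  rownames(summary) <- NULL
  structure(list(
    replicates = replicates,
    summary = summary[, c("quantity", "median", "q25", "q75")],
    fraction_cost_effective = mean(replicates$nmb > 0),
    settings = list(n = n, n_reps = n_reps, seed = seed,
                    horizon_years = params$horizon_years, nni = params$nni,
                    wtp = params$wtp, sens_diff = params$sens_diff,
                    or_evt = params$or_evt)
  ), class = "ctp_psa")
}

#' @export
print.ctp_psa <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<ctp_psa: %d replicates, n=%d, %d-year horizon, NNI %.1f>\n",
              s$n_reps, s$n, s$horizon_years, s$nni))
  print(x$summary, digits = 4)
  cat(sprintf("fraction cost-effective: %.3f\n", x$fraction_cost_effective))
  invisible(x)
}

#' Scenario grid of probabilistic sensitivity analyses
#'
#' Runs one PSA per combination of follow-up horizon, NNI, sensitivity
#' difference offset (added to the baseline per-site differences, floored at
#' 0) and, optionally, EVT odds-ratio median (the log-scale spread is held
#' at the baseline value). Every cell uses the same master seed, hence the
#' same replicate seed schedule, so `delta_qalys` is identical across NNI at
#' fixed horizon and offset.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param params A `ctp_params` object.
#' @param horizons Follow-up horizons in years.
#' @param nni_values NNI values.
#' @param sens_offsets Offsets (percentage points as fractions) applied to
#'   all baseline sensitivity differences.
#' @param or_medians Optional EVT odds-ratio medians; default baseline only.
#' @param n_reps Replicates per cell.
#' @param seed Master seed shared across cells.
#' @return `data.frame` with one row per scenario: settings plus median and
#'   IQR of `delta_costs`, `delta_qalys`, `nmb`, and the fraction of
#'   replicates cost-effective.
#' @export
scenario_grid <- function(cohort, params, horizons = c(10, 5),
                          nni_values = c(4.3, 8.3),
                          sens_offsets = c(0.08, 0.04, 0, -0.04, -0.08),
                          or_medians = NULL, n_reps = 200L, seed = 1L) {
  base_sdlog <- dist_lognormal_from_ci(params$or_evt[["median"]],
                                       params$or_evt[["ci_low"]],
                                       params$or_evt[["ci_high"]])$sdlog
  z <- 1.959964
  if (is.null(or_medians)) or_medians <- params$or_evt[["median"]]
  rows <- list()
  for (h in horizons) for (orm in or_medians) for (nni in nni_values) {
    for (off in sens_offsets) {
      p2 <- params
      p2$horizon_years <- as.integer(h)
      p2$nni <- nni
      p2$sens_diff[] <- pmax(0, params$sens_diff + off)
      p2$or_evt <- c(median = orm, ci_low = orm * exp(-z * base_sdlog),
                     ci_high = orm * exp(z * base_sdlog))
      psa <- run_psa(cohort, p2, n_reps = n_reps, seed = seed)
      s <- psa$summary
      g <- function(q, w) s[[w]][s$quantity == q]
      rows[[length(rows) + 1L]] <- data.frame(
        horizon_years = h, nni = nni, sens_offset = off, or_median = orm,
        delta_costs_median = g("delta_costs", "median"),
        delta_costs_q25 = g("delta_costs", "q25"),
        delta_costs_q75 = g("delta_costs", "q75"),
        delta_qalys_median = g("delta_qalys", "median"),
        delta_qalys_q25 = g("delta_qalys", "q25"),
        delta_qalys_q75 = g("delta_qalys", "q75"),
        nmb_median = g("nmb", "median"),
        nmb_q25 = g("nmb", "q25"),
        nmb_q75 = g("nmb", "q75"),
        fraction_cost_effective = psa$fraction_cost_effective
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
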