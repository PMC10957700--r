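#' Deterministic mean-input baseline run
#'
#' Evaluates the incremental outcomes of CTP-based LVO detection at the mean
#' values of all input parameters. The counterfactual no-EVT state of every
#' patient is fixed deterministically through the rank-preserving latent
#' uniform; the missed/not-missed selection is taken in expectation (each
#' patient contributes to the control arm as a mixture of the missed and
#' not-missed branch, weighted by the occlusion-specific sensitivity
#' difference), and event randomness is averaged over `n_streams`
#' common-random-number stream replications. Because the not-missed control
#' branch shares its event stream with the CTP arm, its follow-up outcomes
#' cancel exactly and the residual Monte-Carlo noise comes only from the
#' missed branch.
#'
#' Per patient:
#' `delta_costs = screening + CTP own cost + p_miss * (EVT cost + followup_treated - followup_missed)`
#' and `delta_qalys = p_miss * (qalys_treated - qalys_missed)`;
#' `nmb = wtp * delta_qalys - delta_costs`. Reported values are cohort means.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param params A `ctp_params` object (means are the stored values).
#' @param seed Integer seed; the run is reproducible bit-for-bit.
#' @param n_streams Number of event-stream replications averaged over.
#' @return A list with `delta_qalys`, `delta_costs`, `nmb` (cohort means),
#'   `per_patient` (stream-averaged per-patient deltas) and `settings`.
#' @export
run_baseline <- function(cohort, params, seed = 1L, n_streams = 20L) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  n <- nrow(cohort)
  or <- params$or_evt[["median"]]
  dists <- stratum_mrs_dists(cohort)
  cf <- cohort$mrs90_treated
  for (s in occlusion_sites) {
    i <- which(cohort$occlusion == s)
    if (length(i)) {
      cf[i] <- counterfactual_mrs(cohort$mrs90_treated[i], cohort$latent_u[i],
                                  dists[s, ], or)
    }
  }
  p_miss <- unname(params$sens_diff[cohort$occlusion])
  redist_cum <- no_evt_redistribution(dists, or)
  oh <- params$overhead_factor
  ctp_own <- params$cost_ctp * (if (isTRUE(params$overhead_applies_to_ctp)) oh else 1)
  screening <- screening_cost_per_lvo(params$nni, params$cost_ctp, oh)
  evt_component <- params$cost_evt * oh
  set.seed(seed)
  stream_seeds <- sample.int(2147483646L, n_streams)
  dC <- dQ <- numeric(n)
  for (k in seq_len(n_streams)) {
    set.seed(stream_seeds[k])
    streams <- draw_streams(n, params$horizon_years)
    tr <- simulate_states(cohort$mrs90_treated, cohort$age, cohort$sex,
                          cohort$occlusion, params, streams, redist_cum)
    ms <- simulate_states(cf, cohort$age, cohort$sex,
                          cohort$occlusion, params, streams, redist_cum)
    acc_tr <- accumulate_states(tr$states, params)
    acc_ms <- accumulate_states(ms$states, params)
    dC <- dC + screening + ctp_own +
      p_miss * (evt_component + acc_tr$followup_costs - acc_ms$followup_costs)
    dQ <- dQ + p_miss * (acc_tr$qalys - acc_ms$qalys)
  }
  dC <- dC / n_streams
  dQ <- dQ / n_streams
  nmb <- params$wtp * dQ - dC
  list(
    delta_qalys = mean(dQ),
    delta_costs = mean(dC),
    nmb = mean(nmb),
    per_patient = data.frame(id = cohort$id, delta_costs = dC,
                             delta_qalys = dQ, nmb = nmb),
    settings = list(n = n, horizon_years = params$horizon_years,
                    nni = params$nni, wtp = params$wtp,
                    seed = seed, n_streams = n_streams)
  )
}
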