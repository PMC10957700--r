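#' Annual probability of death
#'
#' Background annual death probability from the life table, inflated on the
#' probability scale by the mRS-specific mortality hazard ratio and capped at
#' 1. mRS 0 and 1 share one hazard-ratio level; state 6 is absorbing and not
#' a valid input.
#'
#' @param age,sex,year Patient age (years), sex (`"male"`/`"female"`) and
#'   calendar year for the life-table lookup; vectorised.
#' @param mrs Current mRS state, 0..5.
#' @param life_table Life table (see [make_life_table()]).
#' @param hr_mortality Length-5 hazard ratios for mRS 0-1, 2, 3, 4, 5.
#' @return Annual death probability in `[0, 1]`.
#' @export
annual_death_prob <- function(age, sex, year, mrs, life_table, hr_mortality) {
  q <- life_table_q(life_table, age, sex, year)
  pmin(1, q * hr_mortality[mrs_hr_index(mrs)])
}

#' Annual probability of recurrent stroke
#'
#' Baseline recurrence probability by years since the index stroke, inflated
#' by the age-band and mRS-dependent recurrence hazard ratio, capped at 1.
#'
#' @param years_since_stroke Whole years since the index stroke (>= 1).
#' @param age Current age.
#' @param mrs Current mRS state, 0..5.
#' @param params A `ctp_params` object.
#' @return Annual recurrence probability in `[0, 1]`.
#' @export
annual_recurrence_prob <- function(years_since_stroke, age, mrs, params) {
  stopifnot(all(years_since_stroke >= 1))
  base <- recurrence_baseline_prob(params, years_since_stroke)
  hr <- hr_recurrence_lookup(params$hr_recurrence)(age, mrs)
  pmin(1, base * hr)
}

#' Redistribute mRS after a recurrent stroke
#'
#' A recurrent stroke moves the patient to a state drawn from the stratum's
#' no-EVT (odds-shifted) 90-day mRS distribution truncated to
#' `[current_mrs, 6]` and renormalised, so the state never improves; drawing
#' state 6 represents a fatal recurrence. If the truncated distribution is
#' degenerate (all mass below the current state) the patient stays put.
#'
#' @param current_mrs Current states, 0..5.
#' @param stratum_no_evt_dist Length-7 probability vector (the stratum's
#'   no-EVT distribution).
#' @param u Uniform deviates, one per patient; drawn from the current RNG
#'   state when omitted.
#' @return Integer vector of new states, each `>= current_mrs`.
#' @export
apply_recurrence <- function(current_mrs, stratum_no_evt_dist,
                             u = stats::runif(length(current_mrs))) {
  stopifnot(all(current_mrs %in% 0:5), length(u) == length(current_mrs))
  cs <- cumsum(stratum_no_evt_dist)
  cs[7] <- 1
  lower <- c(0, cs)[current_mrs + 1L]
  mass <- 1 - lower
  uu <- lower + u * mass
  new <- findInterval(uu, cs, left.open = TRUE)
  new <- as.integer(pmin(pmax(new, current_mrs), 6L))
  new[mass <= 0] <- current_mrs[mass <= 0]
  new
}

# Vectorised trajectory engine over a whole arm. `streams` supplies the
# per-patient, per-cycle uniform deviates (death, recurrence, redistribution)
# so that both arms can be simulated on common random numbers. Within each
# yearly cycle the death trial precedes the recurrence trial; states are
# recorded end-of-cycle; a fatal recurrence is a redistribution draw of 6.
simulate_states <- function(mrs0, age, sex, occlusion, params, streams,
                            redist_cum = NULL) {
  n <- length(mrs0)
  horizon <- params$horizon_years
  states <- matrix(6L, nrow = n, ncol = horizon + 1L)
  states[, 1L] <- as.integer(mrs0)
  if (n == 0L || horizon == 0L) {
    return(list(states = states,
                death_year = ifelse(mrs0 == 6L, 0L, NA_integer_),
                recurrence = matrix(FALSE, n, horizon)))
  }
  if (is.null(redist_cum)) {
    stop("redist_cum (per-stratum no-EVT cumulative distributions) required")
  }
  qfun <- life_table_lookup(params$life_table)
  hrfun <- hr_recurrence_lookup(params$hr_recurrence)
  hrm <- params$hr_mortality
  base_rec <- recurrence_baseline_prob(params, seq_len(horizon))
  occ_idx <- match(occlusion, occlusion_sites)
  cur <- as.integer(mrs0)
  death_year <- ifelse(cur == 6L, 0L, NA_integer_)
  recurrence <- matrix(FALSE, n, horizon)
  for (t in seq_len(horizon)) {
    alive <- which(cur < 6L)
    if (length(alive)) {
      q <- qfun(age[alive] + t, sex[alive], params$start_year + t)
      pd <- pmin(1, q * hrm[mrs_hr_index(cur[alive])])
      dies <- streams$death[alive, t] < pd
      dead_idx <- alive[dies]
      if (length(dead_idx)) {
        cur[dead_idx] <- 6L
        death_year[dead_idx] <- t
      }
      surv <- alive[!dies]
      if (length(surv)) {
        pr <- pmin(1, base_rec[t] * hrfun(age[surv] + t, cur[surv]))
        rec <- streams$recur[surv, t] < pr
        ri <- surv[rec]
        if (length(ri)) {
          recurrence[ri, t] <- TRUE
          for (s in unique(occ_idx[ri])) {
            j <- ri[occ_idx[ri] == s]
            cs <- redist_cum[s, ]
            lower <- c(0, cs)[cur[j] + 1L]
            mass <- 1 - lower
            uu <- lower + streams$redraw[j, t] * mass
            new <- findInterval(uu, cs, left.open = TRUE)
            new <- as.integer(pmin(pmax(new, cur[j]), 6L))
            new[mass <= 0] <- cur[j][mass <= 0]
            fatal <- j[new == 6L]
            cur[j] <- new
            if (length(fatal)) death_year[fatal] <- t
          }
        }
      }
    }
    states[, t + 1L] <- cur
  }
  list(states = states, death_year = death_year, recurrence = recurrence)
}

draw_streams <- function(n, horizon) {
  h <- max(horizon, 1L)
  list(death = matrix(stats::runif(n * h), n, h),
       recur = matrix(stats::runif(n * h), n, h),
       redraw = matrix(stats::runif(n * h), n, h))
}

#' Simulate yearly mRS trajectories for both arms
#'
#' Runs the patient-level Markov microsimulation from the 90-day state to the
#' horizon for the treated (CTP) and control (NCCT+CTA) arm. Both arms share
#' one per-patient stream of uniform deviates (common random numbers), so
#' paired differences isolate the arm effect and identical arm assignments
#' yield identical trajectories. Recurrence redistribution draws from the
#' odds-shifted (no-EVT) stratum distributions of the input cohort.
#'
#' @param cohort A `ctp_cohort` data frame.
#' @param arms Arm assignments from [build_arms()].
#' @param params A `ctp_params` object.
#' @param seed Integer seed for the event streams; `NULL` uses the current
#'   RNG state.
#' @return A list with elements `treated` and `control`, each a list of
#'   `states` (n x horizon+1 integer matrix, column 1 = 90-day state),
#'   `death_year` and `recurrence`.
#' @export
simulate_arms <- function(cohort, arms, params, seed = NULL) {
  stopifnot(nrow(cohort) == nrow(arms), all(cohort$id == arms$id))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  streams <- draw_streams(n, params$horizon_years)
  dists <- stratum_mrs_dists(cohort)
  redist_cum <- no_evt_redistribution(dists, params$or_evt[["median"]])
  list(
    treated = simulate_states(arms$mrs90_treated, cohort$age, cohort$sex,
                              cohort$occlusion, params, streams, redist_cum),
    control = simulate_states(arms$mrs90_control, cohort$age, cohort$sex,
                              cohort$occlusion, params, streams, redist_cum)
  )
}

#' Simulate a single patient's trajectory
#'
#' Convenience wrapper over the cohort engine for one patient.
#'
#' @param patient One-row `ctp_cohort`-style data frame.
#' @param mrs90 The arm-specific 90-day state to start from.
#' @param params A `ctp_params` object.
#' @param seed Integer seed.
#' @return A list with `mrs_by_year` (length `horizon_years + 1`, entry 1 is
#'   the 90-day state), `death_year` (`NA` if alive at horizon) and
#'   `recurrence_years`.
#' @export
simulate_trajectory <- function(patient, mrs90, params, seed = NULL) {
  stopifnot(nrow(patient) == 1L, mrs90 %in% 0:6)
  if (!is.null(seed)) set.seed(seed)
  streams <- draw_streams(1L, params$horizon_years)
  dist <- rep(0, 7)
  dist[mrs90 + 1L] <- 1
  redist_cum <- matrix(rep(cumsum(dist), 3), nrow = 3, byrow = TRUE,
                       dimnames = list(occlusion_sites, NULL))
  # Single-patient runs use a degenerate redistribution at the current state
  # only when the stratum distribution is unknown; prefer the cohort engine.
  dists <- stratum_mrs_dists(patient)
  if (!any(is.na(dists[patient$occlusion, ]))) {
    redist_cum[patient$occlusion, ] <-
      cumsum(shift_distribution_by_or(dists[patient$occlusion, ],
                                      params$or_evt[["median"]]))
  }
  res <- simulate_states(mrs90, patient$age, patient$sex, patient$occlusion,
                         params, streams, redist_cum)
  list(mrs_by_year = res$states[1L, ],
       death_year = res$death_year[1L],
       recurrence_years = which(res$recurrence[1L, ]))
}

#' Trajectories as a long-format table
#'
#' @param sim Output of [simulate_arms()].
#' @param ids Patient ids (row order of the simulated cohort).
#' @return `data.frame` with columns `id`, `arm`, `year`, `mrs`.
#' @export
trajectories_long <- function(sim, ids) {
  out <- lapply(c("treated", "control"), function(arm) {
    st <- sim[[arm]]$states
    data.frame(id = rep(ids, times = ncol(st)),
               arm = arm,
               year = rep(seq_len(ncol(st)) - 1L, each = nrow(st)),
               mrs = as.integer(st))
  })
  do.call(rbind, out)
}
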