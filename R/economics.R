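#' Discount factor
#'
#' Present-value multiplier for accrual year `year_index` (0-based: the first
#' simulated year is undiscounted), `(1 + rate)^(-year_index)`.
#'
#' @param year_index Nonnegative integer year index.
#' @param rate Annual discount rate (> -1).
#' @return Multiplier in `(0, Inf)`.
#' @export
discount_factor <- function(year_index, rate) {
  stopifnot(all(year_index >= 0))
  if (any(rate <= -1)) stop("discount rate must exceed -1")
  (1 + rate)^(-year_index)
}

#' Inflate a cost between calendar years
#'
#' Multiplies by `prod(1 + rate_y)` over years `y` in `(from_year, to_year]`;
#' deflation (negative rates, or `to_year < from_year`) is applied
#' symmetrically.
#'
#' @param cost Amount in `from_year` euros.
#' @param from_year,to_year Calendar years, both covered by `series`.
#' @param series `data.frame` with columns `year`, `rate`.
#' @return Amount in `to_year` euros.
#' @export
inflate_cost <- function(cost, from_year, to_year, series) {
  lo <- min(from_year, to_year)
  hi <- max(from_year, to_year)
  if (lo == hi) return(cost)
  years <- (lo + 1L):hi
  if (!all(years %in% series$year)) {
    stop("inflation series does not cover years ", lo + 1L, " to ", hi)
  }
  f <- prod(1 + series$rate[match(years, series$year)])
  if (to_year >= from_year) cost * f else cost / f
}

#' Acute care cost of the index stroke
#'
#' Imaging and treatment costs at presentation, multiplied by the hospital
#' overhead factor (42\% by default). In the CTP arm every patient incurs the
#' CTP, EVT and (if given) IVT cost; in the control arm missed patients
#' incur no EVT cost. IVT is assumed given in both arms. The NCCT+CTA cost
#' is identical across arms (default 0, differenced out). When
#' `overhead_applies_to_ctp` is `FALSE` the CTP component is exempt from the
#' overhead factor.
#'
#' @param arm `"ctp"` or `"control"`.
#' @param missed Logical vector: LVO missed under the control strategy.
#' @param ivt Logical vector: IVT administered.
#' @param params A `ctp_params` object.
#' @return Acute cost in euros per patient.
#' @export
acute_cost <- function(arm = c("ctp", "control"), missed, ivt, params) {
  arm <- match.arg(arm)
  oh <- params$overhead_factor
  ctp_oh <- if (isTRUE(params$overhead_applies_to_ctp)) oh else 1
  base <- params$cost_ncct_cta + ivt * params$cost_ivt
  if (arm == "ctp") {
    (base + params$cost_evt) * oh + params$cost_ctp * ctp_oh
  } else {
    (base + ifelse(missed, 0, params$cost_evt)) * oh
  }
}

#' CTP screening cost per detected LVO
#'
#' For every detected LVO, `nni - 1` additional suspected-stroke patients
#' without an EVT-eligible occlusion are imaged with CTP; their screening
#' cost is charged to the index patient in the CTP arm. The index patient's
#' own CTP sits in [acute_cost()], so the total CTP spend per LVO equals
#' `nni * cost_ctp` (times overhead).
#'
#' @param nni Number needed to image (>= 1).
#' @param cost_ctp Unit CTP cost.
#' @param overhead_factor Hospital overhead multiplier.
#' @return Screening cost in euros per LVO patient.
#' @export
screening_cost_per_lvo <- function(nni, cost_ctp, overhead_factor) {
  if (any(nni < 1)) stop("nni must be >= 1")
  (nni - 1) * cost_ctp * overhead_factor
}

#' Yearly mRS-keyed cost and utility
#'
#' Follow-up cost for the accrual year (1-based): year 1 uses the first-year
#' cost row, year 2 the second-year row, year 3 onward the long-term row,
#' keyed by the mRS state occupied that year (mRS 0 and 1 merged). The
#' mRS-6 row is charged once, in the year death occurs (or year 1 for
#' patients dead at 90 days); `post_death = TRUE` marks years after that and
#' returns 0. `annual_qaly()` returns the mRS-keyed utility (0 for state 6).
#'
#' @param mrs mRS state occupied in the year, 0..6.
#' @param year_index Accrual year, 1-based.
#' @param params A `ctp_params` object.
#' @param post_death Logical: the patient died in an earlier year.
#' @return Cost in euros / utility in QALYs per year.
#' @export
annual_cost <- function(mrs, year_index, params, post_death = FALSE) {
  stopifnot(all(mrs %in% 0:6), all(year_index >= 1))
  tab <- rbind(params$costs_y1_mean, params$costs_y2_mean, params$costs_y3plus_mean)
  out <- tab[cbind(pmin(year_index, 3L), mrs_cost_index(mrs))]
  out[post_death] <- 0
  out
}

#' @rdname annual_cost
#' @export
annual_qaly <- function(mrs, params) {
  stopifnot(all(mrs %in% 0:6))
  unname(params$utility_mean[mrs_cost_index(mrs)])
}

# Accrual-year state keys for a state matrix (n x horizon+1). Year t is keyed
# to the state entering the year (end of year t-1); a death during year t
# keys that year to mRS 6 (one-off death-year cost, zero utility); years
# after the death year contribute nothing.
accrual_keys <- function(states) {
  horizon <- ncol(states) - 1L
  n <- nrow(states)
  key <- matrix(NA_integer_, n, max(horizon, 0L))
  for (t in seq_len(horizon)) {
    s_prev <- states[, t]
    s_end <- states[, t + 1L]
    k <- s_prev
    k[s_end == 6L & s_prev < 6L] <- 6L
    if (t > 1L) k[s_prev == 6L] <- NA_integer_ # post-death: no accrual
    key[, t] <- k
  }
  key
}

#' Discounted costs and QALYs per patient
#'
#' Converts simulated state matrices into cumulative discounted follow-up
#' costs and QALYs: for each accrual year the mRS-keyed cost (year-specific
#' row) and utility are discounted at 1.5\%/year and 4\%/year respectively,
#' with the first year undiscounted. Acute and screening costs are added at
#' year 0 undiscounted by [arm_economics()].
#'
#' @param states Integer matrix (n x horizon+1) of yearly states, column 1 =
#'   90-day state.
#' @param params A `ctp_params` object.
#' @return `data.frame` with columns `followup_costs`, `qalys`.
#' @export
accumulate_states <- function(states, params) {
  horizon <- ncol(states) - 1L
  n <- nrow(states)
  costs <- numeric(n)
  qalys <- numeric(n)
  if (horizon > 0L && n > 0L) {
    key <- accrual_keys(states)
    cost_tab <- rbind(params$costs_y1_mean, params$costs_y2_mean,
                      params$costs_y3plus_mean)
    u <- unname(params$utility_mean)
    for (t in seq_len(horizon)) {
      k <- key[, t]
      live <- !is.na(k)
      if (any(live)) {
        ci <- mrs_cost_index(k[live])
        costs[live] <- costs[live] +
          cost_tab[cbind(rep(pmin(t, 3L), sum(live)), ci)] *
          discount_factor(t - 1L, params$discount_rate_cost)
        qalys[live] <- qalys[live] +
          u[ci] * discount_factor(t - 1L, params$discount_rate_qaly)
      }
    }
  }
  data.frame(followup_costs = costs, qalys = qalys)
}

#' Per-patient economic results for one arm
#'
#' @param states Simulated state matrix for the arm.
#' @param cohort The simulated cohort.
#' @param missed Logical vector of missed-LVO flags.
#' @param arm `"ctp"` or `"control"`.
#' @param params A `ctp_params` object.
#' @return `data.frame` with columns `id`, `arm`, `discounted_costs`,
#'   `discounted_qalys`.
#' @export
arm_economics <- function(states, cohort, missed, arm, params) {
  acc <- accumulate_states(states, params)
  acute <- acute_cost(arm, missed, cohort$ivt, params)
  screening <- if (arm == "ctp") {
    screening_cost_per_lvo(params$nni, params$cost_ctp, params$overhead_factor)
  } else 0
  data.frame(id = cohort$id, arm = arm,
             discounted_costs = acute + screening + acc$followup_costs,
             discounted_qalys = acc$qalys)
}

#' Per-patient and cohort-level outcome differences
#'
#' Pairs the two arms by patient id and computes `delta_costs` (CTP arm minus
#' control), `delta_qalys`, and the net monetary benefit
#' `nmb = wtp * delta_qalys - delta_costs` (an exact identity per patient).
#' Cohort summaries report the mean and the median with 25th/75th
#' percentiles of each quantity.
#'
#' @param treated,control Outputs of [arm_economics()] for the two arms.
#' @param wtp Willingness to pay per QALY.
#' @return A list with `per_patient` (data frame) and `summary` (data frame
#'   with one row per quantity: mean, median, q25, q75).
#' @export
delta_outcomes <- function(treated, control, wtp) {
  if (!setequal(treated$id, control$id)) stop("arms are not paired by patient id")
  m <- match(treated$id, control$id)
  per <- data.frame(
    id = treated$id,
    delta_costs = treated$discounted_costs - control$discounted_costs[m],
    delta_qalys = treated$discounted_qalys - control$discounted_qalys[m]
  )
  per$nmb <- wtp * per$delta_qalys - per$delta_costs
  qs <- function(x) c(mean = mean(x), median = stats::median(x),
                      q25 = unname(stats::quantile(x, 0.25)),
                      q75 = unname(stats::quantile(x, 0.75)))
  summary <- as.data.frame(t(vapply(per[c("delta_costs", "delta_qalys", "nmb")],
                                    qs, numeric(4))))
  summary$quantity <- rownames(summary)
  rownames(summary) <- NULL
  list(per_patient = per, summary = summary[, c("quantity", "mean", "median", "q25", "q75")])
}
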