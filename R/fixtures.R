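#' Synthetic life table from a Gompertz-Makeham mortality law
#'
#' The national Dutch life table used by the original evaluation is not
#' redistributable, so the package ships a deterministic synthetic stand-in:
#' annual death probabilities `q(age) = min(1, a + b * c^age)` per sex, with
#' `b` calibrated by root finding so that the curtate life expectancy at the
#' cohort's median age (72 years) equals `le_target` (defaults 14 years for
#' women, 12 for men). A real national table can be supplied instead via
#' [read_life_table()] or the `life_table_csv` configuration key.
#'
#' The returned table is constant over calendar years; a table read from CSV
#' may carry a `year` column, in which case lookups use the nearest available
#' year.
#'
#' @param le_target Named vector: target life expectancy at `at_age`, in
#'   years, for `female` and `male`.
#' @param at_age Calibration age.
#' @param makeham_a Age-independent background hazard component.
#' @param gompertz_c Exponential ageing rate.
#' @param min_age,max_age Age range of the table; `q(max_age)` is forced to 1.
#' @return A `data.frame` with columns `age`, `sex`, `qx`, carrying the
#'   calibrated `(a, b, c)` per sex as an attribute.
#' @export
make_life_table <- function(le_target = c(female = 14, male = 12), at_age = 72,
                            makeham_a = 2e-4, gompertz_c = 1.1,
                            min_age = 18, max_age = 110) {
  stopifnot(all(c("female", "male") %in% names(le_target)))
  ages_from <- at_age:max_age
  life_expectancy <- function(b) {
    q <- pmin(1, makeham_a + b * gompertz_c^ages_from)
    q[length(q)] <- 1
    sum(cumprod(1 - q))
  }
  solve_b <- function(target) {
    stats::uniroot(function(b) life_expectancy(b) - target,
                   interval = c(1e-10, 1e-2), tol = 1e-14)$root
  }
  ages <- min_age:max_age
  rows <- lapply(c("female", "male"), function(sx) {
    b <- solve_b(le_target[[sx]])
    q <- pmin(1, makeham_a + b * gompertz_c^ages)
    q[length(q)] <- 1
    data.frame(age = ages, sex = sx, qx = q)
  })
  out <- do.call(rbind, rows)
  attr(out, "calibration") <- list(a = makeham_a, c = gompertz_c,
                                   le_target = le_target, at_age = at_age)
  attr(out, "synthetic") <- TRUE
  out
}

#' Read a life table from CSV
#'
#' Expected header: `age,sex,year,qx` (`year` may be empty to denote all
#' years). `sex` must be `male`/`female`.
#'
#' @param path CSV file path.
#' @return A life table `data.frame` usable wherever [make_life_table()]
#'   output is.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table fixture not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(lt))) {
    stop("life table CSV must have columns age, sex, qx (optionally year): ", path)
  }
  if (!all(lt$sex %in% c("male", "female"))) stop("life table sex must be male/female")
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  lt
}

#' Annual death probability lookup
#'
#' Vectorised lookup of `q(age, sex, year)`. Ages outside the table range are
#' clamped to the nearest tabulated age with a warning; if the table has a
#' `year` column the nearest available calendar year is used.
#'
#' @param life_table Output of [make_life_table()] or [read_life_table()].
#' @param age,sex Vectors (sex as `"male"`/`"female"`).
#' @param year Calendar year (scalar or vector); ignored for year-invariant
#'   tables.
#' @return Numeric vector of annual death probabilities.
#' @export
life_table_q <- function(life_table, age, sex, year = NULL) {
  lk <- life_table_lookup(life_table)
  lk(age, sex, year)
}

# Returns a fast closure over a [age x sex (x year)] array.
life_table_lookup <- function(life_table) {
  has_year <- "year" %in% names(life_table) && any(!is.na(life_table$year))
  ages <- sort(unique(life_table$age))
  amin <- min(ages); amax <- max(ages)
  if (!has_year) {
    qmat <- matrix(NA_real_, nrow = amax - amin + 1L, ncol = 2L,
                   dimnames = list(NULL, c("female", "male")))
    for (sx in c("female", "male")) {
      sub <- life_table[life_table$sex == sx, ]
      qmat[sub$age - amin + 1L, sx] <- sub$qx
    }
    function(age, sex, year = NULL) {
      if (any(age < amin | age > amax)) {
        warning("age outside life table range; clamped to table bounds")
      }
      a <- pmin(pmax(round(age), amin), amax) - amin + 1L
      qmat[cbind(a, ifelse(sex == "male", 2L, 1L))]
    }
  } else {
    years <- sort(unique(life_table$year))
    qarr <- array(NA_real_, dim = c(amax - amin + 1L, 2L, length(years)))
    for (yi in seq_along(years)) for (si in 1:2) {
      sx <- c("female", "male")[si]
      sub <- life_table[life_table$sex == sx & life_table$year == years[yi], ]
      qarr[sub$age - amin + 1L, si, yi] <- sub$qx
    }
    function(age, sex, year = NULL) {
      if (is.null(year)) year <- years[1]
      if (any(age < amin | age > amax)) {
        warning("age outside life table range; clamped to table bounds")
      }
      a <- pmin(pmax(round(age), amin), amax) - amin + 1L
      yi <- vapply(year, function(y) which.min(abs(years - y)), 1L)
      if (length(yi) == 1L) yi <- rep(yi, length(a))
      qarr[cbind(a, ifelse(sex == "male", 2L, 1L), yi)]
    }
  }
}

#' Annual inflation series
#'
#' Stylised Dutch consumer-price series used to bring reference-year (2015)
#' costs to the simulation start year: 2\% per year historically and 2.5\%
#' from 2022 onward. Override with a real series via `inflation_csv`
#' (columns `year,rate`).
#'
#' @return `data.frame` with columns `year`, `rate` (fractions per year).
#' @export
default_inflation_series <- function() {
  years <- 2015:2040
  data.frame(year = years, rate = ifelse(years < 2022, 0.02, 0.025))
}

#' @rdname default_inflation_series
#' @param path CSV with columns `year,rate`.
#' @export
read_inflation_series <- function(path) {
  if (!file.exists(path)) stop("inflation fixture not found: ", path)
  inf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "rate") %in% names(inf))) {
    stop("inflation CSV must have columns year, rate: ", path)
  }
  inf
}

#' Baseline annual probability of recurrent ischemic stroke
#'
#' The recurrence study underlying the original model tabulates the baseline
#' probability by years since the index stroke; those values are not printed,
#' so the package ships a labelled stand-in: 4\% in the first year declining
#' linearly to 2\% by year 5 and constant thereafter. Override via
#' `recurrence_csv` (columns `years_since,prob`).
#'
#' @return `data.frame` with columns `years_since`, `prob`.
#' @export
default_recurrence_baseline <- function() {
  data.frame(years_since = 1:5, prob = c(0.04, 0.035, 0.03, 0.025, 0.02))
}

#' @rdname default_recurrence_baseline
#' @param path CSV with columns `years_since,prob`.
#' @export
read_recurrence_baseline <- function(path) {
  if (!file.exists(path)) stop("recurrence fixture not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("years_since", "prob") %in% names(rec))) {
    stop("recurrence CSV must have columns years_since, prob: ", path)
  }
  if (any(rec$prob < 0 | rec$prob > 1)) stop("recurrence prob outside [0, 1]")
  rec
}

# Baseline recurrence probability for given years since index stroke; years
# beyond the table carry the last tabulated value forward.
recurrence_baseline_prob <- function(params, years_since) {
  tab <- params$recurrence_baseline
  idx <- pmin(pmax(years_since, min(tab$years_since)), max(tab$years_since))
  tab$prob[match(idx, tab$years_since)]
}

#' Recurrence hazard-ratio table stand-in
#'
#' The published model inflates the baseline recurrence probability with
#' hazard ratios dependent on age and mRS; the table itself is not printed.
#' Stand-in values step from 1.0 (mRS 0-1) to 2.0 (mRS 5) with mild age-band
#' multipliers (higher relative recurrence at younger ages), clamped to
#' [1, 2].
#'
#' @return `data.frame` with columns `age_min`, `age_max`, `mrs_level`
#'   (1 = mRS 0-1 ... 5 = mRS 5), `hr`.
#' @export
default_hr_recurrence <- function() {
  bands <- data.frame(age_min = c(18, 65, 75, 85), age_max = c(64, 74, 84, 110),
                      factor = c(1.1, 1.0, 0.95, 0.9))
  base <- c(1.0, 1.25, 1.5, 1.75, 2.0) # mRS 0-1, 2, 3, 4, 5
  out <- expand.grid(band = seq_len(nrow(bands)), mrs_level = 1:5)
  out$age_min <- bands$age_min[out$band]
  out$age_max <- bands$age_max[out$band]
  out$hr <- pmin(2, pmax(1, base[out$mrs_level] * bands$factor[out$band]))
  out$band <- NULL
  out[, c("age_min", "age_max", "mrs_level", "hr")]
}

# HR lookup as a [band x mrs_level] matrix closure.
hr_recurrence_lookup <- function(hr_table) {
  starts <- sort(unique(hr_table$age_min))
  nb <- length(starts)
  hrmat <- matrix(NA_real_, nb, 5L)
  for (i in seq_len(nrow(hr_table))) {
    b <- match(hr_table$age_min[i], starts)
    hrmat[b, hr_table$mrs_level[i]] <- hr_table$hr[i]
  }
  function(age, mrs) {
    b <- pmax(1L, findInterval(age, starts))
    hrmat[cbind(b, mrs_hr_index(mrs))]
  }
}
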