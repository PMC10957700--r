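#' Distribution specifications for uncertain model inputs
#'
#' Parameter uncertainty is expressed through parametric distributions derived
#' from published summary statistics: log-normal for ratio measures reported
#' as a median with a 95\% confidence interval (odds and hazard ratios), gamma
#' for yearly care costs reported as mean (sd), and beta for mRS-level
#' utilities reported as mean (sd). A degenerate specification (`fixed`)
#' represents point-mass inputs such as unit prices.
#'
#' `dist_lognormal_from_ci()` places the log-scale location at `log(median)`
#' and derives the log-scale scale from the CI width,
#' `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' `dist_gamma_from_mean_sd()` and `dist_beta_from_mean_sd()` use method of
#' moments. A beta specification whose variance is infeasible
#' (`sd^2 >= mean * (1 - mean)`) or whose mean sits on the boundary degrades
#' to a point mass at the mean with a warning.
#'
#' @param median,ci_low,ci_high Positive reals with
#'   `ci_low <= median <= ci_high`.
#' @param mean,sd Summary moments; `sd = 0` yields a point mass.
#' @param value Value of a degenerate (point-mass) distribution.
#' @return An object of class `ctp_dist`: a list with a `family` element and
#'   the family's parameters.
#' @examples
#' dist_lognormal_from_ci(1.67, 1.21, 2.30)
#' dist_gamma_from_mean_sd(33402, 31930)
#' dist_beta_from_mean_sd(0.94, 0.09)
#' @name distributions
NULL

#' @rdname distributions
#' @export
dist_lognormal_from_ci <- function(median, ci_low, ci_high) {
  if (!all(is.finite(c(median, ci_low, ci_high))) ||
      any(c(median, ci_low, ci_high) <= 0)) {
    stop("log-normal specification requires strictly positive median and CI bounds")
  }
  if (!(ci_low <= median && median <= ci_high)) {
    stop("log-normal specification requires ci_low <= median <= ci_high")
  }
  sdlog <- (log(ci_high) - log(ci_low)) / (2 * 1.959964)
  structure(list(family = "lognormal", meanlog = log(median), sdlog = sdlog),
            class = "ctp_dist")
}

#' @rdname distributions
#' @export
dist_gamma_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("gamma specification requires mean > 0")
  if (!is.finite(sd) || sd < 0) stop("gamma specification requires sd >= 0")
  if (sd == 0) return(dist_fixed(mean))
  structure(list(family = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean),
            class = "ctp_dist")
}

#' @rdname distributions
#' @export
dist_beta_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean < 0 || mean > 1) {
    stop("beta specification requires mean in [0, 1]")
  }
  if (!is.finite(sd) || sd < 0) stop("beta specification requires sd >= 0")
  if (sd == 0 || mean %in% c(0, 1)) return(dist_fixed(mean))
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    warning(sprintf(
      "beta specification with mean %.3g, sd %.3g has infeasible variance; using point mass",
      mean, sd))
    return(dist_fixed(mean))
  }
  k <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", shape1 = mean * k, shape2 = (1 - mean) * k),
            class = "ctp_dist")
}

#' @rdname distributions
#' @export
dist_fixed <- function(value) {
  structure(list(family = "fixed", value = value), class = "ctp_dist")
}

#' Draw from a distribution specification
#'
#' Uses the current RNG state.
#'
#' @param spec A `ctp_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "ctp_dist"))
  switch(spec$family,
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    gamma     = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    beta      = stats::rbeta(n, spec$shape1, spec$shape2),
    fixed     = rep(spec$value, n),
    stop("unknown distribution family: ", spec$family)
  )
}

#' @export
print.ctp_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<ctp_dist %s: %s>\n", x$family,
              paste(names(pars), signif(unlist(pars), 5), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
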