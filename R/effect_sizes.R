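draws_matrix <- function(draws) {
  if (inherits(draws, "bsced")) {
    m <- as.matrix(draws, derived = FALSE)
    prior <- draws$prior
  } else {
    m <- as.matrix(draws)
    prior <- sced_prior()
  }
  th0 <- full_theta(NULL, prior)
  need <- c("intercept_p1", "slope_p1", "intercept_p2", "slope_p2",
            "rho", "sigma_eps")
  for (p in setdiff(need, colnames(m))) {
    m <- cbind(m, rep(if (p %in% names(prior$fixed)) th0[[p]] else 0,
                      nrow(m)))
    colnames(m)[ncol(m)] <- p
  }
  m
}

#' Intercept effect size per posterior draw
#'
#' The standardized mean difference of the phase intercepts,
#' `(intercept_p2 - intercept_p1) / sigma_eps`, evaluated elementwise at each
#' retained draw (each draw's own `sigma_eps` in the denominator).
#'
#' @param draws A `bsced` fit or a matrix of draws with named columns
#'   (structural zeros substituted for absent components).
#' @return Numeric vector with one value per draw.
#' @export
es1_draws <- function(draws) {
  m <- draws_matrix(draws)
  (m[, "intercept_p2"] - m[, "intercept_p1"]) / m[, "sigma_eps"]
}

#' Slope effect size per posterior draw
#'
#' The difference between the predicted value at the midpoint of the
#' intervention phase with and without an intervention effect,
#' `(intercept_p2 + M * slope_p2) - (intercept_p1 + M * slope_p1)` with
#' `M = t_b + t_i / 2`, evaluated per draw. For models without slopes this
#' reduces to the intercept difference.
#'
#' @inheritParams es1_draws
#' @param t_b Number of baseline observations.
#' @param t_i Number of intervention-phase observations.
#' @return Numeric vector with one value per draw.
#' @export
es2_draws <- function(draws, t_b, t_i) {
  if (inherits(draws, "bsced")) {
    if (missing(t_b)) t_b <- series_tb(draws$series)
    if (missing(t_i)) t_i <- series_ti(draws$series)
  }
  m <- draws_matrix(draws)
  mm <- t_b + t_i / 2
  (m[, "intercept_p2"] + mm * m[, "slope_p2"]) -
    (m[, "intercept_p1"] + mm * m[, "slope_p1"])
}

#' Equal-tailed credible interval
#'
#' @param lower,upper Interval endpoints.
#' @param level Nominal level in (0, 1).
#' @param truth Optional true value.
#' @return A list of class `sced_ci` with `lower`, `upper`, `level`,
#'   `contains_zero`, and `contains_truth` (NULL when no truth given).
#'   Containment is inclusive at the endpoints.
#' @export
sced_ci <- function(lower, upper, level, truth = NULL) {
  if (lower > upper) stop("lower must not exceed upper")
  structure(
    list(lower = lower, upper = upper, level = level,
         contains_zero = lower <= 0 && 0 <= upper,
         contains_truth = if (is.null(truth)) NULL else
           (lower <= truth && truth <= upper)),
    class = "sced_ci"
  )
}

#' Summarize per-draw values
#'
#' Point estimate is the pooled-chain posterior mean; the interval is the
#' equal-tailed sample quantile interval at the requested level.
#'
#' @param x Numeric vector of per-draw values.
#' @param level Interval level in (0, 1).
#' @param truth Optional true value for truth-containment.
#' @param min_draws Minimum number of draws required (default 100).
#' @return A list with `mean` and `interval` (an [sced_ci()]).
#' @export
#' @examples
#' summarize_draws(c(1, 2, 3), min_draws = 1)$mean # 2
summarize_draws <- function(x, level = 0.95, truth = NULL, min_draws = 100) {
  if (length(x) < min_draws) stop("too few draws")
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  q <- stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  list(mean = mean(x), interval = sced_ci(q[1], q[2], level, truth))
}
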