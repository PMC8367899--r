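#' Pooled posterior draws of a fit
#'
#' @param x A `bsced` fit.
#' @param derived Include the per-draw effect sizes (`ES1`, `ES2`) and the
#'   marginal residual SD (`sigma_e`) as extra columns.
#' @param ... Unused.
#' @return Matrix with one row per retained draw (chains stacked) and one
#'   column per free parameter (plus derived quantities).
#' @export
as.matrix.bsced <- function(x, derived = TRUE, ...) {
  m <- do.call(rbind, x$chains)
  if (derived) m <- cbind(m, do.call(rbind, x$derived))
  m
}

#' @export
print.bsced <- function(x, ...) {
  cat(sprintf("Bayesian two-phase interrupted time-series fit (%s model)\n",
              x$model$name))
  cat(sprintf("  series: %d + %d observations\n", series_tb(x$series),
              series_ti(x$series)))
  cat(sprintf("  %d chain(s) x %d retained draws (%d round(s))\n",
              length(x$chains), nrow(x$chains[[1]]), x$rounds))
  cat(sprintf("  converged: %s (MPSRF %.3f)\n", x$converged,
              if (is.na(x$mpsrf)) NA else x$mpsrf))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Posterior means of the model parameters
#'
#' @param object A `bsced` fit.
#' @param ... Unused.
#' @return Named vector of posterior means of the free parameters.
#' @export
coef.bsced <- function(object, ...) {
  colMeans(as.matrix(object, derived = FALSE))
}

#' Posterior summary table
#'
#' One row per free parameter and derived quantity: posterior mean, SD,
#' equal-tailed credible interval, zero-containment, and (when the true
#' generative values are known) truth-containment.
#'
#' @param object A `bsced` fit.
#' @param level Credible-interval level; defaults to the control setting.
#' @param ... Unused.
#' @return A data frame of class `summary.bsced`.
#' @export
summary.bsced <- function(object, level = object$control$level, ...) {
  m <- as.matrix(object)
  truth <- fit_truth_values(object)
  rows <- lapply(colnames(m), function(p) {
    s <- summarize_draws(m[, p], level = level,
                         truth = if (p %in% names(truth)) truth[[p]] else NULL,
                         min_draws = 1)
    data.frame(parameter = p, mean = s$mean, sd = stats::sd(m[, p]),
               lower = s$interval$lower, upper = s$interval$upper,
               contains_zero = s$interval$contains_zero,
               contains_truth = if (is.null(s$interval$contains_truth))
                 NA else s$interval$contains_truth,
               truth = if (p %in% names(truth)) truth[[p]] else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  attr(out, "mpsrf") <- object$mpsrf
  attr(out, "converged") <- object$converged
  class(out) <- c("summary.bsced", "data.frame")
  out
}

#' @export
print.summary.bsced <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (%.0f%% equal-tailed credible intervals)\n",
              100 * attr(x, "level")))
  cat(sprintf("MPSRF %.3f, converged: %s\n", attr(x, "mpsrf"),
              attr(x, "converged")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# true values on the fitted-parameter scale, from an sced_params or named list
fit_truth_values <- function(object) {
  tp <- object$truth
  if (is.null(tp)) return(list())
  if (inherits(tp, "sced_params")) {
    list(intercept_p1 = tp$intercept_p1, slope_p1 = tp$slope_p1,
         intercept_p2 = tp$intercept_p2, slope_p2 = tp$slope_p2,
         rho = tp$rho, sigma_eps = tp$sigma_eps,
         ES1 = tp$es1_true, ES2 = tp$es2_true,
         sigma_e = tp$sigma_eps / sqrt(1 - tp$rho^2))
  } else {
    as.list(tp)
  }
}

# regression mean at given parameter values for phase/time columns
sced_mean <- function(theta, phase, time, t_b) {
  ifelse(phase == 1L,
         theta[["intercept_p1"]] + theta[["slope_p1"]] * time,
         theta[["intercept_p2"]] + theta[["slope_p2"]] * (time - t_b))
}

#' Posterior-mean regression line
#'
#' @param object A `bsced` fit.
#' @param newdata Optional data frame with `phase` and `time` columns;
#'   defaults to the fitted series.
#' @param ... Unused.
#' @return Numeric vector of predicted means.
#' @export
predict.bsced <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$series
  cf <- coef(object)
  th <- full_theta(NULL, object$prior)
  th[names(cf)] <- cf
  sced_mean(as.list(th), newdata$phase, newdata$time, series_tb(object$series))
}

#' @export
fitted.bsced <- function(object, ...) predict(object)

#' Raw residuals from the posterior-mean regression line
#'
#' @param object A `bsced` fit.
#' @param ... Unused.
#' @return Numeric vector `value - fitted`.
#' @export
residuals.bsced <- function(object, ...) {
  object$series$value - predict(object)
}

#' Posterior-predictive simulation
#'
#' Draws parameter vectors from the pooled posterior and simulates new
#' two-phase series from them (same phase lengths and error-recursion mode as
#' the fitted series).
#'
#' @param object A `bsced` fit.
#' @param nsim Number of series.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `sced_series` objects.
#' @export
simulate.bsced <- function(object, nsim = 1, seed = 1L, ...) {
  m <- as.matrix(object, derived = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(m), nsim, replace = TRUE)
  sub_seeds <- vapply(seq_len(nsim), function(i) sced_seed(seed, i, 1L), 1L)
  tb <- series_tb(object$series)
  lapply(seq_len(nsim), function(i) {
    th <- full_theta(NULL, object$prior)
    th[colnames(m)] <- m[idx[i], ]
    tp <- structure(
      list(intercept_p1 = th[["intercept_p1"]], slope_p1 = th[["slope_p1"]],
           intercept_p2 = th[["intercept_p2"]], slope_p2 = th[["slope_p2"]],
           rho = th[["rho"]], sigma_eps = th[["sigma_eps"]],
           t_b = tb, t_i = series_ti(object$series),
           gen = sced_gen_config(boundary = object$control$boundary)),
      class = "sced_params"
    )
    sced_simulate(tp, sub_seeds[i])
  })
}

#' Plot a fit
#'
#' `which = "fit"` draws the series with the posterior-mean regression lines;
#' `which = "trace"` draws per-chain trace plots of the free parameters.
#'
#' @param x A `bsced` fit.
#' @param which `"fit"` or `"trace"`.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.bsced <- function(x, which = c("fit", "trace"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    plot(x$series, ...)
    tb <- series_tb(x$series)
    f <- fitted(x)
    graphics::lines(seq_len(tb), f[seq_len(tb)], col = "grey30", lwd = 2)
    graphics::lines((tb + 1):length(f), f[(tb + 1):length(f)],
                    col = "firebrick", lwd = 2)
  } else {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(x$free)),
                         mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (p in x$free) {
      tr <- sapply(x$chains, function(ch) ch[, p])
      graphics::matplot(tr, type = "l", lty = 1, ylab = p, ...)
    }
  }
  invisible(x)
}

#' @export
confint.bsced <- function(object, parm, level = 0.95, ...) {
  m <- as.matrix(object)
  if (missing(parm)) parm <- colnames(m)
  t(vapply(parm, function(p) {
    stats::quantile(m[, p], c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  }, numeric(2)))
}
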