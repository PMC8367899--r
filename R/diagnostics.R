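#' Root mean squared error of point estimates
#'
#' `sqrt(mean((x_i - X)^2))` over replications for a parameter with true value
#' `X`.
#'
#' @param estimates Numeric vector of per-replication point estimates.
#' @param truth True value (scalar).
#' @return Non-negative scalar.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0) stop("empty input")
  sqrt(mean((estimates - truth)^2))
}

#' Mean relative bias of point estimates
#'
#' `mean(x_i - X) / X`; undefined (NA) when the true value is 0, since the
#' ratio has no meaning there. The result carries a `substantial` attribute
#' flagging absolute relative bias above 0.05.
#'
#' @inheritParams rmse
#' @return Scalar with attribute `substantial`, or `NA` when `truth == 0`.
#' @export
relative_bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("empty input")
  if (truth == 0) return(NA_real_)
  out <- mean(estimates - truth) / truth
  attr(out, "substantial") <- abs(out) > 0.05
  out
}

ci_bounds <- function(intervals) {
  if (inherits(intervals, "sced_ci")) intervals <- list(intervals)
  if (is.data.frame(intervals) || is.matrix(intervals)) {
    lo <- intervals[, "lower"]
    hi <- intervals[, "upper"]
  } else {
    lo <- vapply(intervals, function(ci) ci$lower, 1)
    hi <- vapply(intervals, function(ci) ci$upper, 1)
  }
  if (length(lo) == 0) stop("empty input")
  list(lower = as.numeric(lo), upper = as.numeric(hi))
}

#' Coverage and 0-coverage of interval estimates
#'
#' Coverage is the percentage of intervals containing the true value;
#' 0-coverage the percentage containing 0 (excess 0-coverage of a truly
#' nonzero parameter signals type II error risk). Containment is inclusive at
#' the endpoints. Both are reported on the 0-100 scale.
#'
#' @param intervals A list of [sced_ci()] objects, or a data frame/matrix with
#'   `lower` and `upper` columns.
#' @param truth True value.
#' @return Percentage in [0, 100].
#' @export
coverage <- function(intervals, truth) {
  b <- ci_bounds(intervals)
  100 * mean(b$lower <= truth & truth <= b$upper)
}

#' @rdname coverage
#' @export
zero_coverage <- function(intervals) {
  coverage(intervals, 0)
}

#' Indeterminacy cross-tab of autocorrelation and phase-2 slope intervals
#'
#' Partitions paired credible intervals into the four zero-containment
#' classes: both contain 0 (trend attributable to neither source with
#' certainty), only the autocorrelation interval, only the slope interval, or
#' neither. A large "both" share signals indeterminacy between slope and
#' autocorrelation as explanations of trend.
#'
#' @param rho_cis,b22_cis Paired interval collections (same format as
#'   [coverage()]), one pair per dataset.
#' @return A list of class `sced_crosstab` with `pct_both`, `pct_rho_only`,
#'   `pct_b22_only`, `pct_neither`, and `n_datasets`.
#' @export
indeterminacy_crosstab <- function(rho_cis, b22_cis) {
  r <- ci_bounds(rho_cis)
  b <- ci_bounds(b22_cis)
  if (length(r$lower) != length(b$lower)) stop("length mismatch")
  rz <- r$lower <= 0 & 0 <= r$upper
  bz <- b$lower <= 0 & 0 <= b$upper
  n <- length(rz)
  structure(
    list(pct_both = 100 * mean(rz & bz),
         pct_rho_only = 100 * mean(rz & !bz),
         pct_b22_only = 100 * mean(!rz & bz),
         pct_neither = 100 * mean(!rz & !bz),
         n_datasets = n),
    class = "sced_crosstab"
  )
}

#' @export
print.sced_crosstab <- function(x, ...) {
  cat(sprintf(
    "0-containment of rho and phase-2 slope CIs over %d datasets:\n",
    x$n_datasets))
  cat(sprintf("  both %.2f%% | rho only %.2f%% | slope only %.2f%% | neither %.2f%%\n",
              x$pct_both, x$pct_rho_only, x$pct_b22_only, x$pct_neither))
  invisible(x)
}

#' Replication adequacy from cumulative RMSE traces
#'
#' Computes the cumulative RMSE after each replication and returns the
#' smallest index `k` after which every successive change of the cumulative
#' RMSE stays below `window_threshold`. Used to judge whether the number of
#' Monte-Carlo replications per condition suffices.
#'
#' @param estimates Per-replication point estimates (>= 10 unless
#'   `min_replications` is lowered).
#' @param truth True value.
#' @param window_threshold Maximum tolerated successive change (default 0.03).
#' @param min_replications Minimum trace length.
#' @return Integer index, or `NA` (sentinel "not reached") when the trace
#'   never settles (its last successive change still exceeds the threshold).
#' @export
replication_adequacy <- function(estimates, truth, window_threshold = 0.03,
                                 min_replications = 10) {
  n <- length(estimates)
  if (n < min_replications) stop("need at least ", min_replications,
                                 " replications")
  cum <- sqrt(cumsum((estimates - truth)^2) / seq_len(n))
  d <- abs(diff(cum))
  viol <- which(d >= window_threshold)
  if (length(viol) == 0) return(1L)
  if (max(viol) == n - 1L) return(NA_integer_)
  max(viol) + 1L
}

#' Per-condition recovery diagnostics from per-fit summary rows
#'
#' Aggregates a long table of per-fit posterior summaries (as produced by
#' [run_study()]) into one row per (condition, model, parameter): RMSE of the
#' posterior means, mean bias, relative bias (NA when the truth is 0),
#' coverage and 0-coverage percentages, mean posterior SD, and convergence
#' counts.
#'
#' @param fits Data frame with columns `condition`, `model`, `parameter`,
#'   `estimate`, `post_sd`, `lower`, `upper`, `truth`, `converged` (plus any
#'   design columns, which are carried through).
#' @param converged_only Drop non-converged fits before aggregating (default
#'   keeps them; they are always counted in `n_converged`).
#' @return A data frame of class `sced_diagnostics`.
#' @export
sced_diagnostics <- function(fits, converged_only = FALSE) {
  need <- c("condition", "model", "parameter", "estimate", "post_sd",
            "lower", "upper", "truth", "converged")
  if (!all(need %in% names(fits))) {
    stop("fits is missing columns: ",
         paste(setdiff(need, names(fits)), collapse = ", "))
  }
  design_cols <- intersect(.sced_factors, names(fits))
  key <- interaction(fits$condition, fits$model, fits$parameter, drop = TRUE)
  rows <- lapply(split(fits, key), function(g) {
    n_total <- nrow(g)
    n_conv <- sum(g$converged)
    if (converged_only) g <- g[g$converged, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    truth <- g$truth[1]
    cbind(
      data.frame(condition = g$condition[1], model = g$model[1],
                 parameter = g$parameter[1]),
      g[1, design_cols, drop = FALSE],
      data.frame(
        truth = truth,
        rmse = rmse(g$estimate, truth),
        mean_bias = mean(g$estimate - truth),
        relative_bias = as.numeric(relative_bias(g$estimate, truth)),
        coverage_pct = coverage(g[, c("lower", "upper")], truth),
        zero_coverage_pct = zero_coverage(g[, c("lower", "upper")]),
        mean_posterior_sd = mean(g$post_sd),
        n_replications = n_total,
        n_converged = n_conv
      )
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$model, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("sced_diagnostics", "data.frame")
  out
}
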