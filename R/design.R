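#' Default factor levels of the simulation design
#'
#' The fully crossed Monte-Carlo design covers phase length (observations per
#' phase, both phases equal), white-noise standard deviation, intercept effect
#' size, slope effect size, and lag-1 autocorrelation of the residuals.
#'
#' @return Named list of numeric level vectors with elements `phase_length`,
#'   `sigma_eps`, `es1`, `es2`, `rho`.
#' @export
#' @examples
#' lengths(sced_factor_defaults())
sced_factor_defaults <- function() {
  list(
    phase_length = c(5, 8, 10, 15),
    sigma_eps = c(1, 2, 5),
    es1 = c(0.5, 1, 2, 5),
    es2 = c(0, 0.3, 0.5, 1),
    rho = c(0, 0.2, 0.5, 0.8)
  )
}

.sced_factors <- c("phase_length", "sigma_eps", "es1", "es2", "rho")

#' Enumerate the factorial design
#'
#' Builds the full Cartesian product of the design factor levels. Rows are
#' deterministically ordered with `phase_length` varying slowest and `rho`
#' fastest (then `es2`, `es1`, `sigma_eps` in between), and carry a 1-based
#' `condition` index used for reproducible per-dataset seeding.
#'
#' @param factor_levels Named list of level vectors as in
#'   [sced_factor_defaults()]; every factor must have at least one level.
#' @return A data frame of class `sced_design` with one row per condition and
#'   columns `condition`, `phase_length`, `sigma_eps`, `es1`, `es2`, `rho`.
#' @export
#' @examples
#' nrow(sced_conditions()) # 768
sced_conditions <- function(factor_levels = sced_factor_defaults()) {
  for (f in .sced_factors) {
    lv <- factor_levels[[f]]
    if (is.null(lv) || length(lv) == 0) stop("empty design factor: ", f)
    if (!is.numeric(lv) || anyNA(lv)) stop("invalid levels for factor: ", f)
  }
  if (any(factor_levels$phase_length < 2) ||
      any(factor_levels$phase_length != round(factor_levels$phase_length)))
    stop("phase_length levels must be integers >= 2")
  if (any(factor_levels$sigma_eps <= 0)) stop("sigma_eps levels must be > 0")
  if (any(abs(factor_levels$rho) >= 1)) stop("rho levels must lie in (-1, 1)")
  g <- expand.grid(
    rho = factor_levels$rho,
    es2 = factor_levels$es2,
    es1 = factor_levels$es1,
    sigma_eps = factor_levels$sigma_eps,
    phase_length = factor_levels$phase_length,
    KEEP.OUT.ATTRS = FALSE
  )
  g <- g[, rev(names(g))]
  g <- cbind(condition = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  class(g) <- c("sced_design", "data.frame")
  g
}

#' Generation settings mapping design factors to true parameters
#'
#' @param baseline_intercept True phase-1 intercept; the design factors do not
#'   pin it down, so it defaults to 20, the centre of the 0-50 range the
#'   intercept prior means live on.
#' @param baseline_slope True phase-1 slope (default 0: no pre-intervention
#'   trend; the slope effect size is carried entirely by phase 2).
#' @param es2_mapping How the slope effect size determines the phase-2 slope.
#'   `"pure_slope"` (default) assigns the whole effect to the slope-difference
#'   term, `beta22 = es2 / (t_b + t_i/2)`; `"literal"` inverts the full
#'   mid-intervention contrast including the intercept change,
#'   `beta22 = beta21 + (es2 - es1 * sigma_eps) / (t_b + t_i/2)`.
#' @param init SD of the first residual of a phase: `"eq1"` (default) draws it
#'   with the innovation SD `sigma_eps`; `"stationary"` uses the marginal AR(1)
#'   SD `sigma_eps / sqrt(1 - rho^2)`.
#' @param boundary `"reset"` (default) restarts the error recursion at the
#'   phase boundary; `"carry"` runs a single AR(1) process across both phases.
#' @return A list of class `sced_gen_config`.
#' @export
sced_gen_config <- function(baseline_intercept = 20, baseline_slope = 0,
                            es2_mapping = c("pure_slope", "literal"),
                            init = c("eq1", "stationary"),
                            boundary = c("reset", "carry")) {
  structure(
    list(
      baseline_intercept = baseline_intercept,
      baseline_slope = baseline_slope,
      es2_mapping = match.arg(es2_mapping),
      init = match.arg(init),
      boundary = match.arg(boundary)
    ),
    class = "sced_gen_config"
  )
}

#' True generative parameters for one design condition
#'
#' Inverts the effect-size definitions to obtain regression parameters: the
#' phase-2 intercept is `beta11 + es1 * sigma_eps` (standardized mean
#' difference of the phase intercepts), and the phase-2 slope follows the
#' chosen `es2_mapping`. The true effect sizes stored in the result are always
#' recomputed from the betas with the same formulas the estimator uses
#' (`es1_true = (beta12 - beta11)/sigma_eps`;
#' `es2_true = (beta12 + M*beta22) - (beta11 + M*beta21)` with
#' `M = t_b + t_i/2`), so recovery diagnostics are internally coherent under
#' either mapping.
#'
#' @param cond One row of an [sced_conditions()] design (or a list with the
#'   same fields).
#' @param gen An [sced_gen_config()].
#' @return A list of class `sced_params` with elements `intercept_p1`,
#'   `slope_p1`, `intercept_p2`, `slope_p2`, `rho`, `sigma_eps`, `t_b`, `t_i`,
#'   `es1_true`, `es2_true`, and the `gen` config used.
#' @export
#' @examples
#' tp <- true_params(list(phase_length = 5, sigma_eps = 2, es1 = 1,
#'                        es2 = 1, rho = 0.2))
#' tp$intercept_p2 # 22
true_params <- function(cond, gen = sced_gen_config()) {
  l <- as.integer(cond$phase_length)
  sig <- cond$sigma_eps
  if (l < 2) stop("phase_length must be >= 2")
  if (sig <= 0) stop("sigma_eps must be > 0")
  if (abs(cond$rho) >= 1) stop("rho must lie in (-1, 1)")
  t_b <- l
  t_i <- l
  m <- t_b + t_i / 2
  b11 <- gen$baseline_intercept
  b21 <- gen$baseline_slope
  b12 <- b11 + cond$es1 * sig
  b22 <- switch(gen$es2_mapping,
    pure_slope = cond$es2 / m,
    literal = b21 + (cond$es2 - cond$es1 * sig) / m
  )
  out <- list(
    intercept_p1 = b11, slope_p1 = b21,
    intercept_p2 = b12, slope_p2 = b22,
    rho = cond$rho, sigma_eps = sig,
    t_b = t_b, t_i = t_i,
    es1_true = (b12 - b11) / sig,
    es2_true = (b12 + m * b22) - (b11 + m * b21),
    gen = gen
  )
  class(out) <- "sced_params"
  out
}

#' @export
print.sced_params <- function(x, ...) {
  cat("Two-phase SCED generative parameters\n")
  cat(sprintf("  phase 1: intercept %.4g, slope %.4g\n",
              x$intercept_p1, x$slope_p1))
  cat(sprintf("  phase 2: intercept %.4g, slope %.4g\n",
              x$intercept_p2, x$slope_p2))
  cat(sprintf("  rho %.3g, sigma_eps %.3g, t_b %d, t_i %d\n",
              x$rho, x$sigma_eps, x$t_b, x$t_i))
  cat(sprintf("  true effect sizes: ES1 %.4g, ES2 %.4g\n",
              x$es1_true, x$es2_true))
  invisible(x)
}

#' Deterministic seed derivation
#'
#' Derives a reproducible 31-bit seed from a root seed and two indices
#' (typically condition and replication), so any single simulated dataset or
#' fit can be regenerated in isolation, independent of execution order.
#'
#' @param root Integer root seed.
#' @param a,b Integer indices.
#' @return A strictly positive integer below 2^31 - 1.
#' @export
sced_seed <- function(root, a = 0L, b = 0L) {
  cpp_seed_hash(as.integer(root), as.integer(a), as.integer(b))
}
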