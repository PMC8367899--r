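#' @useDynLib bsced, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# canonical parameter layout shared by all models (order matters: it matches
# the C++ core)
sced_par_names <- c(
  "intercept_p1", "slope_p1", "intercept_p2", "slope_p2",
  "rho", "sigma_eps",
  "mu_int_p1", "mu_int_p2", "mu_slope_p1", "mu_slope_p2",
  "var_int", "var_slope",
  "gmode_int", "gsd_int", "gmode_slope", "gsd_slope"
)

.slope_block <- c("slope_p1", "slope_p2", "mu_slope_p1", "mu_slope_p2",
                  "var_slope", "gmode_slope", "gsd_slope")
.int_block <- c("intercept_p1", "intercept_p2", "mu_int_p1", "mu_int_p2",
                "var_int", "gmode_int", "gsd_int")

#' The four Bayesian two-phase model structures
#'
#' `IO` estimates phase intercepts only; `NS` adds the lag-1 autocorrelation
#' but no slopes; `SI` adds phase slopes but no autocorrelation; `SA` estimates
#' intercepts, slopes, and the autocorrelation. Components a model does not
#' estimate are fixed at 0 and never sampled.
#'
#' @param name One of `"IO"`, `"NS"`, `"SI"`, `"SA"` (case-insensitive), or an
#'   existing `sced_model_spec`.
#' @return A list of class `sced_model_spec` with fields `name`, `has_slopes`,
#'   `has_autocorrelation`.
#' @export
#' @examples
#' sced_model("SA")
sced_model <- function(name) {
  if (inherits(name, "sced_model_spec")) return(name)
  name <- toupper(name)
  if (!name %in% c("IO", "NS", "SI", "SA")) {
    stop("unknown model: ", name, " (expected IO, NS, SI or SA)")
  }
  structure(
    list(
      name = name,
      has_slopes = name %in% c("SI", "SA"),
      has_autocorrelation = name %in% c("NS", "SA")
    ),
    class = "sced_model_spec"
  )
}

#' @export
print.sced_model_spec <- function(x, ...) {
  cat(sprintf("SCED model %s: slopes %s, autocorrelation %s\n", x$name,
              if (x$has_slopes) "yes" else "no",
              if (x$has_autocorrelation) "yes" else "no"))
  invisible(x)
}

#' Weakly informative prior configuration
#'
#' The hierarchy: phase intercepts are normal around phase-specific means
#' `mu_int_pp ~ unif(mu_int_range)` with common variance `var_int`; phase
#' slopes are normal around `mu_slope_pp ~ norm(mu_slope_mean, mu_slope_sd)`
#' with common variance `var_slope`; the intercept and slope variances are
#' drawn from gamma distributions whose mode and SD are themselves uniform on
#' `hyper_range`; `sigma_eps ~ unif(sigma_eps_range)` and
#' `rho ~ unif(rho_range)`.
#'
#' @param mu_int_range Support of the uniform prior on intercept prior means.
#' @param mu_slope_mean,mu_slope_sd Normal prior on slope prior means.
#' @param sigma_eps_range Support of the uniform prior on the innovation SD.
#' @param rho_range Support of the uniform prior on the autocorrelation.
#' @param hyper_range Support of the uniform priors on the gamma hyperprior's
#'   mode and SD.
#' @param hyper_scale Whether the gamma hyperprior governs the `"variance"`
#'   (default) or the `"sd"` of the intercept/slope distributions.
#' @param fixed Named list pinning any parameter in the canonical layout to a
#'   constant (a degenerate prior); fixed parameters are removed from the
#'   sampled set. Fixing `var_int`/`var_slope` also drops the corresponding
#'   gamma hyperparameters.
#' @return A list of class `sced_prior`.
#' @export
sced_prior <- function(mu_int_range = c(0, 50), mu_slope_mean = 0,
                       mu_slope_sd = 1, sigma_eps_range = c(0.1, 5),
                       rho_range = c(-1, 1), hyper_range = c(0.01, 1),
                       hyper_scale = c("variance", "sd"), fixed = list()) {
  if (length(fixed) && !all(names(fixed) %in% sced_par_names)) {
    stop("unknown parameter in fixed: ",
         paste(setdiff(names(fixed), sced_par_names), collapse = ", "))
  }
  structure(
    list(
      mu_int_range = mu_int_range, mu_slope_mean = mu_slope_mean,
      mu_slope_sd = mu_slope_sd, sigma_eps_range = sigma_eps_range,
      rho_range = rho_range, hyper_range = hyper_range,
      hyper_scale = match.arg(hyper_scale), fixed = fixed
    ),
    class = "sced_prior"
  )
}

prior_cfg_vec <- function(prior) {
  c(prior$mu_int_range, prior$mu_slope_mean, prior$mu_slope_sd,
    prior$sigma_eps_range, prior$rho_range, prior$hyper_range,
    if (prior$hyper_scale == "sd") 1 else 0)
}

#' Free (sampled) parameters of a model under a prior
#'
#' @param model A model name or [sced_model()] spec.
#' @param prior An [sced_prior()].
#' @return Character vector of free parameter names in canonical order.
#' @export
free_params <- function(model, prior = sced_prior()) {
  model <- sced_model(model)
  keep <- c(.int_block, "sigma_eps")
  if (model$has_slopes) keep <- c(keep, .slope_block)
  if (model$has_autocorrelation) keep <- c(keep, "rho")
  fixed <- names(prior$fixed)
  if ("var_int" %in% fixed) fixed <- c(fixed, "gmode_int", "gsd_int")
  if ("var_slope" %in% fixed) fixed <- c(fixed, "gmode_slope", "gsd_slope")
  sced_par_names[sced_par_names %in% setdiff(keep, fixed)]
}

# expand a partial named parameter vector/list to the full canonical layout;
# unspecified structural components are 0, unspecified hyper mode/sd are set
# to an arbitrary valid value (only relevant when their block is inactive)
full_theta <- function(params, prior = sced_prior()) {
  th <- stats::setNames(numeric(16), sced_par_names)
  th[c("gmode_int", "gsd_int", "gmode_slope", "gsd_slope")] <- 0.5
  th[c("var_int", "var_slope")] <- 1
  th["sigma_eps"] <- 1
  if (length(prior$fixed)) th[names(prior$fixed)] <- unlist(prior$fixed)
  p <- unlist(params)
  if (length(p)) {
    bad <- setdiff(names(p), sced_par_names)
    if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
    th[names(p)] <- p
  }
  th
}

#' Conditional log-likelihood of a two-phase AR(1) model
#'
#' Exact conditional log-density of the series: the first point of each phase
#' (of the whole series in carry-over mode) is Gaussian around the regression
#' mean with SD `sigma_eps`; every later point is Gaussian around the
#' regression mean plus `rho` times the previous raw residual, with innovation
#' SD `sigma_eps`. For models without slopes or autocorrelation the
#' corresponding components are 0 and the expression reduces to the nested
#' model's likelihood.
#'
#' @param model A model name or [sced_model()] spec (used for validation; the
#'   density is evaluated at the supplied parameter values).
#' @param params Named numeric vector/list with (a subset of) the canonical
#'   parameters; omitted structural components are 0.
#' @param series An `sced_series` (or coercible data frame).
#' @param boundary `"reset"` or `"carry"` error recursion at the phase
#'   boundary.
#' @return The log-likelihood (a scalar; `-Inf` for invalid `rho`/`sigma_eps`).
#' @export
#' @examples
#' s <- as_sced_series(data.frame(phase = c(1, 1, 2, 2), time = 1:4,
#'                                value = c(0.3, -0.2, 0.1, 0.4)))
#' log_likelihood("IO", c(intercept_p1 = 0, intercept_p2 = 0, sigma_eps = 1), s)
log_likelihood <- function(model, params, series,
                           boundary = c("reset", "carry")) {
  model <- sced_model(model)
  boundary <- match.arg(boundary)
  series <- as_sced_series(series)
  th <- full_theta(params)
  if (!model$has_slopes && any(th[c("slope_p1", "slope_p2")] != 0)) {
    stop("model ", model$name, " fixes slopes at 0")
  }
  if (!model$has_autocorrelation && th["rho"] != 0) {
    stop("model ", model$name, " fixes rho at 0")
  }
  tp <- attr(series, "params")
  if (!is.null(tp) && !is.null(tp$t_b) && tp$t_b != series_tb(series)) {
    stop("series t_b does not match its phase labels")
  }
  cpp_loglik(series$value, series_tb(series), unname(th),
             boundary == "carry")
}

#' Hierarchical log-prior density
#'
#' Sum of the log-densities of all free components of `model` under the prior
#' hierarchy; returns `-Inf` outside the support. Fixed components (degenerate
#' priors) contribute nothing.
#'
#' @inheritParams log_likelihood
#' @param prior An [sced_prior()].
#' @return The log-prior density (a scalar, possibly `-Inf`).
#' @export
log_prior <- function(model, params, prior = sced_prior()) {
  model <- sced_model(model)
  th <- full_theta(params, prior)
  fr <- as.integer(sced_par_names %in% free_params(model, prior))
  cpp_logprior(unname(th), fr, prior_cfg_vec(prior))
}

#' Gamma shape and rate from mode and standard deviation
#'
#' Solves for the gamma distribution with the requested mode
#' `(shape - 1)/rate` and variance `sd^2`; the solution always has
#' `shape > 1`, so the density vanishes at 0.
#'
#' @param mode,sd Positive reals.
#' @return Named numeric vector `c(shape, rate)`.
#' @export
#' @examples
#' gamma_from_mode_sd(1, 1) # rate = (1 + sqrt(5))/2
gamma_from_mode_sd <- function(mode, sd) {
  if (!is.numeric(mode) || !is.numeric(sd) || any(mode <= 0) || any(sd <= 0)) {
    stop("mode and sd must be positive")
  }
  rate <- (mode + sqrt(mode^2 + 4 * sd^2)) / (2 * sd^2)
  c(shape = 1 + mode * rate, rate = rate)
}

#' Draw a parameter vector from the prior
#'
#' Samples the hierarchy top-down (gamma hyperparameters, variances, prior
#' means, regression coefficients, `sigma_eps`, `rho`), honouring any fixed
#' components; used for chain initialization and prior-predictive simulation.
#'
#' @inheritParams log_prior
#' @return Full named parameter vector in the canonical layout (structural
#'   zeros included).
#' @export
sced_prior_draw <- function(model, prior = sced_prior()) {
  model <- sced_model(model)
  fr <- free_params(model, prior)
  th <- full_theta(NULL, prior)
  th[setdiff(sced_par_names, c(names(prior$fixed), fr))] <- 0
  hr <- prior$hyper_range
  draw_var <- function(vname, gm, gs) {
    if (gm %in% fr) th[gm] <<- stats::runif(1, hr[1], hr[2])
    if (gs %in% fr) th[gs] <<- stats::runif(1, hr[1], hr[2])
    if (vname %in% fr) {
      ab <- gamma_from_mode_sd(th[[gm]], th[[gs]])
      g <- stats::rgamma(1, shape = ab[["shape"]], rate = ab[["rate"]])
      th[vname] <<- if (prior$hyper_scale == "sd") g^2 else g
    }
  }
  draw_var("var_int", "gmode_int", "gsd_int")
  draw_var("var_slope", "gmode_slope", "gsd_slope")
  ir <- prior$mu_int_range
  for (p in c("mu_int_p1", "mu_int_p2")) {
    if (p %in% fr) th[p] <- stats::runif(1, ir[1], ir[2])
  }
  for (p in c("mu_slope_p1", "mu_slope_p2")) {
    if (p %in% fr) th[p] <- stats::rnorm(1, prior$mu_slope_mean,
                                         prior$mu_slope_sd)
  }
  s_int <- sqrt(th[["var_int"]])
  s_slope <- sqrt(th[["var_slope"]])
  if ("intercept_p1" %in% fr) th["intercept_p1"] <-
    stats::rnorm(1, th[["mu_int_p1"]], s_int)
  if ("intercept_p2" %in% fr) th["intercept_p2"] <-
    stats::rnorm(1, th[["mu_int_p2"]], s_int)
  if ("slope_p1" %in% fr) th["slope_p1"] <-
    stats::rnorm(1, th[["mu_slope_p1"]], s_slope)
  if ("slope_p2" %in% fr) th["slope_p2"] <-
    stats::rnorm(1, th[["mu_slope_p2"]], s_slope)
  if ("sigma_eps" %in% fr) th["sigma_eps"] <-
    stats::runif(1, prior$sigma_eps_range[1], prior$sigma_eps_range[2])
  if ("rho" %in% fr) th["rho"] <-
    stats::runif(1, prior$rho_range[1], prior$rho_range[2])
  th
}
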