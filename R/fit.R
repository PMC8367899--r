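#' Sampler settings
#'
#' @param chains Number of MCMC chains (the multivariate R-hat needs at least
#'   2; default 4).
#' @param burn_in Adaptation/burn-in iterations per chain, discarded.
#' @param draws Retained draws per chain per convergence round.
#' @param thin Thinning interval.
#' @param mpsrf_threshold Convergence cut-off for the multivariate potential
#'   scale reduction factor.
#' @param hw_alpha Significance level of the Heidelberger-Welch stationarity
#'   test applied to every free parameter of every chain.
#' @param hw_eps Relative half-width tolerance (reported, not gating).
#' @param max_rounds Maximum convergence rounds; each failed round extends
#'   every chain by another `draws` iterations. A fit that still fails is
#'   returned with `converged = FALSE`, never discarded.
#' @param boundary Error-recursion treatment at the phase boundary in the
#'   likelihood (`"reset"` per the first-point-of-phase convention, or
#'   `"carry"`).
#' @param level Credible-interval level used by `summary()`.
#' @param profile Convenience presets: `"desk"` (the defaults) or `"paper"`
#'   (burn-in 100,000, 10,000 retained draws per chain).
#' @return A list of class `sced_control`.
#' @export
sced_control <- function(chains = 4L, burn_in = 2000L, draws = 4000L,
                         thin = 1L, mpsrf_threshold = 1.1, hw_alpha = 0.01,
                         hw_eps = 0.1, max_rounds = 2L,
                         boundary = c("reset", "carry"), level = 0.95,
                         profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("desk", "paper"))
    if (profile == "paper") {
      burn_in <- 100000L
      draws <- 10000L
    }
  }
  stopifnot(chains >= 1, burn_in >= 0, draws >= 1, thin >= 1, max_rounds >= 1)
  structure(
    list(chains = as.integer(chains), burn_in = as.integer(burn_in),
         draws = as.integer(draws), thin = as.integer(thin),
         mpsrf_threshold = mpsrf_threshold, hw_alpha = hw_alpha,
         hw_eps = hw_eps, max_rounds = as.integer(max_rounds),
         boundary = match.arg(boundary), level = level),
    class = "sced_control"
  )
}

# transform spec (type/lo/hi) for each free parameter
par_transforms <- function(fr, prior) {
  type <- integer(length(fr))
  lo <- numeric(length(fr))
  hi <- numeric(length(fr))
  for (j in seq_along(fr)) {
    p <- fr[j]
    if (p %in% c("mu_int_p1", "mu_int_p2")) {
      type[j] <- 1L; lo[j] <- prior$mu_int_range[1]; hi[j] <- prior$mu_int_range[2]
    } else if (p == "sigma_eps") {
      type[j] <- 1L; lo[j] <- prior$sigma_eps_range[1]; hi[j] <- prior$sigma_eps_range[2]
    } else if (p == "rho") {
      type[j] <- 1L; lo[j] <- prior$rho_range[1]; hi[j] <- prior$rho_range[2]
    } else if (p %in% c("gmode_int", "gsd_int", "gmode_slope", "gsd_slope")) {
      type[j] <- 1L; lo[j] <- prior$hyper_range[1]; hi[j] <- prior$hyper_range[2]
    } else if (p %in% c("var_int", "var_slope")) {
      type[j] <- 2L
    }
  }
  list(type = type, lo = lo, hi = hi)
}

derived_draws <- function(free_mat, prior, t_b, t_i) {
  th0 <- full_theta(NULL, prior)
  get <- function(p) {
    if (p %in% colnames(free_mat)) free_mat[, p] else
      rep(if (p %in% names(prior$fixed)) th0[[p]] else 0, nrow(free_mat))
  }
  b11 <- get("intercept_p1"); b12 <- get("intercept_p2")
  b21 <- get("slope_p1"); b22 <- get("slope_p2")
  sig <- get("sigma_eps")
  rho <- get("rho")
  m <- t_b + t_i / 2
  cbind(ES1 = (b12 - b11) / sig,
        ES2 = (b12 + m * b22) - (b11 + m * b21),
        sigma_e = sig / sqrt(1 - rho^2))
}

#' Fit a Bayesian two-phase interrupted time-series model
#'
#' Draws posterior samples for one of the four model structures ([sced_model()])
#' on a two-phase series with an adaptive Metropolis-within-Gibbs sampler.
#' Chains are initialized independently from the prior; after sampling, the
#' multivariate potential scale reduction factor and per-parameter
#' Heidelberger-Welch stationarity tests are computed, and chains are extended
#' (up to `max_rounds`) until both indicate convergence. Intercept and slope
#' effect sizes and the marginal residual SD are computed for every retained
#' draw.
#'
#' @param data An `sced_series` or a data frame with columns `phase`, `time`,
#'   `value`.
#' @param model Model name (`"IO"`, `"NS"`, `"SI"`, `"SA"`) or spec.
#' @param prior An [sced_prior()].
#' @param control An [sced_control()].
#' @param seed Integer seed; per-chain seeds are derived deterministically.
#' @param truth Optional `sced_params` (or named vector) of true generative
#'   values; defaults to the simulating parameters attached to `data` when
#'   present. Used by `summary()` for truth-containment flags.
#' @return An object of class `bsced` with per-chain draws (burn-in excluded),
#'   derived effect-size draws, convergence diagnostics (`mpsrf`, `hw`,
#'   `converged`, `rounds`), and the fitting configuration.
#' @export
#' @examples
#' tp <- true_params(list(phase_length = 5, sigma_eps = 1, es1 = 2,
#'                        es2 = 0.5, rho = 0))
#' s <- sced_simulate(tp, seed = 7)
#' fit <- bsced(s, "SI", control = sced_control(chains = 2, burn_in = 200,
#'                                              draws = 300, max_rounds = 1))
#' coef(fit)[c("intercept_p1", "intercept_p2")]
bsced <- function(data, model = "SA", prior = sced_prior(),
                  control = sced_control(), seed = 1L, truth = NULL) {
  series <- as_sced_series(data)
  model <- sced_model(model)
  fr <- free_params(model, prior)
  if (length(fr) == 0) stop("no free parameters to sample")
  tr <- par_transforms(fr, prior)
  fr_idx <- match(fr, sced_par_names) - 1L
  cfg <- prior_cfg_vec(prior)
  tb <- series_tb(series)
  ti <- series_ti(series)
  carry <- control$boundary == "carry"
  if (is.null(truth)) truth <- attr(series, "params")

  chains <- vector("list", control$chains)
  state <- vector("list", control$chains)
  for (c in seq_len(control$chains)) {
    set.seed(sced_seed(seed, c, 0L))
    th0 <- NULL
    for (try in 1:100) {
      cand <- sced_prior_draw(model, prior)
      lp <- cpp_loglik(series$value, tb, unname(cand), carry) +
        log_prior(model, cand, prior)
      if (is.finite(lp)) {
        th0 <- cand
        break
      }
    }
    if (is.null(th0)) stop("posterior unevaluable")
    res <- cpp_mwg(series$value, tb, carry, unname(th0), fr_idx, tr$type,
                   tr$lo, tr$hi, cfg, control$burn_in, control$draws,
                   control$thin, rep(log(0.5), length(fr)), TRUE)
    colnames(res$draws) <- fr
    chains[[c]] <- res$draws
    state[[c]] <- list(theta = res$theta, lstep = res$lstep,
                       rng = .Random.seed)
  }

  diag_round <- function(chains) {
    mp <- if (control$chains >= 2) {
      tryCatch(mpsrf(chains), error = function(e) NA_real_)
    } else NA_real_
    hw <- if (nrow(chains[[1]]) < 100) {
      # stationarity test undefined on very short chains
      stats::setNames(rep(NA, length(fr)), fr)
    } else {
      vapply(fr, function(p) {
        all(vapply(chains, function(ch) {
          heidelberger_welch(ch[, p], alpha = control$hw_alpha,
                             eps = control$hw_eps)$stationarity
        }, TRUE))
      }, TRUE)
    }
    mp_ok <- if (control$chains >= 2) is.finite(mp) && mp < control$mpsrf_threshold else TRUE
    list(mpsrf = mp, hw = hw, converged = mp_ok && all(hw, na.rm = TRUE))
  }

  dg <- diag_round(chains)
  rounds <- 1L
  while (!dg$converged && rounds < control$max_rounds) {
    for (c in seq_len(control$chains)) {
      assign(".Random.seed", state[[c]]$rng, envir = globalenv())
      res <- cpp_mwg(series$value, tb, carry, state[[c]]$theta, fr_idx,
                     tr$type, tr$lo, tr$hi, cfg, 0L, control$draws,
                     control$thin, state[[c]]$lstep, FALSE)
      colnames(res$draws) <- fr
      chains[[c]] <- rbind(chains[[c]], res$draws)
      state[[c]] <- list(theta = res$theta, lstep = res$lstep,
                         rng = .Random.seed)
    }
    rounds <- rounds + 1L
    dg <- diag_round(chains)
  }

  derived <- lapply(chains, derived_draws, prior = prior, t_b = tb, t_i = ti)
  structure(
    list(model = model, prior = prior, control = control, seed = seed,
         series = series, truth = truth, free = fr, chains = chains,
         derived = derived, mpsrf = dg$mpsrf, hw = dg$hw,
         converged = dg$converged, rounds = rounds),
    class = "bsced"
  )
}
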