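#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman multivariate R-hat: combines the pooled within-chain
#' covariance `W` and the between-chain covariance of means `B/n` through the
#' largest eigenvalue of `W^{-1} B/n`,
#' `MPSRF = (n - 1)/n + (m + 1)/m * lambda_max`. Values near 1 indicate that
#' the chains have mixed.
#'
#' @param chains A list of at least two equal-dimension matrices (iterations x
#'   parameters), a 3-d array (iterations x parameters x chains), or a
#'   `bsced` fit.
#' @return The MPSRF (a scalar `>= (n-1)/n`).
#' @export
mpsrf <- function(chains) {
  if (inherits(chains, "bsced")) chains <- chains$chains
  if (is.array(chains) && length(dim(chains)) == 3) {
    chains <- lapply(seq_len(dim(chains)[3]),
                     function(k) matrix(chains[, , k], ncol = dim(chains)[2]))
  }
  chains <- lapply(chains, as.matrix)
  m <- length(chains)
  if (m < 2) stop("at least two chains are required")
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 1L) != n)) stop("chains must have equal length")
  w <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mu <- do.call(rbind, lapply(chains, colMeans))
  bn <- stats::cov(mu)
  sol <- tryCatch(solve(w, bn), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) stop("degenerate chains")
  lam <- max(Re(eigen(sol, only.values = TRUE)$values))
  (n - 1) / n + (m + 1) / m * lam
}

# Cramer-von Mises goodness-of-fit CDF (series expansion with Bessel K terms)
pcvm <- function(q) {
  if (!is.finite(q) || q <= 0) return(0)
  y <- 0
  for (k in 0:3) {
    u <- (4 * k + 1)^2 / (16 * q)
    if (u > 700) next
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    y <- y + z * exp(-u) * besselK(u, 0.25)
  }
  min(max(y, 0), 1)
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE), error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger-Welch convergence diagnostic for a single chain
#'
#' Stationarity is tested with a Cramer-von Mises statistic on the Brownian
#' bridge of the cumulative sums, standardized by the spectral density of the
#' chain at frequency zero; if the full chain fails, the first 10%, 20%, ...,
#' up to 40% of the draws are discarded and the test repeated. The half-width
#' test then asks whether the 95% confidence half-width of the retained
#' segment's mean is below `eps` times the absolute mean.
#'
#' @param chain Numeric vector of draws (length >= 100).
#' @param alpha Significance level of the stationarity test.
#' @param eps Relative half-width tolerance.
#' @return A list with `stationarity` (pass flag), `start` (1-based index of
#'   the retained segment), `halfwidth_pass`, `mean`, and `halfwidth`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  chain <- as.numeric(chain)
  n_full <- length(chain)
  if (n_full < 100) stop("chain length must be >= 100")
  if (stats::var(chain) == 0) {
    return(list(stationarity = TRUE, start = 1L, halfwidth_pass = TRUE,
                mean = chain[1], halfwidth = 0))
  }
  s0 <- spectrum0_ar(chain[(n_full %/% 2 + 1):n_full])
  pass <- FALSE
  start <- 1L
  for (frac in seq(0, 0.4, by = 0.1)) {
    start <- floor(frac * n_full) + 1L
    y <- chain[start:n_full]
    n <- length(y)
    if (s0 <= 0) break
    b <- cumsum(y) - mean(y) * seq_len(n)
    stat <- sum((b / sqrt(n * s0))^2) / n
    if (pcvm(stat) < 1 - alpha) {
      pass <- TRUE
      break
    }
  }
  y <- chain[start:n_full]
  mu <- mean(y)
  hw <- 1.96 * sqrt(spectrum0_ar(y) / length(y))
  list(
    stationarity = pass, start = start,
    halfwidth_pass = pass && is.finite(hw) && (hw <= eps * abs(mu) ||
                                                 (mu == 0 && hw == 0)),
    mean = mu, halfwidth = hw
  )
}
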