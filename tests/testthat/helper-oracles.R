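# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: covariances are built explicitly from the error
# recursion and densities evaluated by direct linear algebra.

# multivariate normal log-density via Cholesky
mvn_loglik <- function(y, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# covariance of an AR(1) error process e_t = rho e_{t-1} + eps started with
# Var(e_1) = init_sd^2
ar1_cov <- function(n, rho, sigma, init_sd = sigma) {
  v <- numeric(n)
  v[1] <- init_sd^2
  for (t in seq_len(n)[-1]) v[t] <- rho^2 * v[t - 1] + sigma^2
  m <- matrix(0, n, n)
  for (s in 1:n) for (t in s:n) m[s, t] <- m[t, s] <- rho^(t - s) * v[s]
  m
}

# joint-Gaussian oracle for the two-phase likelihood (phase-reset recursion:
# phases are independent blocks)
oracle_loglik_reset <- function(y, tb, b11, b21, b12, b22, rho, sigma) {
  n <- length(y)
  mu <- c(b11 + b21 * seq_len(tb), b12 + b22 * seq_len(n - tb))
  mvn_loglik(y[1:tb], mu[1:tb], ar1_cov(tb, rho, sigma)) +
    mvn_loglik(y[(tb + 1):n], mu[(tb + 1):n], ar1_cov(n - tb, rho, sigma))
}

# carry-over mode: one AR(1) process across the boundary
oracle_loglik_carry <- function(y, tb, b11, b21, b12, b22, rho, sigma) {
  n <- length(y)
  mu <- c(b11 + b21 * seq_len(tb), b12 + b22 * seq_len(n - tb))
  mvn_loglik(y, mu, ar1_cov(n, rho, sigma))
}

# plain-R re-implementation of the generator recursion (the oracle the
# simulator's moments are compared against)
oracle_simulate <- function(b11, b21, b12, b22, rho, sigma, l, seed) {
  set.seed(seed)
  n <- 2L * l
  mu <- c(b11 + b21 * seq_len(l), b12 + b22 * seq_len(l))
  e <- numeric(n)
  for (t in seq_len(n)) {
    e[t] <- if (t == 1L || t == l + 1L) rnorm(1, 0, sigma)
    else rho * e[t - 1] + rnorm(1, 0, sigma)
  }
  mu + e
}

# construct generative parameters directly (bypassing true_params)
make_params <- function(b11 = 0, b21 = 0, b12 = 0, b22 = 0, rho = 0,
                        sigma = 1, l = 10,
                        init = "eq1", boundary = "reset") {
  m <- l + l / 2
  structure(
    list(intercept_p1 = b11, slope_p1 = b21, intercept_p2 = b12,
         slope_p2 = b22, rho = rho, sigma_eps = sigma, t_b = l, t_i = l,
         es1_true = (b12 - b11) / sigma,
         es2_true = (b12 + m * b22) - (b11 + m * b21),
         gen = sced_gen_config(init = init, boundary = boundary)),
    class = "sced_params"
  )
}

# within-phase lag-1 sample autocorrelation of residuals around the true mean
lag1_autocorr <- function(values, mu, tb) {
  e <- values - mu
  blocks <- list(e[seq_len(tb)], e[-seq_len(tb)])
  num <- sum(vapply(blocks, function(b) sum(b[-1] * b[-length(b)]), 1))
  den <- sum(e^2)
  num / den
}

# effective sample size (coda), used only to set Monte-Carlo-error tolerances
mc_se <- function(x) {
  ess <- as.numeric(coda::effectiveSize(x))
  sd(x) / sqrt(max(ess, 1))
}
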