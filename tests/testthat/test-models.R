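random_series <- function(n1, n2, seed) {
  set.seed(seed)
  as_sced_series(data.frame(
    phase = rep(c(1L, 2L), c(n1, n2)),
    time = seq_len(n1 + n2),
    value = rnorm(n1 + n2, 10, 3)
  ))
}

test_that("model structures follow the slopes/autocorrelation grid", {
  grid <- list(IO = c(FALSE, FALSE), NS = c(FALSE, TRUE),
               SI = c(TRUE, FALSE), SA = c(TRUE, TRUE))
  for (nm in names(grid)) {
    m <- sced_model(nm)
    expect_equal(m$has_slopes, grid[[nm]][1])
    expect_equal(m$has_autocorrelation, grid[[nm]][2])
  }
  expect_error(sced_model("XX"), "unknown model")
})

test_that("log-likelihood nesting equalities are exact", {
  s <- random_series(6, 6, 1)
  base <- c(intercept_p1 = 9.5, intercept_p2 = 11, sigma_eps = 2.5)
  slopes <- c(slope_p1 = 0.3, slope_p2 = -0.2)
  expect_lt(abs(log_likelihood("SA", c(base, slopes, rho = 0), s) -
                  log_likelihood("SI", c(base, slopes), s)), 1e-12)
  expect_lt(abs(log_likelihood("NS", c(base, rho = 0), s) -
                  log_likelihood("IO", base, s)), 1e-12)
  expect_lt(abs(log_likelihood("SA", c(base, slope_p1 = 0, slope_p2 = 0,
                                       rho = 0.4), s) -
                  log_likelihood("NS", c(base, rho = 0.4), s)), 1e-12)
  # models reject parameters they fix at zero
  expect_error(log_likelihood("IO", c(base, slope_p1 = 1), s), "slopes")
  expect_error(log_likelihood("SI", c(base, rho = 0.5), s), "rho")
})

test_that("iid toy case equals the direct normal-density sum", {
  y <- c(0.4, -1.1, 0.7, 0.2)
  s <- as_sced_series(data.frame(phase = c(1, 1, 2, 2), time = 1:4, value = y))
  ll <- log_likelihood("IO", c(intercept_p1 = 0, intercept_p2 = 0,
                               sigma_eps = 1), s)
  expect_equal(ll, -(4 / 2) * log(2 * pi) - sum(y^2) / 2, tolerance = 1e-12)
})

test_that("conditional AR(1) likelihood matches the joint-Gaussian oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    s <- random_series(n1, n2, seed + 100)
    th <- c(intercept_p1 = runif(1, 5, 15), slope_p1 = runif(1, -1, 1),
            intercept_p2 = runif(1, 5, 15), slope_p2 = runif(1, -1, 1),
            rho = runif(1, -0.9, 0.9), sigma_eps = runif(1, 0.5, 3))
    ll <- log_likelihood("SA", th, s)
    orc <- oracle_loglik_reset(s$value, n1, th[["intercept_p1"]],
                               th[["slope_p1"]], th[["intercept_p2"]],
                               th[["slope_p2"]], th[["rho"]],
                               th[["sigma_eps"]])
    expect_equal(ll, orc, tolerance = 1e-8)
    ll_c <- log_likelihood("SA", th, s, boundary = "carry")
    orc_c <- oracle_loglik_carry(s$value, n1, th[["intercept_p1"]],
                                 th[["slope_p1"]], th[["intercept_p2"]],
                                 th[["slope_p2"]], th[["rho"]],
                                 th[["sigma_eps"]])
    expect_equal(ll_c, orc_c, tolerance = 1e-8)
  }
})

test_that("log-prior support bounds and symmetry hold", {
  p <- c(intercept_p1 = 20, intercept_p2 = 22, sigma_eps = 1, mu_int_p1 = 20,
         mu_int_p2 = 20, var_int = 1, gmode_int = 0.5, gsd_int = 0.5)
  expect_identical(log_prior("NS", c(p, rho = 1.2)), -Inf)
  expect_identical(log_prior("NS", c(p, rho = -0.3)),
                   log_prior("NS", c(p, rho = 0.3)))
  p2 <- p
  p2["mu_int_p1"] <- 60
  expect_identical(log_prior("IO", p2), -Inf)
  p3 <- p
  p3["sigma_eps"] <- 0.05 # below the uniform support
  expect_identical(log_prior("IO", p3), -Inf)
  expect_true(is.finite(log_prior("IO", p)))
})

test_that("each scalar prior component integrates to 1", {
  # pin every other parameter so the log-prior reduces to the single
  # component's stated density
  all_par_vals <- list(
    intercept_p1 = 20, slope_p1 = 0.1, intercept_p2 = 22, slope_p2 = -0.1,
    rho = 0.2, sigma_eps = 1, mu_int_p1 = 20, mu_int_p2 = 20,
    mu_slope_p1 = 0, mu_slope_p2 = 0, var_int = 1, var_slope = 1,
    gmode_int = 0.5, gsd_int = 0.5, gmode_slope = 0.5, gsd_slope = 0.5
  )
  pin_except <- function(keep) {
    fixed <- all_par_vals
    fixed[[keep]] <- NULL
    sced_prior(fixed = fixed)
  }
  dens <- function(keep, x) {
    pr <- pin_except(keep)
    vapply(x, function(v) {
      p <- stats::setNames(v, keep)
      exp(log_prior("SA", p, pr))
    }, 1)
  }
  expect_equal(integrate(function(x) dens("mu_int_p1", x), 0, 50)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(x) dens("mu_slope_p1", x), -10, 10)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(x) dens("sigma_eps", x), 0.1, 5)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(x) dens("rho", x), -1, 1)$value, 1,
               tolerance = 1e-6)
  # variance given pinned gamma mode/sd: a proper gamma on (0, Inf)
  expect_equal(integrate(function(x) dens("var_int", x), 0, Inf)$value, 1,
               tolerance = 1e-6)
  # the gamma-mode hyperparameter only enters jointly with the variance it
  # governs (fixing the variance drops it), so test the block normalization:
  # integral over (gmode, var) of unif(gmode) * gamma(var | gmode, gsd) = 1
  fixed_gm <- all_par_vals
  fixed_gm[c("gmode_int", "var_int")] <- NULL
  pr_gm <- sced_prior(fixed = fixed_gm)
  inner <- function(g) {
    integrate(function(v) vapply(v, function(vv)
      exp(log_prior("SA", c(gmode_int = g, var_int = vv), pr_gm)), 1),
      0, Inf)$value
  }
  expect_equal(integrate(function(g) vapply(g, inner, 1), 0.01, 1)$value, 1,
               tolerance = 1e-5)
  # on the SD scale the transformed density must still normalize
  fixed <- all_par_vals
  fixed[["var_int"]] <- NULL
  prs <- sced_prior(hyper_scale = "sd", fixed = fixed)
  d <- function(x) vapply(x, function(v)
    exp(log_prior("SA", c(var_int = v), prs)), 1)
  expect_equal(integrate(d, 0, Inf)$value, 1, tolerance = 1e-6)
})

test_that("gamma mode/SD re-parameterization satisfies its defining identities", {
  g <- gamma_from_mode_sd(1, 1)
  expect_equal(unname(g["rate"]), (1 + sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(unname(g["shape"]), 1 + (1 + sqrt(5)) / 2, tolerance = 1e-12)
  g2 <- gamma_from_mode_sd(0.01, 0.01)
  expect_equal(unname(g2["rate"]), 100 * unname(g["rate"]), tolerance = 1e-10)
  expect_equal(unname(g2["shape"]), unname(g["shape"]), tolerance = 1e-10)
  set.seed(3)
  for (i in 1:100) {
    mode <- runif(1, 0.01, 5)
    sd <- runif(1, 0.01, 5)
    ab <- gamma_from_mode_sd(mode, sd)
    expect_equal(unname((ab["shape"] - 1) / ab["rate"]), mode,
                 tolerance = 1e-10)
    expect_equal(unname(ab["shape"] / ab["rate"]^2), sd^2, tolerance = 1e-10)
    expect_gt(ab[["shape"]], 1)
  }
  expect_error(gamma_from_mode_sd(0, 1), "positive")
  expect_error(gamma_from_mode_sd(1, -1), "positive")
})

test_that("prior draws land in support and respect fixed components", {
  set.seed(11)
  for (i in 1:50) {
    th <- sced_prior_draw("SA")
    expect_true(is.finite(log_prior("SA", th)))
    expect_true(abs(th[["rho"]]) < 1)
    expect_true(th[["sigma_eps"]] >= 0.1 && th[["sigma_eps"]] <= 5)
  }
  pr <- sced_prior(fixed = list(sigma_eps = 2))
  th <- sced_prior_draw("IO", pr)
  expect_identical(th[["sigma_eps"]], 2)
  expect_identical(th[["slope_p2"]], 0) # structural zero for IO
})
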