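tiny_config <- function(out_dir = NULL, resume = FALSE, seed = 5,
                        replications = 2) {
  sced_study_config(
    factor_levels = list(phase_length = 5, sigma_eps = 1, es1 = c(1, 2),
                         es2 = 0.5, rho = 0),
    replications = replications, models = c("IO", "SI"), seed = seed,
    control = sced_control(chains = 2, burn_in = 200, draws = 200,
                           max_rounds = 1),
    out_dir = out_dir, resume = resume
  )
}

test_that("the schedule is a bijection onto the condition x replication x model grid", {
  st <- run_study(tiny_config(replications = 3))
  keys <- unique(paste(st$fits$condition, st$fits$replication, st$fits$model))
  expect_equal(length(keys), 2 * 3 * 2) # no duplicates, no gaps
  expect_setequal(
    keys,
    as.vector(outer(as.vector(outer(1:2, 1:3, paste)), c("IO", "SI"), paste))
  )
  # every fit row carries its design factors
  expect_true(all(st$fits$phase_length == 5))
  expect_true(all(st$fits$es1 %in% c(1, 2)))
})

test_that("identical config and seed reproduce bit-identical fit tables", {
  s1 <- run_study(tiny_config())
  s2 <- run_study(tiny_config())
  expect_identical(s1$fits, s2$fits)
  s3 <- run_study(tiny_config(seed = 6))
  expect_false(identical(s1$fits, s3$fits))
})

test_that("interrupted studies resume without refitting completed cells", {
  d1 <- file.path(tempdir(), "study_full")
  unlink(d1, recursive = TRUE)
  full <- run_study(tiny_config(out_dir = d1))
  expect_true(file.exists(file.path(d1, "fits.csv")))
  expect_true(file.exists(file.path(d1, "diagnostics.csv")))
  # simulate an interruption: keep only the first condition's rows
  d2 <- file.path(tempdir(), "study_part")
  unlink(d2, recursive = TRUE)
  dir.create(d2)
  part <- utils::read.csv(file.path(d1, "fits.csv"))
  utils::write.csv(part[part$condition == 1, ], file.path(d2, "fits.csv"),
                   row.names = FALSE)
  resumed <- run_study(tiny_config(out_dir = d2, resume = TRUE))
  expect_equal(resumed$fits$estimate, full$fits$estimate, tolerance = 1e-10)
  # without the resume flag an existing table is an error, not silent reuse
  expect_error(run_study(tiny_config(out_dir = d2)), "resume")
})

test_that("full-scale schedule counts match the published design", {
  cfg <- sced_study_config() # defaults: full factorial, 100 replications
  expect_equal(nrow(sced_conditions(cfg$factor_levels)) * cfg$replications,
               76800)
})

test_that("eta-squared decomposes hand-computable designs exactly", {
  # pure main effect: the factor explains everything
  d <- expand.grid(a = 1:3, b = 1:2)
  d$y <- c(1, 2, 3)[d$a]
  e <- eta_squared(d, "y", c("a", "b"))
  expect_equal(e$eta_sq[e$term == "a"], 100)
  expect_equal(e$eta_sq[e$term == "b"], 0)
  # constant response: zero total SS convention
  d$y <- 5
  expect_true(all(eta_squared(d, "y", c("a", "b"))$eta_sq == 0))
  # 2x2 single-observation cells {0,0,0,1}: SS_A = SS_B = SS_AB = 0.25,
  # SS_total = 0.75, so each term takes a third of the total
  d2 <- expand.grid(a = 1:2, b = 1:2)
  d2$y <- c(0, 0, 0, 1)
  e2 <- eta_squared(d2, "y", c("a", "b"))
  expect_equal(e2$eta_sq[e2$term %in% c("a", "b", "a:b")],
               rep(100 / 3, 3), tolerance = 1e-10)
  expect_error(eta_squared(d2[-1, ], "y", c("a", "b")), "unbalanced")
})

test_that("eta-squared is invariant to affine rescaling of the response", {
  set.seed(31)
  d <- expand.grid(a = 1:3, b = 1:2, c = 1:2)
  d$y <- rnorm(nrow(d)) + d$a + 0.5 * d$b * d$c
  e1 <- eta_squared(d, "y", c("a", "b", "c"))
  d$y2 <- -3.7 * d$y + 11
  e2 <- eta_squared(d, "y2", c("a", "b", "c"))
  expect_equal(e1$eta_sq, e2$eta_sq, tolerance = 1e-9)
  # shares live in [0, 100] and the modeled terms never exceed the total
  expect_true(all(e1$eta_sq >= 0 & e1$eta_sq <= 100))
  expect_lte(sum(e1$eta_sq[e1$term != "Residuals"]), 100 + 1e-9)
})

test_that("study eta tables stack the requested diagnostics", {
  set.seed(17)
  d <- expand.grid(condition = 1:8, model = c("NS", "SA"),
                   parameter = "rho", stringsAsFactors = FALSE)
  design <- expand.grid(phase_length = c(5, 10), rho = c(0.5, 0.8),
                        es1 = c(1, 2))
  d <- cbind(d, design[d$condition, ])
  d$rmse <- rexp(nrow(d))
  d$coverage_pct <- runif(nrow(d), 80, 100)
  d$zero_coverage_pct <- runif(nrow(d), 0, 100)
  tabs <- study_eta_tables(d, parameters = "rho")
  expect_setequal(names(tabs), c("rho.rmse", "rho.coverage_pct",
                                 "rho.zero_coverage_pct"))
  expect_true("model" %in% tabs$rho.rmse$term)
  expect_true("phase_length:rho" %in% tabs$rho.rmse$term)
  expect_true(any(grepl("Residuals", tabs$rho.rmse$term)))
})

test_that("study configs round-trip through the structured text format", {
  path <- tempfile(fileext = ".yml")
  writeLines(c(
    "factor_levels:",
    "  phase_length: [5, 10]",
    "  sigma_eps: [1]",
    "  es1: [1, 2]",
    "  es2: [0.3]",
    "  rho: [0.5, 0.8]",
    "replications: 4",
    "models: [NS, SA]",
    "seed: 9",
    "control:",
    "  chains: 2",
    "  burn_in: 300",
    "  draws: 250",
    "gen:",
    "  es2_mapping: literal"
  ), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$factor_levels$phase_length, c(5, 10))
  expect_equal(cfg$replications, 4)
  expect_equal(cfg$models, c("NS", "SA"))
  expect_equal(cfg$control$draws, 250)
  expect_equal(cfg$gen$es2_mapping, "literal")
  expect_equal(nrow(sced_conditions(cfg$factor_levels)), 8)
})

test_that("reduced-scale smoke study reproduces the SA/NS 0-coverage ordering", {
  cfg <- sced_study_config(
    factor_levels = list(phase_length = c(5, 10), sigma_eps = 1,
                         es1 = c(1, 2), es2 = c(0.3, 1), rho = c(0.5, 0.8)),
    replications = 5, models = c("NS", "SA"), seed = 1,
    control = sced_control(chains = 2, burn_in = 500, draws = 500,
                           max_rounds = 1)
  )
  st <- run_study(cfg)
  r <- st$fits[st$fits$parameter == "rho", ]
  zc <- function(m, cond = NULL) {
    sub <- r[r$model == m & (if (is.null(cond)) TRUE else r$condition == cond), ]
    zero_coverage(sub[, c("lower", "upper")])
  }
  # autocorrelation is truly present everywhere, yet the full model's rho
  # intervals cover 0 more often than the no-slopes model's; at 5
  # replications per condition only pooled comparisons carry power
  expect_gt(zc("SA"), zc("NS"))
  for (rv in c(0.5, 0.8)) {
    sa <- r[r$model == "SA" & r$rho == rv, ]
    ns <- r[r$model == "NS" & r$rho == rv, ]
    expect_gte(zero_coverage(sa[, c("lower", "upper")]),
               zero_coverage(ns[, c("lower", "upper")]))
  }
})
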