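#' Configuration of a Monte-Carlo recovery study
#'
#' @param factor_levels Design factor levels ([sced_factor_defaults()] gives
#'   the full crossed design of 768 conditions).
#' @param replications Simulated datasets per condition (the full-scale design
#'   uses 100).
#' @param models Character vector of models to fit to every dataset.
#' @param seed Root seed; per-dataset and per-fit seeds are derived
#'   deterministically from it, so results are independent of execution order.
#' @param control Sampler settings ([sced_control()]).
#' @param gen Generation settings ([sced_gen_config()]).
#' @param level Credible-interval level for the per-fit summaries.
#' @param out_dir Optional directory; when given, per-fit rows are appended to
#'   `<out_dir>/fits.csv` as they complete and summary tables are written at
#'   the end.
#' @param resume Reuse rows already present in `<out_dir>/fits.csv` instead of
#'   refitting them; without this flag an existing fits table is an error.
#' @return A list of class `sced_study_config`.
#' @export
sced_study_config <- function(factor_levels = sced_factor_defaults(),
                              replications = 100L,
                              models = c("IO", "NS", "SI", "SA"),
                              seed = 1L, control = sced_control(),
                              gen = sced_gen_config(), level = 0.95,
                              out_dir = NULL, resume = FALSE) {
  stopifnot(replications >= 1, length(models) >= 1)
  models <- vapply(models, function(m) sced_model(m)$name, "")
  structure(
    list(factor_levels = factor_levels,
         replications = as.integer(replications), models = unname(models),
         seed = as.integer(seed), control = control, gen = gen,
         level = level, out_dir = out_dir, resume = resume),
    class = "sced_study_config"
  )
}

#' Read a study configuration from a structured text (YAML) file
#'
#' Recognized keys: `factor_levels` (map of factor name to level list),
#' `replications`, `models`, `seed`, `level`, `control` (map of
#' [sced_control()] arguments), `gen` (map of [sced_gen_config()] arguments),
#' `out_dir`, `resume`.
#'
#' @param path Path to the YAML file.
#' @return An [sced_study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  fl <- sced_factor_defaults()
  for (f in names(y$factor_levels)) fl[[f]] <- as.numeric(y$factor_levels[[f]])
  args <- list(factor_levels = fl)
  for (k in c("replications", "models", "seed", "level", "out_dir", "resume")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$control)) args$control <- do.call(sced_control, y$control)
  if (!is.null(y$gen)) args$gen <- do.call(sced_gen_config, y$gen)
  do.call(sced_study_config, args)
}

# parameters summarized for one fit: free structural params + effect sizes
fit_row_params <- function(model) {
  model <- sced_model(model)
  p <- c("intercept_p1", "intercept_p2")
  if (model$has_slopes) p <- c(p, "slope_p1", "slope_p2")
  if (model$has_autocorrelation) p <- c(p, "rho")
  c(p, "sigma_eps", "ES1", "ES2",
    if (model$has_autocorrelation) "sigma_e")
}

fit_rows <- function(fit, cond, rep_idx, level) {
  m <- as.matrix(fit)
  truth <- fit_truth_values(fit)
  params <- fit_row_params(fit$model)
  rows <- lapply(params, function(p) {
    s <- summarize_draws(m[, p], level = level, truth = truth[[p]],
                         min_draws = 1)
    data.frame(
      condition = cond$condition, phase_length = cond$phase_length,
      sigma_eps = cond$sigma_eps, es1 = cond$es1, es2 = cond$es2,
      rho = cond$rho, replication = rep_idx, model = fit$model$name,
      parameter = p, estimate = s$mean, post_sd = stats::sd(m[, p]),
      lower = s$interval$lower, upper = s$interval$upper,
      contains_zero = s$interval$contains_zero,
      contains_truth = s$interval$contains_truth,
      truth = truth[[p]], converged = fit$converged, mpsrf = fit$mpsrf,
      rounds = fit$rounds
    )
  })
  do.call(rbind, rows)
}

#' Run a factorial parameter-recovery study
#'
#' For every design condition and replication, simulates a two-phase AR(1)
#' series with a deterministically derived seed and fits every requested model
#' to it; per-fit posterior summaries are collected into a long table. The
#' schedule is a bijection onto the condition x replication x model grid, and
#' identical configurations (including the root seed) reproduce bit-identical
#' tables regardless of the order fits are executed in. With `out_dir` set,
#' completed fits are streamed to disk and a `resume` run skips them.
#'
#' @param config An [sced_study_config()].
#' @param progress Print a line per condition.
#' @return A list of class `sced_study`: `conditions` (the design),
#'   `fits` (per-fit rows), `config`.
#' @export
run_study <- function(config = sced_study_config(), progress = FALSE) {
  conditions <- sced_conditions(config$factor_levels)
  done <- NULL
  out_file <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out_file <- file.path(config$out_dir, "fits.csv")
    if (file.exists(out_file)) {
      if (!config$resume) {
        stop("output directory already contains fits.csv; set resume = TRUE")
      }
      done <- utils::read.csv(out_file, stringsAsFactors = FALSE)
    }
  }
  done_keys <- if (!is.null(done) && nrow(done)) {
    unique(paste(done$condition, done$replication, done$model))
  } else character()

  all_rows <- if (!is.null(done)) list(done) else list()
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    if (progress) {
      message(sprintf("condition %d/%d", i, nrow(conditions)))
    }
    tp <- true_params(cond, config$gen)
    for (j in seq_len(config$replications)) {
      data_seed <- sced_seed(config$seed, cond$condition, j)
      series <- NULL
      for (mod in config$models) {
        if (paste(cond$condition, j, mod) %in% done_keys) next
        if (is.null(series)) series <- sced_simulate(tp, data_seed)
        # fit seed keyed to the model's identity, not its position, so the
        # result is invariant to execution order
        model_id <- match(mod, c("IO", "NS", "SI", "SA"))
        fit <- bsced(series, mod, control = config$control,
                     seed = sced_seed(data_seed, model_id, 2L), truth = tp)
        rows <- fit_rows(fit, cond, j, config$level)
        all_rows[[length(all_rows) + 1]] <- rows
        if (!is.null(out_file)) {
          new_file <- !file.exists(out_file)
          suppressWarnings(
            utils::write.table(rows, out_file, sep = ",", row.names = FALSE,
                               col.names = new_file, append = !new_file)
          )
        }
      }
    }
  }
  fits <- do.call(rbind, all_rows)
  ord <- order(fits$condition, fits$replication, match(fits$model, config$models),
               match(fits$parameter, sced_par_names, nomatch = 99L))
  fits <- fits[ord, ]
  rownames(fits) <- NULL
  out <- structure(list(conditions = conditions, fits = fits,
                        config = config),
                   class = "sced_study")
  if (!is.null(config$out_dir)) {
    d <- sced_diagnostics(fits)
    utils::write.csv(d, file.path(config$out_dir, "diagnostics.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.sced_study <- function(x, ...) {
  cat(sprintf("SCED recovery study: %d conditions x %d replications x %s\n",
              nrow(x$conditions), x$config$replications,
              paste(x$config$models, collapse = "/")))
  cat(sprintf("  %d per-fit summary rows, %.1f%% of fits converged\n",
              nrow(x$fits),
              100 * mean(x$fits$converged[!duplicated(
                paste(x$fits$condition, x$fits$replication, x$fits$model))])))
  invisible(x)
}

#' Indeterminacy cross-tab of a study
#'
#' Pairs each dataset's autocorrelation interval with its phase-2 slope
#' interval (one pair per fitted dataset of `model`) and classifies them by
#' zero-containment; by default restricted to conditions where neither true
#' value is 0, the subset where containment of 0 is an error.
#'
#' @param study An `sced_study` (or its `fits` table).
#' @param model Model whose intervals are examined (default `"SA"`, the only
#'   model estimating both sources of trend).
#' @param nonzero_truth_only Keep only datasets with true `rho != 0` and true
#'   phase-2 slope `!= 0`.
#' @return An [indeterminacy_crosstab()] result.
#' @export
study_crosstab <- function(study, model = "SA", nonzero_truth_only = TRUE) {
  fits <- if (inherits(study, "sced_study")) study$fits else study
  f <- fits[fits$model == sced_model(model)$name, ]
  r <- f[f$parameter == "rho", ]
  b <- f[f$parameter == "slope_p2", ]
  if (nrow(r) == 0 || nrow(b) == 0) {
    stop("model ", model, " does not provide both rho and slope_p2 intervals")
  }
  key <- function(d) paste(d$condition, d$replication)
  b <- b[match(key(r), key(b)), ]
  keep <- rep(TRUE, nrow(r))
  if (nonzero_truth_only) keep <- r$rho != 0 & b$truth != 0
  indeterminacy_crosstab(r[keep, c("lower", "upper")],
                         b[keep, c("lower", "upper")])
}

#' Eta-squared decomposition of a balanced factorial response
#'
#' Fits a fixed-effects ANOVA with all main effects and two-way interactions
#' of the given factors and reports each term's share of the total
#' (mean-corrected) sum of squares in percent. The design must be balanced
#' (equal cell counts); a constant response yields all-zero shares.
#'
#' @param data Data frame holding the response and factor columns (e.g. an
#'   [sced_diagnostics()] table, one row per design cell).
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (converted to R
#'   factors; `model` may be included to compare models).
#' @return A data frame of class `sced_eta` with columns `term` and `eta_sq`
#'   (percent), one row per main effect and two-way interaction plus the
#'   residual remainder.
#' @export
#' @examples
#' d <- expand.grid(a = 1:2, b = 1:2)
#' d$y <- c(0, 0, 0, 1)
#' eta_squared(d, "y", c("a", "b"))
eta_squared <- function(data, response, factors) {
  if (!response %in% names(data)) stop("unknown response: ", response)
  if (!all(factors %in% names(data))) stop("unknown factor column")
  data <- data[stats::complete.cases(data[c(response, factors)]), ]
  for (f in factors) data[[f]] <- factor(data[[f]])
  counts <- table(data[factors])
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unbalanced factorial")
  }
  y <- data[[response]]
  terms <- if (length(factors) > 1) {
    paste0("(", paste(factors, collapse = " + "), ")^2")
  } else factors
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    form0 <- stats::reformulate(factors, response)
    labels <- attr(stats::terms(stats::reformulate(terms)), "term.labels")
    out <- data.frame(term = labels, eta_sq = 0)
    class(out) <- c("sced_eta", "data.frame")
    return(out)
  }
  fit <- stats::aov(stats::reformulate(terms, response), data = data)
  a <- summary(fit)[[1]]
  lab <- trimws(rownames(a))
  ss <- a[["Sum Sq"]]
  out <- data.frame(term = lab, eta_sq = 100 * ss / ss_total)
  rownames(out) <- NULL
  class(out) <- c("sced_eta", "data.frame")
  out
}

#' @export
print.sced_eta <- function(x, min_eta = 0, digits = 2, ...) {
  cat("Eta-squared shares (% of total SS)\n")
  keep <- x$eta_sq >= min_eta | x$term == "Residuals"
  print.data.frame(data.frame(term = x$term[keep],
                              eta_sq = round(x$eta_sq[keep], digits)),
                   row.names = FALSE)
  invisible(x)
}

#' Eta-squared tables for every recovery diagnostic of a study
#'
#' Runs [eta_squared()] for each requested diagnostic of each parameter over
#' the design factors, optionally stacking models as an extra factor.
#'
#' @param diagnostics An [sced_diagnostics()] table.
#' @param responses Diagnostic columns to decompose.
#' @param parameters Parameters to include (default: all present).
#' @param with_model Include `model` as a crossed factor (requires every model
#'   to appear in every condition).
#' @return Named list of `sced_eta` tables, one per (parameter, response).
#' @export
study_eta_tables <- function(diagnostics,
                             responses = c("rmse", "coverage_pct",
                                           "zero_coverage_pct"),
                             parameters = unique(diagnostics$parameter),
                             with_model = TRUE) {
  factors <- intersect(.sced_factors, names(diagnostics))
  factors <- factors[vapply(factors,
                            function(f) length(unique(diagnostics[[f]])) > 1,
                            TRUE)]
  if (with_model && length(unique(diagnostics$model)) > 1) {
    factors <- c(factors, "model")
  }
  if (length(factors) == 0) {
    stop("no varying design factors to decompose")
  }
  out <- list()
  for (p in parameters) {
    d <- diagnostics[diagnostics$parameter == p, ]
    if (nrow(d) == 0) next
    for (r in responses) {
      if (all(is.na(d[[r]]))) next
      out[[paste(p, r, sep = ".")]] <- eta_squared(d, r, factors)
    }
  }
  out
}
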