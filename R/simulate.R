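#' Simulate a two-phase interrupted time series with AR(1) errors
#'
#' Generates a series whose mean is `intercept_p1 + slope_p1 * t` for
#' `t <= t_b` and `intercept_p2 + slope_p2 * (t - t_b)` afterwards, with
#' residuals following a first-order autoregression with coefficient `rho` and
#' innovation SD `sigma_eps`. By default the error recursion is restarted at
#' the phase boundary and each phase's first residual is drawn with SD
#' `sigma_eps`; see [sced_gen_config()] for the stationary-initialization and
#' carry-over alternatives.
#'
#' @param params An [true_params()] object (or any list with the same fields).
#' @param seed Integer seed; the same `(params, seed)` pair always yields a
#'   bit-identical series.
#' @return A data frame of class `sced_series` with columns `time`, `phase`
#'   (1 = baseline, 2 = treatment), `value`, and attributes `params` and
#'   `seed`.
#' @export
#' @examples
#' tp <- true_params(list(phase_length = 8, sigma_eps = 1, es1 = 2,
#'                        es2 = 0.5, rho = 0.2))
#' s <- sced_simulate(tp, seed = 42)
#' head(s)
sced_simulate <- function(params, seed) {
  rho <- params$rho
  sig <- params$sigma_eps
  if (abs(rho) >= 1) stop("nonstationary autocorrelation")
  if (sig <= 0) stop("sigma_eps must be > 0")
  gen <- params$gen
  if (is.null(gen)) gen <- sced_gen_config()
  t_b <- params$t_b
  t_i <- params$t_i
  n <- t_b + t_i
  mu <- c(
    params$intercept_p1 + params$slope_p1 * seq_len(t_b),
    params$intercept_p2 + params$slope_p2 * seq_len(t_i)
  )
  sd0 <- if (gen$init == "stationary") sig / sqrt(1 - rho^2) else sig
  set.seed(as.integer(seed))
  e <- numeric(n)
  for (t in seq_len(n)) {
    first <- if (gen$boundary == "carry") t == 1L else (t == 1L || t == t_b + 1L)
    e[t] <- if (first) stats::rnorm(1, 0, sd0) else rho * e[t - 1] + stats::rnorm(1, 0, sig)
  }
  out <- data.frame(
    time = seq_len(n),
    phase = rep(c(1L, 2L), c(t_b, t_i)),
    value = mu + e
  )
  structure(out, params = params, seed = as.integer(seed),
            class = c("sced_series", "data.frame"))
}

#' Coerce a long-format table to an `sced_series`
#'
#' Accepts any data frame with columns `phase` (coded 1/2), `time` (1-based,
#' consecutive) and `value`; rows are sorted by time.
#'
#' @param data A data frame.
#' @return An `sced_series` object.
#' @export
as_sced_series <- function(data) {
  if (inherits(data, "sced_series")) return(data)
  need <- c("phase", "time", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns phase, time, value")
  }
  data <- data[order(data$time), need[c(2, 1, 3)]]
  if (!all(data$time == seq_len(nrow(data)))) {
    stop("time must be the consecutive sequence 1..n")
  }
  if (!all(data$phase %in% c(1L, 2L))) stop("phase must be coded 1/2")
  if (is.unsorted(data$phase)) stop("phase 2 must follow phase 1")
  if (!any(data$phase == 1L) || !any(data$phase == 2L)) {
    stop("both phases must be present")
  }
  if (!all(is.finite(data$value))) stop("values must be finite")
  rownames(data) <- NULL
  structure(data, class = c("sced_series", "data.frame"))
}

series_tb <- function(series) sum(series$phase == 1L)
series_ti <- function(series) sum(series$phase == 2L)

#' Write / read series in the long delimited interchange format
#'
#' The on-disk format is a comma-separated table with header
#' `series_id,phase,time,value`; `phase` is coded 1/2 and `time` is 1-based.
#'
#' @param series A single `sced_series` or a (possibly named) list of them.
#' @param path File path.
#' @return `write_sced_series` returns `path` invisibly; `read_sced_series`
#'   returns a named list of `sced_series` objects.
#' @export
write_sced_series <- function(series, path) {
  if (inherits(series, "sced_series")) series <- list(series)
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  rows <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(series_id = ids[i], phase = s$phase, time = s$time,
               value = s$value)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sced_series
#' @export
read_sced_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "phase", "time", "value")
  if (!all(need %in% names(d))) {
    stop("file must have columns series_id, phase, time, value")
  }
  out <- lapply(split(d, d$series_id), as_sced_series)
  out[unique(as.character(d$series_id))]
}

#' @export
print.sced_series <- function(x, ...) {
  tb <- series_tb(x)
  cat(sprintf("Two-phase SCED series: %d + %d observations\n",
              tb, series_ti(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.sced_series <- function(x, ...) {
  tb <- series_tb(x)
  plot(x$time, x$value, type = "b", pch = 19,
       col = ifelse(x$phase == 1L, "grey30", "firebrick"),
       xlab = "time", ylab = "value", ...)
  graphics::abline(v = tb + 0.5, lty = 2)
  invisible(x)
}
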