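# Within-session engagement: normalised behavioural-response timecourses,
# single-term exponential fits, and the HIT/MISS intersection time.

#' Binned behavioural-response timecourse
#'
#' Bins trials by actual onset time and computes, per bin, the proportion of
#' each response type relative to the presentations of the relevant tone
#' role: HIT and MISS are normalised by the bin's deviant count, FA and CR
#' by its standard count. A bin with no relevant tones contributes no point
#' for that response type. By construction HIT + MISS = 1 and FA + CR = 1
#' within every bin where they are defined.
#'
#' @param trials Trial data frame from a `session_log` (needs
#'   `actual_onset_s`, `role`, `outcome`), or a list of them (sessions are
#'   pooled on the session clock).
#' @param bin_width_s Bin width in seconds (default 120).
#' @param cumulative If `TRUE`, normalise by cumulative presentations up to
#'   each bin instead of per-bin counts.
#' @return A `timecourse` data frame: `bin_center_s`, `response_type`,
#'   `n_events`, `n_presentations`, `value`.
#' @export
response_timecourse <- function(trials, bin_width_s = 120, cumulative = FALSE) {
  if (is.data.frame(trials)) trials <- list(trials)
  tr <- do.call(rbind, lapply(trials, function(d) {
    d[, c("actual_onset_s", "role", "outcome")]
  }))
  if (is.null(tr) || nrow(tr) == 0L) {
    stop_oddballr("no trials in input", "empty_input")
  }
  stopifnot(bin_width_s > 0)
  bin <- floor(tr$actual_onset_s / bin_width_s)
  bins <- sort(unique(bin))
  rows <- list()
  for (b in bins) {
    inb <- bin == b
    center <- (b + 0.5) * bin_width_s
    n_dev <- sum(inb & tr$role == "deviant")
    n_std <- sum(inb & tr$role == "standard")
    denom_dev <- if (cumulative) sum(bin <= b & tr$role == "deviant") else n_dev
    denom_std <- if (cumulative) sum(bin <= b & tr$role == "standard") else n_std
    if (denom_dev > 0) {
      n_hit <- sum(inb & tr$outcome == "HIT")
      n_miss <- sum(inb & tr$outcome == "MISS")
      rows[[length(rows) + 1L]] <- data.frame(
        bin_center_s = center,
        response_type = c("HIT", "MISS"),
        n_events = c(n_hit, n_miss),
        n_presentations = denom_dev,
        value = c(n_hit, n_miss) / denom_dev)
    }
    if (denom_std > 0) {
      n_fa <- sum(inb & tr$outcome == "FA")
      n_cr <- sum(inb & tr$outcome == "CR")
      rows[[length(rows) + 1L]] <- data.frame(
        bin_center_s = center,
        response_type = c("FA", "CR"),
        n_events = c(n_fa, n_cr),
        n_presentations = denom_std,
        value = c(n_fa, n_cr) / denom_std)
    }
  }
  structure(do.call(rbind, rows),
            bin_width_s = bin_width_s,
            class = c("timecourse", "data.frame"))
}

#' Single-term exponential fit
#'
#' Least-squares fit of `y = a * exp(b * t)` with `a > 0` and `b` of either
#' sign (a declining response has `b < 0`). The fit is seeded by a
#' log-linear regression on the strictly positive values and refined by
#' nonlinear least squares over all points (zeros included); if refinement
#' fails to improve the seed, the seed is returned.
#'
#' @param bin_centers_s Time points (bin centers), seconds.
#' @param values Response proportions at those times.
#' @return An `exp_fit` list: `a`, `b`, `r_squared`.
#' @examples
#' t <- seq(60, 1020, by = 120)
#' fit_exponential(t, 0.8 * exp(-0.001 * t))
#' @export
fit_exponential <- function(bin_centers_s, values) {
  t <- as.numeric(bin_centers_s)
  y <- as.numeric(values)
  stopifnot(length(t) == length(y))
  if (length(t) < 3L) {
    stop_oddballr("exponential fit needs at least 3 bins", "fit_error")
  }
  if (all(y <= 0)) {
    stop_oddballr("all values are zero; no exponential amplitude to fit",
                  "fit_error")
  }
  pos <- y > 0
  if (sum(pos) >= 2L && length(unique(t[pos])) >= 2L) {
    seedfit <- stats::lm(log(y[pos]) ~ t[pos])
    a0 <- exp(unname(stats::coef(seedfit)[1]))
    b0 <- unname(stats::coef(seedfit)[2])
  } else {
    a0 <- mean(y[pos])
    b0 <- 0
  }
  if (!is.finite(a0) || a0 <= 0) a0 <- max(y)
  if (!is.finite(b0)) b0 <- 0
  a <- a0; b <- b0
  fitted_y <- a0 * exp(b0 * t)
  ss_seed <- sum((y - fitted_y)^2)
  refined <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t),
                      start = list(a = a0, b = b0),
                      lower = c(a = .Machine$double.eps, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(refined)) {
    cf <- stats::coef(refined)
    ss_ref <- sum(stats::resid(refined)^2)
    if (is.finite(ss_ref) && ss_ref <= ss_seed + 1e-12) {
      a <- unname(cf["a"]); b <- unname(cf["b"])
      fitted_y <- a * exp(b * t)
    }
  }
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(a = a, b = b, r_squared = r2), class = "exp_fit")
}

#' Fit exponentials to every response type of a timecourse
#'
#' @param tc A `timecourse` from [response_timecourse()].
#' @return Named list of `exp_fit` objects, one per response type present.
#' @export
fit_timecourses <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  types <- unique(tc$response_type)
  fits <- lapply(types, function(ty) {
    d <- tc[tc$response_type == ty, ]
    fit_exponential(d$bin_center_s, d$value)
  })
  names(fits) <- types
  fits
}

#' Intersection time of two exponential timecourse fits
#'
#' Solves `a1 * exp(b1 t) = a2 * exp(b2 t)`:
#' `t* = log(a1 / a2) / (b2 - b1)` when the rate constants differ. Returns
#' the intersection only if it falls within the session (`0 <= t* <= t_max`).
#' Parallel curves (`b1 == b2`, `a1 != a2`) never intersect; identical
#' curves are everywhere equal and flagged degenerate.
#'
#' @param fit1,fit2 `exp_fit` objects (e.g. the HIT and MISS fits).
#' @param t_max Session length in seconds.
#' @return List with `t_star_s` (number or `NULL`) and `degenerate` flag.
#' @examples
#' f1 <- structure(list(a = 1, b = -0.1), class = "exp_fit")
#' f2 <- structure(list(a = 0.2, b = 0.05), class = "exp_fit")
#' curve_intersection(f1, f2, 100)$t_star_s   # log(5)/0.15
#' @export
curve_intersection <- function(fit1, fit2, t_max) {
  a1 <- fit1$a; b1 <- fit1$b
  a2 <- fit2$a; b2 <- fit2$b
  if (a1 <= 0 || a2 <= 0) {
    stop_oddballr("exponential amplitudes must be positive", "invalid_fit")
  }
  if (b1 == b2) {
    if (a1 == a2) return(list(t_star_s = NULL, degenerate = TRUE))
    return(list(t_star_s = NULL, degenerate = FALSE))
  }
  t_star <- log(a1 / a2) / (b2 - b1)
  if (t_star < 0 || t_star > t_max) {
    return(list(t_star_s = NULL, degenerate = FALSE))
  }
  list(t_star_s = t_star, degenerate = FALSE)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: y = %.4g * exp(%.4g t), R^2 = %.3f>\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
plot.timecourse <- function(x, ...) {
  types <- c("HIT", "FA", "CR", "MISS")
  cols <- c(HIT = "red", FA = "blue", CR = "darkgreen", MISS = "orange")
  plot(NA, xlim = range(x$bin_center_s), ylim = c(0, 1),
       xlab = "session time (s)", ylab = "response proportion", ...)
  for (ty in intersect(types, unique(x$response_type))) {
    d <- x[x$response_type == ty, ]
    points(d$bin_center_s, d$value, col = cols[ty], pch = 16)
    f <- tryCatch(fit_exponential(d$bin_center_s, d$value),
                  error = function(e) NULL)
    if (!is.null(f)) {
      tt <- seq(min(d$bin_center_s), max(d$bin_center_s), length.out = 200)
      lines(tt, f$a * exp(f$b * tt), col = cols[ty])
    }
  }
  legend("topright", legend = intersect(types, unique(x$response_type)),
         col = cols[intersect(types, unique(x$response_type))], pch = 16, bty = "n")
  invisible(x)
}
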