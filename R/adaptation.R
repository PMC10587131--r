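# Behavioural adaptation: hit probability as a function of the number of
# standard tones preceding each deviant, with a quadratic trend fit.

#' Number of standards preceding each deviant
#'
#' For each deviant in the sequence, the length of the maximal run of
#' standard tones immediately before it. The first deviant's run includes
#' the forced lead-in standards.
#'
#' @param seq An `oddball_sequence`, or any data frame with a `role` column
#'   in tone order.
#' @return Integer vector, one `k` per deviant, in deviant order.
#' @examples
#' roles <- c(rep("standard", 5), "deviant", rep("standard", 3), "deviant")
#' preceding_standard_counts(data.frame(role = roles))  # 5, 3
#' @export
preceding_standard_counts <- function(seq) {
  dev_i <- which(seq$role == "deviant")
  if (length(dev_i) == 0L) return(integer(0))
  as.integer(diff(c(0L, dev_i)) - 1L)
}

#' Hit rate by number of preceding standards
#'
#' Pools deviant trials from one or more scored sessions and computes, for
#' each observed preceding-standards count `k`, the proportion of deviants
#' answered with a HIT. This is the normalisation used for adaptation
#' curves: hits at a given `k` divided by deviant presentations at that `k`.
#' `k` values at which no deviant occurred are omitted.
#'
#' @param trial_tables A trial data frame (from a `session_log`) or a list
#'   of them. Each must carry `role` and `outcome` in tone order.
#' @param mode `"pooled"` (default) pools counts across sessions before
#'   dividing; `"session_mean"` averages each session's per-k rate instead.
#' @return An `adaptation_curve`: data frame `k`, `n_dev`, `n_hit`, `rate`
#'   (for `"session_mean"`, `rate` is the mean of session rates and counts
#'   are pooled totals), with no fit attached yet.
#' @export
hit_rate_by_preceding <- function(trial_tables, mode = c("pooled", "session_mean")) {
  mode <- match.arg(mode)
  if (is.data.frame(trial_tables)) trial_tables <- list(trial_tables)
  per <- lapply(trial_tables, function(tr) {
    k <- preceding_standard_counts(tr)
    if (length(k) == 0L) return(NULL)
    hit <- tr$outcome[tr$role == "deviant"] == "HIT"
    data.frame(k = k, hit = hit)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) {
    stop_oddballr("no deviant trials in input", "empty_input")
  }
  all <- do.call(rbind, per)
  n_dev <- tapply(all$hit, all$k, length)
  n_hit <- tapply(all$hit, all$k, sum)
  k <- as.integer(names(n_dev))
  rate <- if (mode == "pooled") {
    as.numeric(n_hit) / as.numeric(n_dev)
  } else {
    sess_rates <- lapply(per, function(d) {
      r <- tapply(d$hit, d$k, mean)
      data.frame(k = as.integer(names(r)), rate = as.numeric(r))
    })
    sr <- do.call(rbind, sess_rates)
    as.numeric(tapply(sr$rate, factor(sr$k, levels = k), mean))
  }
  ord <- order(k)
  structure(data.frame(k = k[ord], n_dev = as.integer(n_dev)[ord],
                       n_hit = as.integer(n_hit)[ord], rate = rate[ord]),
            mode = mode,
            class = c("adaptation_curve", "data.frame"))
}

#' Quadratic trend fit for an adaptation curve
#'
#' Unweighted least-squares fit of the per-k hit rate on `(1, k, k^2)`, the
#' second-degree polynomial trend used for adaptation curves, with goodness
#' of fit R^2 = 1 - SS_res / SS_tot. When the rates are constant
#' (SS_tot = 0) the fit is exact and R^2 is reported as 1. A
#' deviant-count-weighted fit is available via `weighted = TRUE`.
#'
#' @param curve An `adaptation_curve` from [hit_rate_by_preceding()], or any
#'   data frame with `k` and `rate` columns (and `n_dev` if weighting).
#' @param weighted Weight each k bin by its deviant count.
#' @return The curve with a `fit` attribute: list `c0`, `c1`, `c2`
#'   (intercept, linear, quadratic coefficients), `r_squared`, `n_points`.
#' @examples
#' k <- 3:27
#' curve <- data.frame(k = k, rate = 0.1 + 0.05 * k - 0.001 * k^2)
#' attr(fit_quadratic(curve), "fit")
#' @export
fit_quadratic <- function(curve, weighted = FALSE) {
  if (length(unique(curve$k)) < 3L) {
    stop_oddballr("quadratic fit needs at least 3 distinct k values",
                  "underdetermined_fit")
  }
  w <- if (weighted) curve$n_dev else NULL
  m <- stats::lm(rate ~ k + I(k^2), data = curve, weights = w)
  cf <- unname(stats::coef(m))
  pred <- stats::fitted(m)
  ss_res <- sum((curve$rate - pred)^2)
  ss_tot <- sum((curve$rate - mean(curve$rate))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  attr(curve, "fit") <- list(c0 = cf[1], c1 = cf[2], c2 = cf[3],
                             r_squared = r2, n_points = nrow(curve))
  if (!inherits(curve, "adaptation_curve")) {
    class(curve) <- c("adaptation_curve", class(curve))
  }
  curve
}

#' @export
print.adaptation_curve <- function(x, ...) {
  cat(sprintf("<adaptation_curve: %d k bins, %d deviants pooled>\n",
              nrow(x), sum(x$n_dev)))
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    cat(sprintf("  quadratic fit: rate = %.4g %+.4g k %+.4g k^2 (R^2 = %.3f)\n",
                fit$c0, fit$c1, fit$c2, fit$r_squared))
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more bins\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.adaptation_curve <- function(x, ...) {
  plot(x$k, x$rate, xlab = "standards before deviant (k)",
       ylab = "HIT rate", ylim = c(0, 1), pch = 16, ...)
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    kk <- seq(min(x$k), max(x$k), length.out = 200)
    lines(kk, fit$c0 + fit$c1 * kk + fit$c2 * kk^2, col = "red", lwd = 2)
  }
  invisible(x)
}
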