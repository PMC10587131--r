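# Signal-detection metrics: hit/false-alarm proportions, the Hautus
# log-linear correction, and the d' sensitivity index.

#' Hit and false-alarm proportions with optional log-linear correction
#'
#' Converts trial counts to proportions. With `correction = "auto"`, the
#' Hautus log-linear correction is applied whenever any count is extreme
#' (0 hits, all hits, 0 false alarms or all false alarms): 0.5 is added to
#' both the HIT and FA counts and 1 to both the deviant and standard counts,
#' so both corrected rates lie strictly inside (0, 1). `"always"` corrects
#' unconditionally; `"never"` returns raw proportions and errors on extreme
#' counts (where d' would be infinite).
#'
#' @param n_hit,n_dev Hits and deviant (signal) trial count.
#' @param n_fa,n_std False alarms and standard (noise) trial count.
#' @param correction `"auto"` (default), `"always"` or `"never"`.
#' @return A `rate_pair` list: `H`, `F`, `corrected`, and the source counts.
#' @examples
#' response_rates(70, 70, 0, 630)          # corrected: H = 70.5/71
#' response_rates(45, 70, 97, 630)         # interior counts, raw
#' @export
response_rates <- function(n_hit, n_dev, n_fa, n_std,
                           correction = c("auto", "always", "never")) {
  correction <- match.arg(correction)
  stopifnot(n_dev > 0, n_std > 0,
            n_hit >= 0, n_hit <= n_dev, n_fa >= 0, n_fa <= n_std)
  extreme <- n_hit %in% c(0, n_dev) || n_fa %in% c(0, n_std)
  correct <- switch(correction,
                    auto = extreme,
                    always = TRUE,
                    never = FALSE)
  if (!correct && extreme) {
    stop_oddballr(
      "extreme count (0 or maximal HIT/FA) gives a degenerate rate; use the log-linear correction",
      "degenerate_rate")
  }
  if (correct) {
    H <- (n_hit + 0.5) / (n_dev + 1)
    F <- (n_fa + 0.5) / (n_std + 1)
  } else {
    H <- n_hit / n_dev
    F <- n_fa / n_std
  }
  structure(list(H = H, F = F, corrected = correct,
                 n_hit = n_hit, n_dev = n_dev, n_fa = n_fa, n_std = n_std),
            class = "rate_pair")
}

#' d' sensitivity index from hit and false-alarm rates
#'
#' The Green & Swets sensitivity index: the difference of standard-normal
#' quantiles of the hit and false-alarm proportions,
#' `d' = qnorm(H) - qnorm(F)`. Antisymmetric in its arguments and zero at
#' `H == F` (chance performance).
#'
#' @param rates A `rate_pair` from [response_rates()], or the hit proportion
#'   when `F` is given.
#' @param F False-alarm proportion (when `rates` is a bare hit proportion).
#' @return A `dprime_result` list: `d_prime` and the provenance `rate_pair`.
#' @examples
#' dprime(0.647, 0.154)$d_prime          # ~ 1.40
#' dprime(pnorm(1), pnorm(-1))$d_prime   # 2
#' @export
dprime <- function(rates, F = NULL) {
  if (inherits(rates, "rate_pair")) {
    H <- rates$H
    Fv <- rates$F
    pair <- rates
  } else {
    H <- rates
    Fv <- F
    pair <- structure(list(H = H, F = Fv, corrected = NA,
                           n_hit = NA, n_dev = NA, n_fa = NA, n_std = NA),
                      class = "rate_pair")
  }
  if (!is.numeric(H) || !is.numeric(Fv) ||
      H <= 0 || H >= 1 || Fv <= 0 || Fv >= 1) {
    stop_oddballr("rates must lie strictly inside (0, 1); correct extreme counts first",
                  "degenerate_rate")
  }
  structure(list(d_prime = stats::qnorm(H) - stats::qnorm(Fv),
                 rate_pair = pair),
            class = "dprime_result")
}

#' d' directly from trial counts
#'
#' Composition of [response_rates()] and [dprime()]. For many-deviant
#' sessions, pool hits and deviants over all deviant frequencies before
#' calling (sensitivity is quantified for all deviants together, regardless
#' of frequency).
#'
#' @inheritParams response_rates
#' @return A `dprime_result`.
#' @examples
#' dprime_from_counts(70, 70, 0, 630)$d_prime    # ~ 5.62 (ceiling, corrected)
#' dprime_from_counts(35, 70, 315, 630)$d_prime  # 0
#' @export
dprime_from_counts <- function(n_hit, n_dev, n_fa, n_std,
                               correction = c("auto", "always", "never")) {
  dprime(response_rates(n_hit, n_dev, n_fa, n_std, match.arg(correction)))
}

#' d' summary for a scored session
#'
#' Convenience wrapper: counts outcomes in a `session_log` and returns the
#' tidy one-row summary consumed by downstream group statistics.
#'
#' @param log A `session_log`.
#' @param correction Passed to [response_rates()].
#' @param session_id,group Optional identifiers carried into the output.
#' @return One-row data frame: `session_id`, `group`, `n_hit`, `n_dev`,
#'   `n_fa`, `n_std`, `H`, `F`, `corrected`, `d_prime`.
#' @export
session_dprime <- function(log, correction = "auto",
                           session_id = NA_character_, group = NA_character_) {
  s <- session_summary(log)
  r <- response_rates(s$n_hit, s$n_dev, s$n_fa, s$n_std, correction)
  d <- dprime(r)
  data.frame(session_id = session_id, group = group,
             n_hit = s$n_hit, n_dev = s$n_dev, n_fa = s$n_fa, n_std = s$n_std,
             H = r$H, F = r$F, corrected = r$corrected,
             d_prime = d$d_prime, stringsAsFactors = FALSE)
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("<dprime_result: d' = %.4f (H = %.4f, F = %.4f%s)>\n",
              x$d_prime, x$rate_pair$H, x$rate_pair$F,
              if (isTRUE(x$rate_pair$corrected)) ", log-linear corrected" else ""))
  invisible(x)
}
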