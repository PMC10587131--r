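# Session scoring: join tone events and nose-poke events into
# HIT/FA/CR/MISS trials with latencies, reward and timeout accounting.

#' Score a session of tone and nose-poke events
#'
#' Walks the tone sequence in order and assigns each tone its behavioural
#' outcome. The response window of a tone is the half-open interval
#' `[onset, onset + response_window_s)`; the earliest not-yet-consumed poke
#' inside the window is that trial's response (later in-window pokes are left
#' unassigned, so no poke ever counts twice). A response to a deviant is a
#' HIT (rewarded); to a standard, a false alarm (FA, punished with a
#' timeout); no response yields a MISS (deviant) or correct rejection (CR,
#' standard).
#'
#' In `"scheduled"` mode tone onsets are computed from the session clock:
#' each tone follows the previous onset by the ISI, plus the timeout after
#' every FA (stimulation pauses during punishment). Pokes falling during a
#' timeout lie in no window; they are reported as unassigned and trigger no
#' further punishment. In `"recorded"` mode onsets are taken from
#' `actual_onset_s` (an argument or a column of `seq`), so logs from
#' hardware that did not pause the schedule are scorable too.
#'
#' @param seq An `oddball_sequence`.
#' @param pokes Numeric vector of nose-poke times in seconds, sorted
#'   ascending (or a data frame with a `time_s` column).
#' @param mode `"scheduled"` (compute onsets; default) or `"recorded"`.
#' @param actual_onset_s Onsets for `"recorded"` mode, one per tone.
#' @return A `session_log`: list with `trials` (data frame: `index`, `role`,
#'   `frequency_khz`, `actual_onset_s`, `outcome`, `latency_s`, `rewarded`,
#'   `timeout_applied`), `unassigned_pokes`, `n_rewards`, and `spec`.
#' @examples
#' sp <- paradigm_spec("oddball", 20, 2, 8.0, 11.3, seed = 1)
#' seq <- make_oddball_sequence(sp)
#' dev_onset <- (which(seq$role == "deviant")[1] - 1) * sp$isi_s
#' log <- score_session(seq, dev_onset + 0.5)
#' log$trials[seq$role == "deviant", ]
#' @export
score_session <- function(seq, pokes, mode = c("scheduled", "recorded"),
                          actual_onset_s = NULL) {
  mode <- match.arg(mode)
  spec <- attr(seq, "spec")
  stopifnot(!is.null(spec))
  if (is.data.frame(pokes)) pokes <- pokes$time_s
  pokes <- as.numeric(pokes)
  if (is.unsorted(pokes)) {
    stop_oddballr("poke times must be sorted ascending", "input_error")
  }
  if (spec$response_window_s >= spec$isi_s) {
    stop_oddballr("response window must be shorter than the ISI", "config_error")
  }
  n <- nrow(seq)
  if (mode == "recorded") {
    if (is.null(actual_onset_s)) actual_onset_s <- seq$actual_onset_s
    if (is.null(actual_onset_s) || length(actual_onset_s) != n) {
      stop_oddballr("recorded mode needs one actual onset per tone", "input_error")
    }
  }
  w <- spec$response_window_s
  onset <- numeric(n)
  outcome <- character(n)
  latency <- rep(NA_real_, n)
  unassigned <- numeric(0)
  j <- 1L
  np <- length(pokes)
  t_next <- 0
  for (k in seq_len(n)) {
    o <- if (mode == "recorded") actual_onset_s[k] else t_next
    onset[k] <- o
    while (j <= np && pokes[j] < o) {
      unassigned <- c(unassigned, pokes[j])
      j <- j + 1L
    }
    responded <- j <= np && pokes[j] < o + w
    if (responded) {
      latency[k] <- pokes[j] - o
      j <- j + 1L
    }
    is_dev <- seq$role[k] == "deviant"
    outcome[k] <- if (is_dev) {
      if (responded) "HIT" else "MISS"
    } else {
      if (responded) "FA" else "CR"
    }
    if (mode == "scheduled") {
      t_next <- o + spec$isi_s + if (outcome[k] == "FA") spec$timeout_s else 0
    }
  }
  if (j <= np) unassigned <- c(unassigned, pokes[j:np])
  trials <- data.frame(
    index = seq$index,
    role = seq$role,
    frequency_khz = seq$frequency_khz,
    actual_onset_s = onset,
    outcome = outcome,
    latency_s = latency,
    rewarded = outcome == "HIT",
    timeout_applied = outcome == "FA",
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials,
                 unassigned_pokes = unassigned,
                 n_rewards = sum(trials$rewarded),
                 spec = spec),
            class = "session_log")
}

#' Summarise a scored session
#'
#' Outcome counts, percentage rates and mean response latencies for one
#' session. Percentages are relative to the relevant tone role: `%HIT` and
#' `%MISS` to deviants, `%FA` and `%CR` to standards. Latency means are
#' taken over trials with a response only and are `NA` when there are none.
#'
#' @param log A `session_log` from [score_session()].
#' @return A `session_counts` list: `n_hit`, `n_fa`, `n_cr`, `n_miss`,
#'   `n_dev`, `n_std`, `pct_hit`, `pct_fa`, `pct_cr`, `pct_miss`,
#'   `mean_hit_latency_s`, `mean_fa_latency_s`, `n_rewards`.
#' @export
session_summary <- function(log) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  n_dev <- sum(tr$role == "deviant")
  n_std <- sum(tr$role == "standard")
  n_hit <- sum(tr$outcome == "HIT")
  n_fa <- sum(tr$outcome == "FA")
  hl <- tr$latency_s[tr$outcome == "HIT"]
  fl <- tr$latency_s[tr$outcome == "FA"]
  structure(list(
    n_hit = n_hit, n_fa = n_fa,
    n_cr = n_std - n_fa, n_miss = n_dev - n_hit,
    n_dev = n_dev, n_std = n_std,
    pct_hit = 100 * n_hit / n_dev,
    pct_fa = 100 * n_fa / n_std,
    pct_cr = 100 * (n_std - n_fa) / n_std,
    pct_miss = 100 * (n_dev - n_hit) / n_dev,
    mean_hit_latency_s = if (n_hit > 0) mean(hl) else NA_real_,
    mean_fa_latency_s = if (n_fa > 0) mean(fl) else NA_real_,
    n_rewards = log$n_rewards
  ), class = "session_counts")
}

#' @export
print.session_counts <- function(x, ...) {
  cat("<session_counts>\n")
  cat(sprintf("  deviants: %d  (HIT %d = %.1f%%, MISS %d = %.1f%%)\n",
              x$n_dev, x$n_hit, x$pct_hit, x$n_miss, x$pct_miss))
  cat(sprintf("  standards: %d (CR %d = %.1f%%, FA %d = %.1f%%)\n",
              x$n_std, x$n_cr, x$pct_cr, x$n_fa, x$pct_fa))
  cat(sprintf("  mean latency: HIT %s s, FA %s s; rewards %d\n",
              format(round(x$mean_hit_latency_s, 3)),
              format(round(x$mean_fa_latency_s, 3)), x$n_rewards))
  invisible(x)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log: %d trials, %d rewards, %d unassigned pokes>\n",
              nrow(x$trials), x$n_rewards, length(x$unassigned_pokes)))
  print(table(x$trials$outcome))
  invisible(x)
}

#' @export
summary.session_log <- function(object, ...) session_summary(object)

#' Training-criterion check over consecutive sessions
#'
#' Determines whether performance reached criterion: `k` consecutive
#' sessions with sensitivity at or above `threshold` (the training rule is
#' d' >= 1 for 3 consecutive sessions).
#'
#' @param dprimes Numeric vector of per-session d' values, in session order.
#' @param threshold Criterion d' value (default 1).
#' @param k Required run length (default 3).
#' @return List with `reached` (logical) and `first_session` (1-based start
#'   of the first qualifying run, or `NA`).
#' @examples
#' criterion_reached(c(0.4, 1.0, 1.2, 1.1))  # reached, run starts at 2
#' @export
criterion_reached <- function(dprimes, threshold = 1, k = 3L) {
  stopifnot(k >= 1L)
  n <- length(dprimes)
  if (n >= k) {
    ok <- dprimes >= threshold
    for (start in seq_len(n - k + 1L)) {
      if (all(ok[start:(start + k - 1L)])) {
        return(list(reached = TRUE, first_session = start))
      }
    }
  }
  list(reached = FALSE, first_session = NA_integer_)
}
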