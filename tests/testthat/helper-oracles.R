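# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Inverse standard-normal CDF by bisection on pnorm (never calls qnorm).
bisect_probit <- function(p, tol = 1e-12) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_dprime <- function(H, F) bisect_probit(H) - bisect_probit(F)

# Brute-force scheduled-clock session scorer: O(n_tones * n_pokes) scan
# with explicit consumed flags, written independently of score_session's
# single-pass pointer walk.
oracle_score_scheduled <- function(roles, pokes, isi, window, timeout) {
  n <- length(roles)
  consumed <- rep(FALSE, length(pokes))
  onset <- numeric(n)
  outcome <- character(n)
  latency <- rep(NA_real_, n)
  t <- 0
  for (k in seq_len(n)) {
    onset[k] <- t
    resp_i <- NA_integer_
    for (j in seq_along(pokes)) {
      if (!consumed[j] && pokes[j] >= t && pokes[j] < t + window) {
        if (is.na(resp_i) || pokes[j] < pokes[resp_i]) resp_i <- j
      }
    }
    responded <- !is.na(resp_i)
    if (responded) {
      consumed[resp_i] <- TRUE
      latency[k] <- pokes[resp_i] - t
    }
    outcome[k] <- if (roles[k] == "deviant") {
      if (responded) "HIT" else "MISS"
    } else {
      if (responded) "FA" else "CR"
    }
    t <- t + isi + if (outcome[k] == "FA") timeout else 0
  }
  list(onset = onset, outcome = outcome, latency = latency,
       unassigned = sort(pokes[!consumed]))
}

# Small random session fixture: sequence plus haphazard pokes.
random_small_session <- function(seed) {
  set.seed(seed)
  n <- sample(10:50, 1)
  n_dev <- sample(1:max(1, n %/% 5), 1)
  lead <- min(2L, n - n_dev - n_dev)  # keep feasible at small n
  spec <- paradigm_spec("oddball", n, n_dev, 8.0, 11.3,
                        isi_s = 1.5, lead_in = max(0L, lead), min_run = 1L)
  seqd <- make_oddball_sequence(spec, seed = seed)
  t_max <- n * (1.5 + 5) # generous: room for timeouts
  pokes <- sort(runif(sample(0:(2 * n), 1), 0, t_max))
  list(seq = seqd, spec = spec, pokes = pokes)
}

make_seq_from_roles <- function(roles, spec) {
  df <- data.frame(index = seq_along(roles) - 1L, role = roles,
                   frequency_khz = ifelse(roles == "deviant",
                                          spec$deviant_khz[1], spec$standard_khz),
                   nominal_onset_s = (seq_along(roles) - 1L) * spec$isi_s,
                   duration_ms = spec$duration_ms, stringsAsFactors = FALSE)
  structure(df, spec = spec, class = c("oddball_sequence", "data.frame"))
}
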