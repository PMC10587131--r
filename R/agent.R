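# Generative synthetic-rat agent: an expectation/prediction-error responder
# that produces nose-poke events for any stimulus sequence, with the
# statistical structure the downstream analyses assume (adaptation to the
# repeated standard, novelty-driven deviant detection, within-session
# engagement decay, impulsive false alarms, realistic latencies).
#
# The agent keeps a decaying "expectation field" E(g) over log-frequency
# (octave) positions g. Each tone deposits expectation mass at its own
# frequency; the novelty of an incoming tone is the expectation-weighted
# distance (under a Gaussian generalization kernel on the octave axis)
# between the tone and the field. A repeated standard becomes expected
# (novelty -> 0) while a rare deviant stays novel, which is the behavioural
# face of stimulus-specific adaptation.

#' Parameters of the synthetic-rat agent
#'
#' Defaults are frozen to produce sessions in the qualitative performance
#' bands of trained rats on a 700-tone 90/10 oddball at ISI 1.5 s
#' (hit rate roughly 55-80%, correct rejections 80-95%, hit latencies
#' around 0.5-0.8 s, responding declining over the session).
#'
#' @param alpha Expectation mass deposited per tone.
#' @param tau_E_s Expectation decay time constant, seconds. Governs how many
#'   intervening standards erase the memory of the last deviant, hence where
#'   the adaptation curve plateaus (~25 standards at ISI 1.5 s).
#' @param sigma_gen_oct Generalization bandwidth on the octave axis; a 0.5
#'   octave contrast is well outside one bandwidth at the default.
#' @param kappa Confidence half-saturation, in expectation-mass units.
#' @param beta Decision slope (logistic).
#' @param theta Decision threshold on the novelty-times-confidence drive.
#' @param lambda_impulse Baseline (impulsive) poke probability per tone.
#' @param A_min Engagement floor in `[0, 1]`.
#' @param tau_eng_s Engagement decay time constant, seconds.
#' @param lat0_s,lat_slope_s,lat_sigma_s Latency model: base latency, slope
#'   on (1 - drive), and noise SD, all seconds. Weak drives answer slower.
#' @param seed RNG seed for the agent's response stream.
#' @return A `rat_agent_params` list.
#' @export
rat_agent_params <- function(alpha = 1, tau_E_s = 10, sigma_gen_oct = 0.35,
                             kappa = 0.3, beta = 28, theta = 0.50,
                             lambda_impulse = 0.15, A_min = 0.02,
                             tau_eng_s = 1800,
                             lat0_s = 0.30, lat_slope_s = 0.50,
                             lat_sigma_s = 0.15, seed = NULL) {
  stopifnot(alpha > 0,
            tau_E_s > 0, sigma_gen_oct > 0, kappa > 0,
            theta > 0, theta < 1,
            lambda_impulse >= 0, lambda_impulse < 1,
            A_min >= 0, A_min <= 1, tau_eng_s > 0,
            lat0_s >= 0, lat_sigma_s >= 0)
  structure(list(alpha = alpha, tau_E_s = tau_E_s,
                 sigma_gen_oct = sigma_gen_oct, kappa = kappa,
                 beta = beta, theta = theta,
                 lambda_impulse = lambda_impulse,
                 A_min = A_min, tau_eng_s = tau_eng_s,
                 lat0_s = lat0_s, lat_slope_s = lat_slope_s,
                 lat_sigma_s = lat_sigma_s,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "rat_agent_params")
}

#' Fresh agent state
#'
#' Empty expectation field at session time zero.
#' @return An `agent_state` list: `oct` and `mass` (the expectation field),
#'   `t_last_s` (time of the previous tone).
#' @export
agent_state <- function() {
  structure(list(oct = numeric(0), mass = numeric(0), t_last_s = 0),
            class = "agent_state")
}

#' One agent decision step
#'
#' Advances the agent by one tone. In order: (1) the expectation field
#' decays by `exp(-dt / tau_E_s)`; (2) the tone's novelty is computed as the
#' expectation-weighted complement of the Gaussian generalization kernel
#' (novelty 1 on an empty field); (3) confidence saturates with total field
#' mass; (4) engagement decays with session time toward `A_min`; (5) the
#' poke probability combines impulsive baseline and a logistic decision on
#' novelty x confidence, scaled by engagement; (6) if responding, a latency
#' is drawn (slower for weaker drives, truncated-normal noise); (7) the tone
#' deposits `alpha` expectation mass at its frequency.
#'
#' Consumes RNG draws; wrap in a seeded context (as [simulate_session()]
#' does) for reproducibility.
#'
#' @param state An `agent_state`.
#' @param params A `rat_agent_params`.
#' @param onset_s Tone onset in session time, seconds (>= `state$t_last_s`).
#' @param frequency_khz Tone frequency, kHz.
#' @return List: `responded`, `latency_s` (`NA` if not), `p` (poke
#'   probability), `nu` (novelty), `confidence`, `engagement`, `state`
#'   (updated).
#' @export
agent_step <- function(state, params, onset_s, frequency_khz) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "rat_agent_params"),
            onset_s >= state$t_last_s)
  dt <- onset_s - state$t_last_s
  mass <- state$mass * exp(-dt / params$tau_E_s)
  f_oct <- log2(frequency_khz)
  tot <- sum(mass)
  if (tot <= 0) {
    nu <- 1
  } else {
    G <- exp(-(f_oct - state$oct)^2 / (2 * params$sigma_gen_oct^2))
    nu <- sum(mass * (1 - G)) / tot
  }
  conf <- tot / (tot + params$kappa)
  A <- params$A_min + (1 - params$A_min) * exp(-onset_s / params$tau_eng_s)
  drive <- nu * conf
  p <- A * (params$lambda_impulse +
              (1 - params$lambda_impulse) * sigmoid(params$beta * (drive - params$theta)))
  responded <- stats::runif(1) < p
  latency <- NA_real_
  if (responded) {
    # truncated-normal noise >= -lat0 keeps the latency non-negative
    lo <- stats::pnorm(-params$lat0_s / max(params$lat_sigma_s, 1e-12))
    u <- stats::runif(1, lo, 1)
    noise <- params$lat_sigma_s * stats::qnorm(u)
    latency <- params$lat0_s + params$lat_slope_s * (1 - drive) + noise
  }
  i <- which(abs(state$oct - f_oct) < 1e-9)
  if (length(i) == 1L) {
    mass[i] <- mass[i] + params$alpha
    oct <- state$oct
  } else {
    oct <- c(state$oct, f_oct)
    mass <- c(mass, params$alpha)
  }
  new_state <- structure(list(oct = oct, mass = mass, t_last_s = onset_s),
                         class = "agent_state")
  list(responded = responded, latency_s = latency, p = p,
       nu = nu, confidence = conf, engagement = A, state = new_state)
}

#' Simulate a full behavioural session
#'
#' Runs the agent over a stimulus sequence under the scheduled session
#' clock: each tone follows the previous onset by the ISI, plus the
#' false-alarm timeout whenever the previous trial scored as an FA. Scoring
#' conventions mirror [score_session()] exactly (earliest unconsumed poke in
#' the half-open response window), so re-scoring the emitted pokes with
#' `score_session(seq, pokes, mode = "scheduled")` reproduces the simulated
#' outcomes. Pokes whose latency falls outside the window are still emitted
#' (they end up unassigned or captured by a later window at scoring).
#'
#' @param seq An `oddball_sequence`.
#' @param params A `rat_agent_params`.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A `rat_simulation` list: `pokes` (sorted poke times), `truth`
#'   (per-tone data frame: `index`, `actual_onset_s`, `p_response`,
#'   `responded`, `latency_s`, `outcome`), `seq`, `params`.
#' @examples
#' sp <- paradigm_spec("oddball", 100, 10, 8.0, 11.3, seed = 1)
#' seq <- make_oddball_sequence(sp)
#' sim <- simulate_session(seq, rat_agent_params(seed = 1))
#' table(sim$truth$outcome)
#' @export
simulate_session <- function(seq, params = rat_agent_params(),
                             seed = params$seed) {
  spec <- attr(seq, "spec")
  stopifnot(!is.null(spec), inherits(params, "rat_agent_params"))
  w <- spec$response_window_s
  n <- nrow(seq)
  with_seed(seed, {
    st <- agent_state()
    onset <- numeric(n)
    p_resp <- numeric(n)
    responded <- logical(n)
    latency <- rep(NA_real_, n)
    outcome <- character(n)
    pokes <- numeric(0)
    open <- numeric(0)  # emitted pokes not yet consumed by a window
    t_next <- 0
    for (k in seq_len(n)) {
      o <- t_next
      onset[k] <- o
      step <- agent_step(st, params, o, seq$frequency_khz[k])
      st <- step$state
      p_resp[k] <- step$p
      responded[k] <- step$responded
      latency[k] <- step$latency_s
      if (step$responded) {
        pt <- o + step$latency_s
        pokes <- c(pokes, pt)
        open <- c(open, pt)
      }
      # consume the earliest open poke falling in this tone's window
      open <- open[open >= o]  # earlier pokes can never be consumed now
      inwin <- which(open < o + w)
      got <- length(inwin) > 0L
      if (got) open <- open[-inwin[which.min(open[inwin])]]
      is_dev <- seq$role[k] == "deviant"
      outcome[k] <- if (is_dev) {
        if (got) "HIT" else "MISS"
      } else {
        if (got) "FA" else "CR"
      }
      t_next <- o + spec$isi_s + if (outcome[k] == "FA") spec$timeout_s else 0
    }
    truth <- data.frame(index = seq$index, actual_onset_s = onset,
                        p_response = p_resp, responded = responded,
                        latency_s = latency, outcome = outcome,
                        stringsAsFactors = FALSE)
    structure(list(pokes = sort(pokes), truth = truth,
                   seq = seq, params = params),
              class = "rat_simulation")
  })
}

#' @export
print.rat_simulation <- function(x, ...) {
  cat(sprintf("<rat_simulation: %d tones, %d pokes>\n",
              nrow(x$truth), length(x$pokes)))
  print(table(x$truth$outcome))
  invisible(x)
}
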