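# Stimulus-sequence construction for the oddball, frequency-contrast and
# many-deviant go/no-go tasks.

#' Build a geometric frequency ladder
#'
#' Constructs the tone-frequency ladder used to place standards and deviants
#' on a log2 (octave) axis: `base_khz * 2^(k * step_oct)` for
#' `k = 0, ..., n - 1`, each value rounded to `round_to` decimals. A
#' quarter-octave ladder anchored at 4.0 kHz reproduces the ten frequencies
#' of the many-deviant task (4.0 ... 19.0 kHz).
#'
#' @param base_khz Anchor frequency in kHz (> 0).
#' @param step_oct Ladder step in octaves (>= 0).
#' @param n Number of rungs (>= 1).
#' @param round_to Decimal places to round each frequency to.
#' @return Numeric vector of `n` frequencies in kHz, strictly increasing
#'   when `step_oct > 0`.
#' @examples
#' build_frequency_ladder(4.0, 0.25, 10)
#' @export
build_frequency_ladder <- function(base_khz, step_oct, n, round_to = 1) {
  if (!is.numeric(base_khz) || length(base_khz) != 1L || base_khz <= 0) {
    stop_oddballr("`base_khz` must be a single positive frequency in kHz",
                  "invalid_parameter")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n)) {
    stop_oddballr("`n` must be a positive integer count of rungs",
                  "invalid_parameter")
  }
  if (!is.numeric(step_oct) || step_oct < 0) {
    stop_oddballr("`step_oct` must be a non-negative octave fraction",
                  "invalid_parameter")
  }
  round(base_khz * 2^((seq_len(n) - 1L) * step_oct), round_to)
}

#' Resolve a frequency contrast on a ladder
#'
#' Returns the ladder element `contrast_oct / step` positions above (or below,
#' for negative contrasts) a standard frequency. Contrasts are realised as
#' ladder steps rather than direct `2^c` multiplication so that printed,
#' rounded ladder values (e.g. the 4.8--6.7 kHz and 8.0--11.3 kHz half-octave
#' training pairs) are recovered exactly.
#'
#' @param standard_khz Standard frequency; must be an element of `ladder`.
#' @param contrast_oct Contrast in octaves; must be a multiple of the ladder
#'   step.
#' @param ladder Frequency ladder from [build_frequency_ladder()].
#' @param step_oct Octave step between adjacent ladder elements.
#' @return The deviant frequency in kHz.
#' @examples
#' lad <- build_frequency_ladder(4.0, 0.25, 10)
#' frequency_for_contrast(8.0, 0.5, lad)   # 11.3
#' frequency_for_contrast(4.8, 0.5, lad)   # 6.7
#' @export
frequency_for_contrast <- function(standard_khz, contrast_oct, ladder,
                                   step_oct = 0.25) {
  i <- match(standard_khz, ladder)
  if (is.na(i)) {
    stop_oddballr(sprintf("standard %.3g kHz is not on the ladder", standard_khz),
                  "invalid_parameter")
  }
  steps <- contrast_oct / step_oct
  if (abs(steps - round(steps)) > 1e-9) {
    stop_oddballr("`contrast_oct` is not a multiple of the ladder step",
                  "invalid_parameter")
  }
  j <- i + round(steps)
  if (j < 1L || j > length(ladder)) {
    stop_oddballr(sprintf("contrast %+.2f oct from %.3g kHz falls off the ladder",
                          contrast_oct, standard_khz), "out_of_range")
  }
  ladder[j]
}

#' Paradigm specification for an oddball-family session
#'
#' Bundles the stimulus-schedule parameters of one session: total and deviant
#' tone counts, standard and deviant frequencies, onset-to-onset interstimulus
#' interval (ISI), the limited-hold response window, the false-alarm timeout,
#' and the ordering constraints (initial forced standards and the minimum
#' number of standards between consecutive deviants).
#'
#' @param kind One of `"oddball"`, `"contrast_variant"`, `"many_deviant"`.
#' @param n_tones Total tones in the session.
#' @param n_deviant Exact number of deviants (not a binomial draw).
#' @param standard_khz Standard (CS-) frequency in kHz.
#' @param deviant_khz Deviant (CS+) frequency in kHz; for `many_deviant`, a
#'   vector of candidate frequencies excluding the standard.
#' @param isi_s Onset-to-onset interstimulus interval in seconds.
#' @param response_window_s Limited hold in seconds; must be < `isi_s`.
#' @param timeout_s Time-out after each false alarm, seconds.
#' @param lead_in Number of initial forced standard tones.
#' @param min_run Minimum standards preceding every deviant.
#' @param duration_ms Tone duration (metadata only).
#' @param seed RNG seed for deviant placement (optional).
#' @return An object of class `paradigm_spec`.
#' @examples
#' paradigm_spec("oddball", 700, 70, standard_khz = 8.0, deviant_khz = 11.3,
#'               isi_s = 1.5, seed = 1)
#' @export
paradigm_spec <- function(kind = c("oddball", "contrast_variant", "many_deviant"),
                          n_tones, n_deviant, standard_khz, deviant_khz,
                          isi_s = 1.5, response_window_s = 1.49,
                          timeout_s = 5.0, lead_in = 5L, min_run = 3L,
                          duration_ms = 200, seed = NULL) {
  kind <- match.arg(kind)
  if (n_deviant <= 0 || n_deviant >= n_tones) {
    stop_oddballr("need 0 < n_deviant < n_tones", "invalid_parameter")
  }
  if (response_window_s >= isi_s) {
    stop_oddballr("response window must be shorter than the ISI (windows would overlap)",
                  "config_error")
  }
  if (lead_in < 0 || min_run < 0) {
    stop_oddballr("lead_in and min_run must be non-negative", "invalid_parameter")
  }
  if (any(standard_khz <= 0) || any(deviant_khz <= 0)) {
    stop_oddballr("frequencies must be positive", "invalid_parameter")
  }
  if (kind == "many_deviant") {
    if (length(deviant_khz) < 1L) {
      stop_oddballr("many_deviant requires a candidate frequency list",
                    "invalid_parameter")
    }
    if (standard_khz %in% deviant_khz) {
      stop_oddballr("standard frequency must not appear among deviant candidates",
                    "invalid_parameter")
    }
  } else {
    if (length(deviant_khz) != 1L) {
      stop_oddballr(sprintf("%s takes a single deviant frequency", kind),
                    "invalid_parameter")
    }
    if (deviant_khz == standard_khz) {
      stop_oddballr("deviant frequency must differ from the standard",
                    "invalid_parameter")
    }
  }
  structure(list(
    kind = kind,
    n_tones = as.integer(n_tones),
    n_deviant = as.integer(n_deviant),
    standard_khz = standard_khz,
    deviant_khz = deviant_khz,
    isi_s = isi_s,
    response_window_s = response_window_s,
    timeout_s = timeout_s,
    lead_in = as.integer(lead_in),
    min_run = as.integer(min_run),
    duration_ms = duration_ms,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf("<paradigm_spec: %s>\n", x$kind))
  cat(sprintf("  tones: %d (%d standard / %d deviant, %.1f%% deviant)\n",
              x$n_tones, x$n_tones - x$n_deviant, x$n_deviant,
              100 * x$n_deviant / x$n_tones))
  cat(sprintf("  standard %.4g kHz; deviant %s kHz\n", x$standard_khz,
              paste(format(x$deviant_khz), collapse = ", ")))
  cat(sprintf("  ISI %.3g s, window %.3g s, timeout %.3g s, lead-in %d, min run %d\n",
              x$isi_s, x$response_window_s, x$timeout_s, x$lead_in, x$min_run))
  invisible(x)
}

# Largest min_run for which deviant placement is feasible.
max_feasible_min_run <- function(n_tones, n_deviant, lead_in) {
  (n_tones - n_deviant - lead_in) %/% n_deviant
}

# Draw deviant positions (1-based tone indices) uniformly over all feasible
# placements: sample a uniform composition of the spare standards into
# n_dev + 1 slots, then prepend the forced lead-in and per-deviant minimum
# runs.
draw_deviant_positions <- function(spec) {
  n_std <- spec$n_tones - spec$n_deviant
  spare <- n_std - spec$lead_in - spec$min_run * spec$n_deviant
  if (spare < 0) {
    stop_oddballr(sprintf(
      "infeasible spacing: %d standards cannot supply lead_in %d plus min_run %d before each of %d deviants; largest feasible min_run is %d",
      n_std, spec$lead_in, spec$min_run, spec$n_deviant,
      max_feasible_min_run(spec$n_tones, spec$n_deviant, spec$lead_in)),
      "feasibility_error",
      max_feasible_min_run = max_feasible_min_run(spec$n_tones, spec$n_deviant,
                                                  spec$lead_in))
  }
  extra <- sample_composition(spare, spec$n_deviant + 1L)
  gaps <- extra[seq_len(spec$n_deviant)] + spec$min_run
  gaps[1L] <- gaps[1L] + spec$lead_in
  cumsum(gaps + 1L)  # position of each deviant among the tones
}

build_sequence_frame <- function(spec, dev_pos, dev_freqs) {
  role <- rep("standard", spec$n_tones)
  role[dev_pos] <- "deviant"
  freq <- rep(spec$standard_khz, spec$n_tones)
  freq[dev_pos] <- dev_freqs
  tones <- data.frame(
    index = seq_len(spec$n_tones) - 1L,
    role = role,
    frequency_khz = freq,
    nominal_onset_s = (seq_len(spec$n_tones) - 1L) * spec$isi_s,
    duration_ms = spec$duration_ms,
    stringsAsFactors = FALSE
  )
  structure(tones, spec = spec, class = c("oddball_sequence", "data.frame"))
}

#' Generate a classic oddball (or contrast-variant) stimulus sequence
#'
#' Places the exact number of deviants uniformly at random among all
#' arrangements that satisfy the lead-in (initial forced standards) and
#' minimum-run (standards before every deviant) constraints. Placement is
#' done by drawing a uniform random composition of the spare standards, so
#' no rejection sampling is needed and all feasible placements are equally
#' likely.
#'
#' @param spec A [paradigm_spec()] of kind `"oddball"` or
#'   `"contrast_variant"`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param auto_relax If `TRUE` and the requested `min_run` is infeasible
#'   (as for 70/30 deviant-probability sessions), silently relax it to the
#'   largest feasible value instead of raising a feasibility error.
#' @return An `oddball_sequence`: a data frame of tone events
#'   (`index`, `role`, `frequency_khz`, `nominal_onset_s`, `duration_ms`)
#'   with the spec attached as an attribute.
#' @examples
#' sp <- paradigm_spec("oddball", 700, 70, 8.0, 11.3, seed = 1)
#' seq <- make_oddball_sequence(sp)
#' table(seq$role)
#' @export
make_oddball_sequence <- function(spec, seed = spec$seed, auto_relax = FALSE) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (!spec$kind %in% c("oddball", "contrast_variant")) {
    stop_oddballr("use make_many_deviant_sequence() for many_deviant specs",
                  "invalid_parameter")
  }
  if (auto_relax) {
    mf <- max_feasible_min_run(spec$n_tones, spec$n_deviant, spec$lead_in)
    if (mf < spec$min_run) spec$min_run <- as.integer(max(0L, mf))
  }
  with_seed(seed, {
    pos <- draw_deviant_positions(spec)
    build_sequence_frame(spec, pos, rep(spec$deviant_khz, spec$n_deviant))
  })
}

#' Generate a many-deviant stimulus sequence
#'
#' As [make_oddball_sequence()], but each deviant's frequency is drawn from a
#' candidate list. By default assignment is balanced: each candidate is used
#' `floor(n_deviant / n_candidates)` or that plus one times (the remainder
#' candidates chosen at random), and the order is shuffled. Set
#' `balanced = FALSE` for i.i.d. uniform assignment.
#'
#' @param spec A [paradigm_spec()] of kind `"many_deviant"`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param balanced Balance deviant frequencies across candidates (default).
#' @param auto_relax See [make_oddball_sequence()].
#' @return An `oddball_sequence`.
#' @examples
#' lad <- build_frequency_ladder(4.0, 0.25, 10)
#' sp <- paradigm_spec("many_deviant", 720, 72, standard_khz = 8.0,
#'                     deviant_khz = setdiff(lad, 8.0), seed = 7)
#' seq <- make_many_deviant_sequence(sp)
#' table(seq$frequency_khz[seq$role == "deviant"])
#' @export
make_many_deviant_sequence <- function(spec, seed = spec$seed,
                                       balanced = TRUE, auto_relax = FALSE) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (spec$kind != "many_deviant") {
    stop_oddballr("spec kind must be many_deviant", "invalid_parameter")
  }
  if (auto_relax) {
    mf <- max_feasible_min_run(spec$n_tones, spec$n_deviant, spec$lead_in)
    if (mf < spec$min_run) spec$min_run <- as.integer(max(0L, mf))
  }
  cand <- spec$deviant_khz
  with_seed(seed, {
    pos <- draw_deviant_positions(spec)
    freqs <- if (balanced) {
      base <- spec$n_deviant %/% length(cand)
      rem <- spec$n_deviant %% length(cand)
      counts <- rep(base, length(cand))
      if (rem > 0) {
        bump <- sample.int(length(cand), rem)
        counts[bump] <- counts[bump] + 1L
      }
      sample(rep(cand, counts))
    } else {
      sample(cand, spec$n_deviant, replace = TRUE)
    }
    build_sequence_frame(spec, pos, freqs)
  })
}

#' Validate a stimulus sequence against its paradigm constraints
#'
#' Report-only check of the sequence invariants: exact standard/deviant
#' counts, all-standard lead-in, minimum standards before every deviant,
#' strictly increasing onsets, and deviant frequencies differing from the
#' standard. Each violation names the broken rule and the offending tone
#' index.
#'
#' @param seq An `oddball_sequence`.
#' @return A data frame with columns `rule`, `index`, `message`; zero rows
#'   when the sequence is valid.
#' @export
validate_sequence <- function(seq) {
  spec <- attr(seq, "spec")
  stopifnot(!is.null(spec))
  v <- list()
  add <- function(rule, index, msg) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, index = index,
                                       message = msg, stringsAsFactors = FALSE)
  }
  n_dev <- sum(seq$role == "deviant")
  if (n_dev != spec$n_deviant) {
    add("deviant_count", NA_integer_,
        sprintf("expected %d deviants, found %d", spec$n_deviant, n_dev))
  }
  if (nrow(seq) != spec$n_tones) {
    add("tone_count", NA_integer_,
        sprintf("expected %d tones, found %d", spec$n_tones, nrow(seq)))
  }
  lead <- which(seq$role[seq_len(min(spec$lead_in, nrow(seq)))] != "standard")
  for (i in lead) add("lead_in", seq$index[i], "deviant inside the forced lead-in")
  dev_i <- which(seq$role == "deviant")
  if (length(dev_i) > 1L) {
    runs <- diff(dev_i) - 1L
    bad <- which(runs < spec$min_run)
    for (b in bad) {
      add("min_run", seq$index[dev_i[b + 1L]],
          sprintf("only %d standards before this deviant (min %d)",
                  runs[b], spec$min_run))
    }
  }
  if (any(diff(seq$nominal_onset_s) <= 0)) {
    add("onset_order", seq$index[which(diff(seq$nominal_onset_s) <= 0)[1L] + 1L],
        "onsets not strictly increasing")
  }
  same <- which(seq$role == "deviant" & seq$frequency_khz == spec$standard_khz)
  for (i in same) add("deviant_frequency", seq$index[i],
                      "deviant at the standard frequency")
  if (length(v) == 0L) {
    return(data.frame(rule = character(), index = integer(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' @export
print.oddball_sequence <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<oddball_sequence: %d tones (%d standard, %d deviant), ISI %.3g s>\n",
              nrow(x), sum(x$role == "standard"), sum(x$role == "deviant"),
              spec$isi_s))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more tones\n", nrow(x) - 8L))
  invisible(x)
}
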