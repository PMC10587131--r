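---
title: "Models and methods behind oddballr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oddballr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballr)
```

This vignette explains the models, conventions and numerical choices the
package implements, in the spirit of a methods section: what each stage
computes, which parameters matter and why their defaults are what they
are, and what the synthetic data can and cannot tell you about real
animals.

## The paradigm and its constraints

A session is a sequence of pure tones at a fixed onset-to-onset
interstimulus interval (ISI). The classic configuration is 700 tones with
exactly 70 deviants (10%), ISI 1.5 s, a 1.49 s limited hold, a 5 s
time-out after each false alarm, the first 5 tones forced to be
standards, and at least 3 standards before every deviant. Deviant counts
are *exact per session*, not binomial draws: the session is designed with
a fixed maximum number of standards (630) and deviants (70), and the
70/30-probability variant uses 493/207.

`make_oddball_sequence()` places deviants uniformly at random over all
arrangements satisfying the lead-in and minimum-run constraints. The
implementation draws a uniform random composition (stars and bars) of the
"spare" standards — those left after the lead-in and the per-deviant
minimum runs are set aside — into `n_deviant + 1` slots. This is exact
uniform sampling without rejection; every feasible placement is equally
likely, and feasibility is checked up front
(`n_std >= lead_in + min_run * n_deviant`). When the constraint cannot be
met (as for 70/30 sessions at the default `min_run = 3`, where the
largest feasible value is 2) the generator raises an error naming the
largest feasible minimum run rather than silently relaxing a design
constraint; `auto_relax = TRUE` opts into the relaxed value explicitly.

Frequencies live on a quarter-octave ladder anchored at 4.0 kHz and
rounded to 0.1 kHz (4.0, 4.8, 5.7, 6.7, 8.0, 9.5, 11.3, 13.5, 16.0,
19.0). Contrasts are realised as ladder steps rather than direct
`2^contrast` multiplication: the printed half-octave training pairs
(4.8–6.7, 8.0–11.3) match ladder arithmetic but not direct multiplication
of the rounded standard (4.8 × 2^0.5 rounds to 6.8, not 6.7). Many-deviant
sequences draw each deviant's frequency from the 9 ladder tones that are
not the standard; assignment is balanced by default (each candidate used
`floor(n_dev/9)` or one more times, remainder at random) so the
per-frequency probability is fixed at 72/9 = 8 per session (1.11% of
tones); an i.i.d. mode is available (`balanced = FALSE`) since the
original assignment scheme is not documented.

## Trial scoring

The response window of a tone is the half-open interval
`[onset, onset + 1.49 s)`: a poke exactly at the bound is not a response,
and latency is measured from tone onset. The earliest not-yet-consumed
poke in the window is the trial's response; later in-window pokes are
reported unassigned, so no poke can count twice. With
`response_window < ISI` and non-negative time-outs, windows never
overlap, which makes this greedy assignment the unique consistent one.

Whether the stimulus schedule pauses during the 5 s punishment time-out
is an implementation detail of the original chamber software that is not
documented. The engine supports both conventions: `scheduled` mode delays
the next onset by the time-out after every FA (a chamber cannot usefully
present a rewarded trial during punishment), while `recorded` mode trusts
logged onsets, so data from hardware that kept the clock running scores
identically. Pokes falling during a time-out lie in no window; they are
returned as unassigned and trigger no cascading punishment.

## Signal detection

Sensitivity is `d' = qnorm(H) - qnorm(F)` on the standard normal
(`mu = 0, sigma = 1`; any common location/scale cancels in the quantile
difference, so the standard convention is adopted). Extreme counts make a
quantile infinite, so the log-linear correction adds 0.5 to both the HIT
and FA counts and 1 to both the deviant and standard counts. The default
`correction = "auto"` corrects only when some count is extreme — and then
corrects *both* rates, as the rule prescribes — while `"always"` corrects
unconditionally; both are provided because conditional application is the
natural reading of "was necessary in cases with a minimum or maximum",
but unconditional application is also defensible and changes interior
sessions by at most ~1%. For many-deviant sessions, hits are pooled over
all deviant frequencies before computing d′.

## Adaptation curve

For each deviant, `k` is the length of the standard run immediately
before it (the first deviant's run includes the lead-in). The adaptation
curve divides pooled hits by pooled deviant presentations at each `k`,
and the trend is an unweighted least-squares quadratic in `k` with
`R^2 = 1 - SS_res/SS_tot` (reported as 1 when `SS_tot = 0`: a constant
curve is fit perfectly by a constant). The fit is to per-`k` mean rates
because the trend summarises the normalised curve, not trial-level data;
a deviant-count-weighted mode (`weighted = TRUE`) is available since
high-`k` bins are much thinner than low-`k` ones. Pooling counts across
sessions before dividing is the default; a per-session-mean mode exists
because pooling order is a genuine free choice when sessions contribute
unequal deviant counts.

One bookkeeping consequence of uniform deviant placement is that a
sequence usually ends with a few standards after the last deviant, so the
per-deviant `k` values sum to the standard count *minus* that trailing
run; the mean of `k` is therefore slightly below `n_std/n_dev`.

## Engagement timecourse

Trials are binned by actual onset (default bin width 120 s — roughly 80
tones at ISI 1.5 s, wide enough for stable proportions and narrow enough
to resolve a ~30 min session; the value is configurable and the fits are
insensitive to it on exact synthetic curves). HIT and MISS are normalised
by the bin's deviants, FA and CR by its standards, so HIT+MISS = 1 and
FA+CR = 1 per bin. Each response type is fit by a single-term exponential
`y = a exp(b t)`. The fit is seeded by a log-linear regression on the
strictly positive values (exact when the data are exactly exponential)
and refined by Levenberg–Marquardt nonlinear least squares over all bins,
zeros included; if refinement does not improve the seed's residual it is
discarded. The HIT/MISS intersection is computed on the fitted curves in
closed form, `t* = log(a1/a2)/(b2 - b1)`, and reported only when it falls
within the session; equal rate constants are classified explicitly
(parallel, or degenerate when the curves coincide).

## The synthetic-rat agent

The agent is a generative stand-in, not a fitted model of any animal: it
exists so that every analysis stage has input with the right statistical
structure. It maintains an *expectation field* `E(g)` over octave
positions `g` that decays exponentially with time constant `tau_E_s` and
gains `alpha` mass at each tone's frequency. An incoming tone's novelty
is the expectation-weighted complement of a Gaussian generalization
kernel of bandwidth `sigma_gen_oct` on the octave axis (novelty 1 on an
empty field); confidence saturates with total field mass
(`M/(M + kappa)`); engagement decays from 1 toward `A_min` with time
constant `tau_eng_s`. The poke probability is
`A * (lambda + (1 - lambda) * plogis(beta * (novelty * confidence - theta)))`,
and response latency is `lat0 + lat_slope * (1 - drive)` plus
truncated-normal noise, so weakly driven responses (false alarms) are
systematically slower than hits at the defaults.

This one mechanism produces, rather than hard-codes, the qualitative
structure the analyses assume: a repeated standard loses novelty
(behavioural stimulus-specific adaptation), expectation of the deviant
decays over long standard runs so hit probability rises with `k` and
plateaus once the last deviant is forgotten (~3 decay constants ≈ 20–25
standards at ISI 1.5 s and `tau_E_s = 10`), more frequent deviants keep
more deviant expectation mass so 30%-deviant sessions yield lower d′
than 10% sessions, and engagement decay makes HIT and FA fall while CR
and MISS rise within a session.

Defaults were calibrated once, then frozen: `tau_E_s = 10` s,
`sigma_gen_oct = 0.35` (a half-octave contrast sits well outside one
bandwidth), `kappa = 0.3`, `beta = 28`, `theta = 0.50` (centred on the
deviant-drive range so the decision operates on the steep part of the
logistic — a saturated decision would flatten the adaptation trend),
`lambda_impulse = 0.15`, `A_min = 0.02`, `tau_eng_s = 1800` s,
`lat0_s = 0.30`, `lat_slope_s = 0.50`, `lat_sigma_s = 0.15`. Over 100
simulated 700-tone 90/10 sessions these give mean hit rate ≈ 58%,
per-session correct rejections 87–92%, mean hit latency ≈ 0.53 s, d′
≈ 1.45, and an FA-timecourse exponential whose fitted rate constant
recovers `-1/tau_eng_s` with a median error under 5% (the small `A_min`
floor keeps the FA curve close to a single exponential; a high floor
would bias the fit).

What the synthetic data does *not* emulate: individual differences
between animals, session-to-session learning, satiety as a mechanism
distinct from generic engagement decay, motor variability beyond a
single truncated-normal latency noise term, and any neural quantity.
Passing tests on synthetic sessions therefore demonstrate that the
*analyses* are correct and sensitive to the structure they target — not
that real rats obey this generative model.

## Numerical and testing choices

- Sequence generation, simulation and the demo pipeline take explicit
  seeds and restore the caller's RNG state; identical seeds give
  byte-identical outputs.
- The d′ path is validated against a bisection inversion of `pnorm` to
  1e-9; the scheduled clock against an independent brute-force
  event-by-event scorer; the intersection formula against numerical
  root-finding to 1e-8.
- Simulation-based checks in the test suite use 6–100 sessions of 700
  tones each, sizes at which every asserted trend is far from its noise
  floor while the whole suite runs in well under a minute.
- Degenerate inputs are classified, not patched: infeasible spacing,
  overlapping windows, extreme rates without correction, all-zero
  timecourses and sub-minimal fits each raise a typed error.

## Known limitations

- The 70/30 session's printed 493/207 split does not follow from
  700 × 0.70/0.30 rounding; the generator accepts explicit counts and
  claims no derivation.
- `recorded` mode requires per-tone onsets; it does not attempt to infer
  a pause convention from poke statistics.
- The agent's ISI dependence is a modelling lever (expectation decay vs
  engagement decay scale differently with ISI), not a claim about which
  mechanism real animals use; the package exposes both time constants.
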