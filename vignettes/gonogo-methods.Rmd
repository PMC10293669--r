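---
title: "Simulating and analyzing the go/no-go nose-poke threshold task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing the go/no-go nose-poke threshold task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

## The task and why it is simulated

Intracortical microstimulation (ICMS) of somatosensory cortex evokes
artificial tactile percepts, and the charge needed to evoke them — the
perception threshold — drifts over the lifetime of an implant. Tracking
that drift in rats requires a behavioral readout. The paradigm implemented
here is a food-rewarded go/no-go nose-poke task: on a *stimulus trial* the
rat receives an ICMS pulse train (or, for auditory controls, a pure tone)
and earns a sugar pellet by poking its nose through a sensor hole within a
hit window; on a *catch trial* nothing is presented and the correct
behavior is to withhold. Incorrect pokes earn a mild air puff and a
red-light timeout. After staged training, a threshold-detection phase
varies the stimulus intensity with a modified up/down staircase, and the
perception threshold is estimated from the resulting quantal (hit/miss)
dose–response data.

`gonogo` implements every rule of that paradigm as testable code and closes
the loop with a simulated rat, so that the session logic, the metrics and
the threshold estimator can be validated end-to-end — including parameter
recovery against a known ground truth, something physical animals cannot
provide. The same analysis path accepts externally recorded trial tables.

## Stimuli and intensity scales

An ICMS stimulus is a current-controlled, charge-balanced symmetric
biphasic pulse train with a cathodal-leading phase. Defaults: 320 Hz pulse
rate, 200 µs per phase, 40 µs interphase interval, 650 ms train duration,
delivered across 10 electrode sites simultaneously. Intensity is expressed
as charge per phase, $Q = I \cdot PW$ (nC/ph), so the 0–25 µA amplitude
range maps to 0–5 nC/ph, and 5 nC/ph is enforced as a safety ceiling.
`make_pulse_train()` expands a spec into onset times (208 pulses for the
defaults, `floor(duration × rate)` — a partial final period emits no pulse,
guaranteeing the train fits its stated duration) and a per-pulse phase
template whose signed charges sum to zero.

The auditory control stimulus is a 6 kHz pure tone, 500 ms long with 50 ms
linear onset/offset ramps (the simplest ramp consistent with a stated ramp
duration), sampled at 100 kHz. Its intensity scale is the sinusoidal
amplitude normalized to 0–100 %, where 100 % is the training tone
(measured at ~90 dB SPL on the rig this package models) and 0 % is silence.
`amplitude_percent_to_db()` reports this scale in dB SPL under the
convention $90 + 20\log_{10}(p/100)$; it is a reporting utility only — no
computation in the package depends on a dB mapping, and other conventions
exist.

## Session schedules

Training proceeds in tiers. **Shaping** rewards any effective poke during
an indefinite green-light window, teaching the poke itself; proficiency is
≥ 100 pellets with no manual dispenses in two consecutive sessions.
**Shape2Detect** introduces the stimulus/catch distinction with parameters
that change over the hour (`shape2detect_schedule()`): trial windows grow
from 3 s to 6 s, the stimulus-trial probability falls from 83.3 % to 50 %
(frequent stimuli early to build the association, fewer later to force
discrimination), and hit windows and timeouts vary per segment. The
probabilities are stored as the printed fractions (0.833, 0.714, 0.667,
0.600, 0.500) rather than re-derived odds. **Detection** fixes the
parameters at the final Shape2Detect values — 6 s window, 50 % stimulus
probability, 3 s hit window, 8 s timeout — to maximize accuracy at a
constant pace.

Segment boundaries are half-open on integer minutes, `[start, end + 1)`,
matching the printed ranges, and lookups are right-continuous (minute 10
uses the 10–19 row). The trial-parameter table ends its last segment at
"40–60" while the step-size table splits "40–49" and "50–60"; both
granularities are kept verbatim in their respective tables, with minute 60
meaning end-of-session in both.

The **threshold-detection** task keeps the Detection constants (they are
not restated in the protocol, and Detection immediately precedes it) and
changes only the trial mixture: minutes 0–19 present the naive-threshold
anchor intensity with 50 % probability (else catch); minutes 20–59 present
anchor, dynamic-staircase and catch trials with 1/3 probability each.

## The session engine

`run_session()` sequences trials on an integer-millisecond time base: a 3 s
white-light inter-trial period, then a green-light trial window whose type
is sampled from the schedule. Pokes within the first 150 ms of a trial are
voided (the lockout exists to discard accidental pokes at onset); a poke at
exactly 150 ms counts as locked out — one boundary had to be chosen, and it
is pinned by tests. The first effective poke decides the trial: within the
hit window on a stimulus-bearing trial it is a **hit** (pellet, trial
ends); in the trial remainder it is a **miss with punishment**; silence is
an unpunished **miss**. On catch trials any effective poke is a **false
alarm** (punished) and silence a **correct rejection**. Both kinds of miss
count identically in the metrics.

Punishment is an air puff plus a timeout at the scheduled base duration.
The protocol adds "more time" for pokes during a timeout without
quantifying it; here each such poke earns one additional air puff and
resets the remaining timeout to the full base duration — the simplest rule
consistent with the escalation intent (`run_timeout()` is pure and
hand-traceable). A punished poke ends the trial at the moment of
punishment. Ten consecutive unanswered stimulus-bearing trials pause the
session until the next poke; catch trials neither advance nor reset that
counter (the protocol counts "stimulus trials in a row"). For a simulated
observer the pause wait is drawn from an exponential with the observer's
spontaneous-poke hazard (guess rate per trial window); an observer that
never pokes stays paused to the end of the session.

Each session runs from one seeded RNG stream, recorded in the log, so a
(config, seed) pair reproduces every byte of output. Logs serialize as a
per-trial CSV plus a JSON-lines event file whose header echoes the
configuration and the observer's ground truth (`write_session_log()` /
`read_session_log()` round-trip exactly; replaying logged pokes through
`classify_response()` reproduces the recorded outcomes).

## The simulated observer

`observer_model()` converts a presented intensity into poke behavior
through

$$p(x) \;=\; \gamma + (1 - \gamma - \lambda)\,
\frac{x^{s}}{\mathrm{ED50}^{s} + x^{s}},$$

a Hill psychometric function with guess rate $\gamma$ (the floor, driving
false alarms), lapse rate $\lambda$ (the ceiling deficit), and slope $s$.
Detected stimuli produce a poke at onset plus a truncated-normal latency on
(0, hit window] (default 800 ± 300 ms), which keeps detection pokes inside
the hit window; late-poke misses arise from spontaneous pokes, which occur
with probability $\gamma$ on catch trials and on undetected stimulus
trials, uniformly over the trial window (at most one — the first poke
decides the outcome anyway). A per-trial Bernoulli distraction flag
(default 2 %) emulates the experimenter's "animal was grooming/turned
away" annotation and is excluded from all metrics downstream. `slope = Inf`
yields a deterministic step observer (detects iff intensity ≥ ED50), used
for hand-traceable staircase tests.

Defaults are chosen once to emulate a trained animal: ED50 1.6 nC/ph (the
scale of published ICMS thresholds with multi-channel stimulation),
$\gamma = \lambda = 0.05$, and $s = 6$, which places detection at a
3 nC/ph naive training intensity near 93–95 % — the hit-rate regime a
proficient animal shows — while leaving genuine uncertainty near
threshold. Shaping behavior (an indefinite window with no stimulus, about
which the detection model says nothing) is modeled as 150 ms plus an
exponential exploration latency with a 15 s mean, enough for an engaged
animal to clear the 100-pellet gate in an hour.

**What the simulation does not emulate:** learning across sessions,
satiety and motivation drift within a session, day-to-day sensitivity
changes, and electrode-tissue changes. Session-to-session threshold
variability therefore comes only from trial sampling noise, which makes
simulated session ED50s more consistent than real animals'. Passing tests
validate the task logic and the estimator, not rat biology.

## Staircase and threshold estimation

The staircase starts at the naive threshold — the intensity that evoked an
observable physical response (e.g., paw withdrawal) after implantation,
3–4 nC/ph in practice, or the 100 % training tone — and steps the dynamic
intensity down after each dynamic-trial hit and up after each miss, with
the step drawn from the scheduled segment (central value ± uniform jitter;
jitter can be disabled for deterministic traces). The intensity is clamped
to [0, anchor]: the anchor is the stated starting "maximum", and a step
larger than the remaining headroom saturates at the clamp rather than
redrawing. Anchor-trial outcomes never move the staircase — anchors serve
as engagement probes. Before minute 20 there is no variation and the
staircase is frozen.

For estimation, dynamic trials (only — anchors are excluded) are binned
into half-open intensity bins of 0.5 nC/ph (ICMS) or 1 % amplitude
(auditory), labeled at the bin center, with percent hit rate and trial
count per bin. `fit_quantal()` then fits

$$y = \frac{100 \, x^{s}}{\mathrm{ED50}^{s} + x^{s}}$$

to the binned percentages by unweighted least squares — matching the
described regression procedure; per-bin $n$ is retained in the output for
users who prefer to re-fit weighted — with one ED50 per session and a
single Hill slope shared across all of an animal's sessions. ED50 > 0 is
enforced by fitting on the log scale; the slope is bounded to [0.1, 20].
The optimizer is bounded Levenberg–Marquardt with a 3 × 3 multi-start grid
over initial slope and ED50 (tolerances 1e-10); tests verify it against an
independent grid-search minimizer. Sessions whose points are all 0 % or
all 100 % (or a single dose) are non-identifiable and are dropped with a
warning rather than failing the animal-level report. The animal's
perception threshold is reported as mean ± SEM of the session ED50s, with
five threshold sessions as the reference design.

## Performance metrics

Per session, with hits H, misses M, false alarms FA and correct rejections
CR (distracted trials excluded before counting):

* accuracy $(H+CR)/(H+M+FA+CR)$, precision $H/(H+FA)$, hit rate $H/(H+M)$,
  correct-rejection rate $CR/(CR+FA)$, F1 the harmonic mean of precision
  and hit rate;
* $d' = z(\text{hit rate}) - z(\text{false-alarm rate})$ with $z$ the
  standard-normal quantile and false-alarm rate $FA/(FA+CR)$. The printed
  source formula for $d'$ is typographically garbled; the standard
  signal-detection definition is used, which contains exactly the terms
  the garbled text lists.

A zero in any cell would put 0 or 1 into a rate and $\pm\infty$ into $d'$,
so the paired zero-count correction is applied first: within each pair
(H/M; FA/CR) a zero member becomes 0.5 and its counterpart gives up 0.5,
preserving pair sums — 119 hits / 0 misses becomes 118.5 / 0.5. Both
members zero means no trials of that kind were run, which is an error, not
a correctable session.

Proficiency gates: Shape2Detect requires accuracy, precision and hit rate
≥ 75 % plus ≥ 100 pellets in two consecutive sessions; Detection requires
all five fraction metrics ≥ 75 % and $d' \ge 1.5$ in three total sessions.

## Numerical choices and degenerate inputs

* Time base: integer milliseconds; observer poke times are quantized to
  the grid before classification so logs replay exactly.
* Lockout boundary closed (150 ms is locked out); hit-window boundary
  closed (a poke exactly at the hit window rewards).
* Bin edges half-open $[kw, (k+1)w)$; a trial exactly on an edge belongs
  to the upper bin. Clamped presentations at 0 or at the anchor fall in
  the corresponding edge bins.
* `step_size()` before minute 20 raises a classed condition
  (`gonogo_no_variation`) rather than returning a sentinel value.
* Hill evaluation uses $x = 0 \Rightarrow y = 0$ explicitly and the ratio
  form $r/(1+r)$ for numerical stability at extreme slopes.

## Problem sizes used in the shipped tests

The suite exercises full 60-min sessions (~300–550 trials each): single
sessions for engine invariants, 3–5 sessions for metrics and fitting, and
a 50-replicate × 5-session parameter-recovery study (~250 sessions) for
the end-to-end pipeline — sizes chosen to match the reference design of
five threshold sessions per animal while keeping the suite fast enough to
run routinely.

## Known limitations

* The observer is stationary; training acquisition, motivation and
  session-to-session drift are out of scope, so simulated between-session
  ED50 spread is tighter than published animal data.
* The estimator, like the procedure it reproduces, fits a pure Hill curve
  through 0 % and 100 % with no guess/lapse asymptotes. With a guessing,
  lapsing observer this leaves a small structural downward bias in ED50
  (about 1–2 % of truth at the default parameters): spontaneous pokes
  inflate low-dose hit rates and the model has no floor parameter to
  absorb them. Re-fitting the exported dose–response tables with a
  guess/lapse-aware psychometric model is straightforward if that bias
  matters for an application.
* With five sessions per animal, a ±2·SEM interval on the threshold has
  the coverage of a $t_4$ interval (~88 %), not a normal one; dispersion
  across sessions is reported so users can apply whichever interval they
  need.
* Hardware control (solenoids, dispensers, commutators, video, GUI) and
  electrochemical characterization are out of scope; light changes and
  air puffs exist as symbolic log events only.
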