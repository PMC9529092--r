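---
title: "Methods: the numeral-comparison DDM and its confidence readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the numeral-comparison DDM and its confidence readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numddm)
```

## The model

A comparison trial presents two numerals of one type (positive digits,
negative digits, or fractions 1/n) and asks for the larger. `numddm` models
the decision as a one-dimensional diffusion: a decision variable starts at
a Uniform(−IC, IC) draw, moves with drift

\[ v(d) = \mathrm{DR} \cdot d^{\mathrm{SYM}}, \qquad
   d = \log(\mathrm{num}_A) - \log(\mathrm{num}_B), \]

and unit-variance Gaussian noise, and is absorbed at symmetric bounds
\(\pm \mathrm{BO}\). The upper bound codes the objectively correct option,
so hitting it produces a correct response. Response time is the absorption
time plus a constant non-decision time NDT covering encoding (detecting the
numeral type, stripping a minus sign) and motor output. The model assumes
decision and non-decision stages are independent and sequential — a single
decision variable, no multi-stage accumulation — and that a trial ending
after the 3 s deadline is a timeout rather than a choice.

Distance enters on the logarithmic scale because log distance both matches
the compressive mental number line and gives each canonical digit pair a
unique difficulty; `bic_distance_comparison()` lets users check the log
versus linear question on any trial table.

### Parameters

| parameter | units | role | typical value (positive digits) |
|---|---|---|---|
| DR | evidence/s | drift at unit log distance | 2.46 |
| SYM | — | distance-compression exponent in [0, 1]; 0 cancels the distance effect | 0.09 |
| BO | evidence | bound magnitude | 0.77 |
| IC | evidence | half-width of uniform starting-point jitter; IC < BO | 0.22 |
| NDT | s | non-decision time | 0.41 |
| UN | evidence | inference uncertainty of the confidence readout; never fitted | 2.5 |

Diffusion noise is fixed at 1 evidence unit per √s. The DDM's scale is not
identified unless one parameter is pinned, and noise is the conventional
choice; all magnitudes above are relative to that convention, so they are
comparable across fits made by this package but not necessarily to fits
made under other conventions. `ddm_reference_params()` stores mean
parameters (and between-subject standard deviations) for three experiments
× three numeral types; they are the defaults of the cohort generator and
the generating values of the recovery studies.

Two conventions are worth stating because reported IC values are only
comparable under one of them: IC is the *half-width* of the uniform
starting-point distribution (support 2·IC), and the decision-variable mean
dv̄ is the arithmetic mean of the post-step samples up to and including the
bound-crossing sample, with n equal to the number of 1 ms steps; the
starting point is not counted as a sample. Results are qualitatively
unchanged if the crossing sample is dropped.

## The confidence readout

With a normal likelihood for the evidence samples and a flat (improper)
prior on their mean, the posterior over the mean decision variable after n
samples is Normal(dv̄, UN/√n). Since positive values code the correct
option, confidence at the moment of choice is

\[ \Pr(\mu_{dv} > 0 \mid \text{trace}) = \Phi\!\left(\frac{\bar{dv}\,\sqrt{n}}{\mathrm{UN}}\right). \]

Confidence is relative to the *objectively correct* side: error trials
typically have dv̄ < 0 and confidence below 0.5. UN does not influence the
decision process or the likelihood; it is a free readout parameter.
`un_presets()` exposes two assignments per experiment: `"equal"` (the same
UN for every numeral type) and `"different"` (a lower UN for positive
numerals, i.e. more information per sample).

This readout makes confidence *increase* with decision time at fixed dv̄:
more samples shrink the posterior sd. Under equal UN the faster positive
trials therefore end *less* confident than negative trials — the ordering
the package's confidence-ordering study (`confidence_ordering_study()`)
reproduces with sign consistency across replicate cohorts. The `"different"`
preset moves the positive-minus-negative contrast upward by about
+0.03, but under this package's conventions it does not cross zero: the
negative type's typical \(\bar{dv}\sqrt{n}\) exceeds the positive type's by
a factor of about 1.4, which almost exactly cancels the preset UN ratio
2.4/1.65 ≈ 1.45. Whether the ordering fully flips depends on conventions
the readout is sensitive to — above all the sampling rate that defines n
(we count samples at 1 kHz; scanning readout intervals from 1 to 50 ms
never produced a robust flip) and the exact per-participant parameter sets.
We report the contrast movement as the robust result and flag the full
reversal as convention-dependent.

## Fitting

`ddm_fit()` estimates (DR, SYM, BO, IC, NDT) per participant × numeral type
by maximizing the joint choice/RT likelihood. The likelihood backbone is a
Crank–Nicolson finite-difference solution of the forward Fokker–Planck
equation with absorbing bounds: correct responses are scored against the
upper-bound defective density, errors against the lower-bound density, each
evaluated at rt − NDT by linear interpolation in time.

Numerical choices:

* **Grid.** 121 interior space nodes (forced odd so 0 is a node) and 5 ms
  time steps out to the slowest observed response. Against the closed-form
  hit probability \(1/(1+e^{-2vB})\) the integrated upper density is
  accurate to ~1e−5 across the relevant parameter range.
* **Mass accounting.** The absorbed probability per time step comes from
  the discrete mass balance, so upper mass + lower mass + survivor equals
  the initial mass to machine precision; the split between bounds follows
  second-order one-sided approximations of the diffusive boundary fluxes.
  (First-order fluxes leave O(dx) errors of ~2e−3 in the split.)
* **Floors.** Densities below 1e−10 — including response times below the
  candidate NDT — contribute −log(1e−10), keeping the objective finite
  everywhere in the search box.
* **Search.** Box constraints DR ∈ [0.2, 8], SYM ∈ [0, 1], BO ∈ [0.3, 4],
  NDT ∈ [0.05, 1.5] s; IC is parameterized as a fraction of BO in
  [0, 0.95] so the starting distribution stays strictly inside the bounds.
  Optimization is differential evolution (rand/1/bin, population 15 × 5
  parameters, F = 0.8, CR = 0.9, stop when the population's objective
  spread falls below 1e−6 of its mean or after 60 generations) followed by
  a Nelder–Mead polish clamped to the box. Everything is seeded, so fits
  are bit-for-bit reproducible from (data, bounds, seed).
* **Degenerate cells.** `fit_participants()` flags rather than fits cells
  with accuracy below 55% or more than 15% timeouts — performance levels
  that would exclude a participant from a single-digit comparison study.

The self-consistency standard is parameter recovery: simulate a 720-trial
single-type session (72 per canonical distance) at the reference means and
refit. Median recovered DR, BO and NDT over three seeds land within a few
percent (DR, BO) and a few milliseconds (NDT) of the generating values for
both the positive and negative parameter sets; SYM and IC are only weakly
identified at this sample size, which is why the acceptance checks target
DR, BO and NDT. Recovery deliberately skips the 2-SD slow-RT exclusion:
truncating the right tail of data whose generating process is known biases
the drift estimate upward by ~19%, because the truncated sample genuinely
looks faster. The exclusion rule belongs in pipelines for empirical data
(where `run_pipeline()` applies it, losing the expected few percent of
trials under realistic right-skewed RT distributions).

## Simulation accuracy

The trial simulator is an Euler–Maruyama walk at dt = 1 ms (3 s deadline ⇒
at most ~3000 steps). A discrete-time walk systematically overshoots
absorbing boundaries, behaving like a continuum diffusion with bounds
displaced outward by ≈ 0.5826·σ·√dt (Siegmund's continuity correction), so
the simulator absorbs at BO − 0.5826·σ·√dt by default. With the correction,
simulated accuracy and mean decision time agree with the closed forms
\(1/(1+e^{-2vB})\) and \((B/v)\tanh(vB)\) within Monte-Carlo error at 1e4
trials per condition; without it, mean decision times are measurably
biased. Oracle-equivalence checks in the test suite use a finer dt (0.5 ms)
and a long deadline so that deadline censoring does not contaminate the
comparison with the deadline-free closed forms.

## The synthetic cohort

`generate_cohort()` emulates the study conditions end to end: per-type
parameters drawn for each participant from independent truncated normals
around the reference means and sds (no covariance structure — only marginal
moments are available); the full designs (ten canonical pairs × three
types × 24 repeats + 150 dummy trials for the first experiment; 12 + 75 for
the second; random 2–8 pairs for the third); side randomization; the 3 s
deadline; and confidence and button pressure per trial. Dummy trials use
digits 2–15 (including 9 and double digits, which mask the design), are
simulated like any other trial, and are flagged out of every analysis.

No validated transfer function from confidence to button pressure exists,
so the generator makes one explicit: raw pressure =
clip(300 + 400·confidence + N(0, 80), 0, 1023) on the force-sensor scale,
then normalized to each subject's per-side session maximum. The defaults
make normalized pressure span roughly 0.03–1, the kind of range real force
sensors produce; gain 0 is the null model under which all three confidence
signatures must fail, which is exactly what the specificity tests check.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: sequential effects (post-error slowing,
feedback carry-over), parameter correlations across types within a
participant, task-order effects, attention or familiarity contributions to
pressure, and any non-monotone or saturating pressure transfer. The
signature diagnostics use OLS with per-subject intercepts rather than
random-effects panel estimators with robust covariance; they answer sign
and monotonicity questions, not coefficient-magnitude questions.

## Diagnostics

`confidence_signatures()` bundles the three checks with deterministic
conventions: ten equal-count quantile bins of the proxy by default;
within-subject median splits with ties assigned to the low half; the
correct-versus-error contrast controls for log distance and is flagged "not
evaluable" when errors appear at fewer than three distances (a real
limitation at ceiling accuracy). `normative_illustration()` shows the same
three properties in a task-agnostic generative model — discriminability
uniform on (0, 1), percept Gaussian around the true signed discriminability
(sd 0.3 by default), confidence the exact posterior given the percept — to
make clear the signatures follow from the statistical definition of
confidence, not from the DDM.

## Problem sizes

The test suite and acceptance script run at the study scale where the check
demands it and smaller where it does not: recovery at the full 720 trials ×
3 seeds per numeral type; oracle equivalence at 1e4 trials per grid point
over 12 (drift, bound) points; the ordering study at 150 simulations per
distance × 50 heterogeneous subjects × 20 replicate cohorts; signature
checks on a 50-subject cohort with the full 870-trial design; smoke-level
pipeline runs at 2 subjects with reduced optimizer budgets.

## Known limitations

Fitted magnitudes are convention-bound (noise = 1, IC as half-width, n at
1 kHz); the full confidence-ordering reversal under the `"different"` UN
preset is convention-sensitive, as discussed above; SYM and IC are weakly
identified from 720 trials; the likelihood ignores deadline censoring
(timeouts are excluded rather than modelled, defensible at the <1% timeout
rates these parameters produce); and collapsing bounds, evidence leakage,
and across-trial drift variability are out of the model family by design.
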