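---
title: "Force-ramp analysis of tip-link protein unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-ramp analysis of tip-link protein unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampfold)
```

## The measurement and the model

In an optical-trap force-ramp experiment on a modular protein such as the
inner-ear tip-link cadherin PCDH15, force on the molecule is raised at a
constant loading rate from a 1 pN resting level to a peak, lowered at the
same rate, and held for 2 s before the next cycle. The end-to-end extension
recorded during each cycle reflects two elastic regimes: at low force the
molecule straightens thermal undulations and unstructured segments (entropic
elasticity); at high force, once those degrees of freedom are exhausted, it
stretches as a nearly linear (enthalpic, Hookean) spring. Discrete unfolding
of a linker region, part of a domain, or a whole extracellular-cadherin (EC)
domain appears as a sudden step in the extension.

rampfold describes a trajectory segment with a saturation model augmented by
a linear-spring term,

$$x(F) = \frac{x_E}{1 + F_{1/2}/F} + \frac{F}{K},$$

where $x_E$ (nm) is the maximal entropic extension, $F_{1/2}$ (pN) the force
at which entropic extension is half complete, and $K$ (pN/nm) the enthalpic
stiffness. All stiffnesses are in pN/nm, numerically identical to the mN/m
customary in hair-cell mechanics. Unfolding increases $x_E$; the fitted
$x_E$ of a segment is therefore the coordinate in which conformations are
compared, clustered into states, and tracked across cycles. Two pieces of
spring calculus complete the model: stiffnesses in series compose as
$1/K_{TL} = 1/K_{PCDH15} + 1/K_{CDH23}$, and a filament of the same material
but $r$ times the contour length has stiffness $K/r$. Contour released by
unfolding is booked at 0.40 nm per residue less the folded length of the
element (4.5 nm for an EC domain), floored at zero and applied once per
unfolded element.

## What the simulator emulates

`condition_presets()` defines six study conditions — wild-type and V507D
dimers at 3 mM, 20 µM, and nominally Ca²⁺-free (EDTA) — as configurations
of a stochastic generator, since the package must be testable without the
original laboratory data. Each configuration combines:

* a **ramp protocol** (default 20 pN/s to a 60 pN peak at 1 kHz, 1 pN rest,
  2 s between cycles). The published protocol does not state its loading
  rates in the main text, so the defaults are explicit, configurable
  choices at the scale typical of optical-trap ramps;
* **base mechanics** for the folded molecule ($x_E$ = 40 nm, with
  per-condition $F_{1/2}$ and $K$ taken from the illustrative per-cycle
  fits, see `reference_fit_params()`);
* a **ladder of unfoldable units** with Bell–Evans kinetics: each
  still-folded unit unfolds in a sampling interval $dt$ with probability
  $1 - e^{-k_0 e^{F \Delta x / k_B T} dt}$, $k_B T$ = 4.11 pN·nm;
* **Gaussian measurement noise** (0.3 nm, the sub-nanometre instrument
  scale);
* **imperfect inter-cycle refolding**: during each rest, every unfolded
  unit refolds independently with its configured probability, and the fold
  state carries over when refolding fails.

The ladder has six units in a sequential cascade — two linkers (6.0 and
6.6 nm), two full domains (30 nm each), a partial domain (18 nm) and a
double-domain (72 nm) — so the accessible conformations sit on six discrete
extension levels whose spacings (≈12.6, 30, 30, 18, 72 nm) mirror the
inter-state gaps reported for the real molecule. The cascade ordering
(linkers first, then domains in order of increasing disruption) reflects
the observation that unstructured linkers come apart before structured
domains and that unfolding of one element destabilizes its neighbours.
Design choices worth knowing:

* **Linkers are nearly force-insensitive** ($\Delta x$ = 0.1 nm) so small
  events scatter across the whole force range, as observed; domain-scale
  units are force-sensitive ($\Delta x$ = 0.5 nm) and concentrate near the
  force peak. A consequence of this kinetics with a symmetric ramp is that
  relaxation-phase events are reliably *fewer* than extension-phase events
  but not systematically *smaller*: the rare domain events cluster at the
  peak and spill into early relaxation, while small linker events exhaust
  themselves during extension. Analyses should not assume smaller
  relaxation steps.
* **Linkers refold sluggishly** (probability 0.25 per rest). Sticky linkers
  keep the molecule's levels discrete: a domain-open molecule almost always
  carries its linkers open too, so no trajectory sits halfway between the
  folded pair of states and the first domain-open state.
* **The first domain carries the per-condition refold probability; deeper
  units refold with certainty.** The probability that a molecule returns
  fully to the folded states after a domain-opening excursion then equals
  one configured Bernoulli parameter per condition, which makes the
  refolding summary directly identifiable in tests. The configured values
  (wild type: 0.842 at 20 µM, 0.629 at 0 M; V507D: 0.822, 0.593, 0.240)
  are the study's reported refolding extents, used here as generator
  settings, not as assertions about the output.
* Unfolding rates $k_0$ rank the conditions: more frequent unfolding at
  lower Ca²⁺ and for the mutant, only sub-10 nm linker events for the wild
  type at 3 mM (which therefore never leaves the folded states — the
  undefined cell of the refolding table), and a double-domain state reached
  only by the mutant without Ca²⁺. The constants are documented package
  choices that reproduce those orderings; they are not measurements.

The ground-truth log of each simulated cycle records, for every event, both
the programmed contour gain and the realized extension jump
$g\,F/(F+F_{1/2})$ at the event force. The two differ at low force because
entropic saturation is incomplete; detector benchmarks use the realized
jump, which is what a step detector can see.

What the generator does *not* emulate — bead and trap Brownian dynamics,
drift, tether-linker elasticity, force noise, multiple tethers — bounds
what green tests mean: the pipeline is validated against data whose noise
is white and whose events are instantaneous. On real records the detector's
penalty and `min_step` would need verification against manual annotation.

## Event detection

`detect_events()` runs binary segmentation on each phase with an $\ell_2$
cost around a per-segment linear trend, computed in O(1) per candidate from
cumulative sums. A split is accepted when it lowers the summed squared
error by more than a penalty, by default $25\,\sigma^2 \log n$ with
$\sigma$ estimated robustly from first differences (floored at 0.05 nm so
that noiseless fixtures terminate). Step sizes are then measured as the
discontinuity between local linear fits over at most 30 samples on either
side of each change point, and only steps of at least `min_step` (default
1.5 nm, below the smallest reported event class at 1.8 nm but five times
the noise) are reported; the event force is the median force in a
±5-sample window. Change points induced by the smooth low-force curvature
of the model have near-zero fitted discontinuity and are discarded by the
size filter. Negative steps (refolding against the ramp) are kept with
negative sign and excluded from unfolding totals. On the six presets the
detector recovers ≥95% of ground-truth events at the reporting threshold
with a false-positive rate well under 5%.

## Fitting protocol

Fitting is two-stage, mirroring the convention that one enthalpic stiffness
serves all phases of a condition:

1. `enthalpic_stiffness()` estimates $K$ per condition as the mean of the
   pointwise inverse derivative of extension with respect to force above
   30 pN, per cycle phase, using a Savitzky–Golay derivative (window 21,
   order 2) on a 0.1 pN uniform force grid, then averages the per-phase
   determinations (mean ± SEM). On purely Hookean data the estimate is
   exact. On saturation-model data the entropic term leaves a residual
   compliance above the threshold, so the estimate is biased low — about
   9% for the stiff 3 mM parameters and about 16% for the softer 20 µM
   parameters at a 60 pN peak — and converges to $K$ as the threshold
   rises. This bias is a property of the published estimator itself, not
   of its implementation, and is shared by the fits it feeds.
2. `fit_segment()` then fits $x_E$ and $F_{1/2}$ to each inter-event
   segment by Levenberg–Marquardt least squares with $K$ fixed, starting
   values from the linearized form $1/(x - F/K)$ versus $1/F$. Segments
   with fewer than 10 samples or spanning less than 2 pN are rejected
   rather than reported. Within `run_pipeline()`, the first segment of
   each phase — which always spans down to the resting force and therefore
   identifies $F_{1/2}$ — anchors the half-saturation force, and later
   segments of that phase inherit it. Without sharing, a high-force-only
   segment can trade $F_{1/2}$ against $x_E$ and inflate $x_E$ by ~10 nm,
   which is enough to cross a state boundary; sharing also matches the
   published per-cycle fits, which quote a single $F_{1/2}$ for all
   segments of a phase. `fit_segment()` itself keeps both parameters free
   unless `f_half_fixed` is supplied.

## States, transitions, refolding

Conformational states are defined on the pooled relaxation-phase $x_E$
values (`define_states()`), consistent with defining states on relaxation
trajectories: by the end of extension the molecule has committed to its
most unfolded conformation of the cycle. The 1-D clustering minimizes the
within-cluster sum of squares *exactly* by dynamic programming over the
sorted values rather than by heuristic k-means: the optimum is
deterministic, order-invariant, and immune to initialization accidents in
which a sparse outlying state absorbs two centres while two dense folded
states merge — a failure mode that actually occurs on this kind of data.
States are labelled 1..6 in ascending mean $x_E$; each state's SEM is the
sample SEM of its members.

All segments (both phases) are then assigned by k-nearest-neighbour vote
(`classify_segment()`, k = 3) against the labelled relaxation values, with
both distance ties at the neighbourhood cut and vote ties broken toward the
lower state — conservative about claiming unfolding. The classifier is
exactly equivalent to brute-force kNN with the same tie rules; the test
suite checks this equivalence exhaustively.

`build_transition_map()` counts transitions between consecutive segment
ordinals within a cycle phase (extension by default, where ordinals ascend
with force) and tallies occupancy as the fraction of segments per state; a
sample-weighted occupancy is available (`time_weighted`) because "fraction
of time" could be read either way, but segment counting is the default.

`refolding_summary()` reproduces the refolding bookkeeping: a cycle
qualifies when it reaches state 3 or higher (at least one domain-scale
opening) and its immediate successor exists; it refolded fully when that
successor starts in state 1 or 2. Percentages are computed per dataset and
summarized as mean ± SEM across datasets; a condition with no qualifying
cycles is *undefined* — a value, not an error — which is how the wild type
at saturating Ca²⁺ behaves.

`entropic_stiffness_by_state()` computes, per state and 5 pN force bin, the
inverse slope of extension versus force from a local linear fit per
segment, averaged over segments. On noiseless model data this equals the
analytic $dF/dx$, which rises with force toward $K$ and falls with $x_E$,
so more-unfolded states are softer at every force. Empty bins are reported
as missing, never as zero.

## Numerical choices and degenerate inputs

* Phase splitting takes the argmax of a 5-sample median-filtered force
  signal, refined on the raw force within ±3 samples because the median
  filter flattens the triangular apex; traces whose force range is below
  1 pN have no identifiable ramp and are rejected.
* `extension_at_force()` is evaluated as $x_E F/(F + F_{1/2}) + F/K$,
  continuous at $F = 0$; inversion uses bracketed root finding on
  $[0, Kx + 1]$ (the model forces $F \le Kx$) with tolerance well below
  1e-6 pN.
* Event-size mixtures (`event_size_distribution()`) are fitted with
  unequal-variance Gaussian mixtures; component SEMs are
  $\sigma_k/\sqrt{n_k}$ with $n_k$ the summed posterior responsibility. A
  fit is flagged as overlapping when neighbouring means are closer than
  twice the combined component widths — an over-split unimodal sample
  separates its means by about one SD, so a width-based criterion flags it
  while a SEM-based one never would.
* Exactly identical inputs (zero variance) short-circuit the mixture fit
  at one component and are an error at more; k-means with fewer distinct
  values than states is an error, as is a constant-extension segment fit.
* All randomness flows through R's RNG: seeding `set.seed()` (or the
  `seed` arguments of `simulate_dataset()` / `run_pipeline()`) makes every
  simulated sample, fit and table bit-reproducible, and the run manifest
  written with a report records seed and parameters sufficient to
  reproduce it.

## Problem sizes

The default pipeline configuration analyses the six presets at 4 datasets
of 25 cycles each (100 cycles per condition, ~5,900 samples per cycle),
which the full simulate–detect–fit–classify–summarize chain completes in
well under a minute on a single core; the test suite and the acceptance
script use the same scale. Statistical checks (detection recall, refolding
recovery, loading-rate dependence) use 200–600 Monte-Carlo cycles at fixed
seeds.

## Known limitations

* The enthalpic-stiffness estimator inherits the published method's
  entropic bias (see above); comparisons across conditions are consistent
  because all conditions share the estimator.
* Event sizes are measured as extension jumps at the change point, not as
  fitted $\Delta x_E$; at forces well below $F_{1/2}$ the two differ by
  the saturation factor.
* The generator's kinetic constants are design choices reproducing
  qualitative orderings; absolute event counts and unfolding-force
  distributions are not calibrated to the laboratory data.
* Only the package's own text format is read; vendor instrument formats
  are out of scope.
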