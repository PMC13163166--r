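---
title: "Methods: multi-resolution sleep fragmentation analysis"
author: "sleepfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-resolution sleep fragmentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Sleep is scored as a sequence of stage labels — wake (W), the three
non-REM depths N1–N3, and REM (R) — over fixed windows. Clinically the
window is 30 s; automatic stagers can emit labels every 5 s
("mini-epochs"), resolving brief stage intrusions and awakenings that
30-s majority scoring absorbs. In disorders of sleep–wake stability
such as narcolepsy type 1, much of the pathology lives exactly in those
short events.

`sleepfrag` treats the staged night as a categorical time series and
quantifies its instability three ways:

1. **Transition indices.** Count the adjacent stage changes of a
   category (all stages; NREM↔REM; sleep↔wake; within NREM) and divide
   by total sleep time in hours. The unit is *transitions per hour of
   TST*, so values are comparable across subjects with different sleep
   durations. The three specific categories partition the all-stages
   count — an identity asserted by tests on every input.
2. **A discrete-time Markov chain** over the five stages. The model
   assumes the next stage depends only on the current one. The
   maximum-likelihood estimate of the transition matrix is the 5×5 step
   count matrix row-normalized by the number of steps originating in
   each stage; diagonal entries are per-step stage stability. The final
   unit of the window originates no step, which makes the normalizer
   well defined (a subject with 390 N2→N2 steps among 432 N2-origin
   steps has stability 0.90). Rows whose stage never originates a step
   are kept as explicit `NA`s — never silent zeros — and such subjects
   are excluded, per cell only, from downstream cell-wise models. For
   per-step counting, normalizing by origin steps and by time in the
   originating stage coincide up to the single boundary unit; a test
   asserts agreement within `1/origin_total`.
3. **Wake-period taxonomy** (5-s inputs only). Maximal runs of
   consecutive wake mini-epochs are classified by length: short
   (1 unit), intermediate (2–3 units), long (≥ 4 units, i.e. > 15 s),
   and counted per hour of TST. The class boundaries are defined by run
   length in mini-epochs; the conventional second-based labels ("≤5 s",
   "5–15 s", ">15 s") are treated as labels, not definitions, since a
   2-unit run literally spans 10 s.

## Conventions and their rationale

- **Coordinates.** Epoch indices are 0-based and the lights window is
  half-open `[lights_off, lights_on)`. This removes fencepost ambiguity
  from TIB and latency arithmetic: TIB is `lights_on − lights_off`
  units, a latency of `k` units is exactly `k` unit-durations.
- **Analysis window.** Every metric is computed between lights off and
  lights on. `crop_to_lights()` is idempotent.
- **Sleep onset** is the first unit scored as any sleep stage after
  lights off (AASM-style); **REM latency** runs from sleep onset, not
  lights off, matching the anchoring of the early-REM definition.
  **Early-appearing REM** (the mini-epoch analogue of a sleep-onset REM
  period) requires a REM unit beginning *strictly* less than 15 min
  after onset; a REM unit at exactly 15.0 min does not qualify.
- **Stage percentages** use scored time in bed as the denominator, so
  wake% plus the four sleep-stage percentages always total 100; with no
  unscored units this equals percent of TIB, making wake% and sleep
  efficiency complementary.
- **Unscored units** (`U`) are retained in sequences, but every
  adjacency containing a `U` is skipped and `U` never enters an
  occupancy denominator. Scoring-artifact handling has no universal
  convention; skipping is conservative, and the count-conservation
  identity (counted steps = adjacencies − skipped pairs) is tested.
- **Wake-run counting region.** Full-night wake runs are counted from
  sleep onset through the last sleep unit: pre-onset wake is sleep
  latency and terminal wake is the final awakening, neither of which is
  fragmentation. The alternative (`counting_region = "window"`) is
  exposed.
- **Split night.** The total sleep period (SPT) runs from sleep onset
  through the last sleep unit, and is divided at `floor(L/2)`, the
  second half receiving the extra unit of an odd-length SPT (any fixed
  rule would do; this one is declared for reproducibility). Halving the
  sleep period rather than the lights window keeps latency and terminal
  wake out of half-specific metrics. Within halves, wake runs are
  counted over the whole half window, because the SPT bounds already
  exclude latency and terminal wake; a run straddling the boundary is
  counted once in each half. Per-half counts plus the single boundary
  pair reproduce whole-SPT counts exactly — a tested identity.
- **Majority downsampling** (used only to derive 30-s twins of
  synthetic 5-s nights) takes the modal stage of each 6-unit window,
  breaking ties in favour of the tied stage whose last occurrence is
  latest ("last-in-window"), a deterministic, forward-continuity-biased
  rule verified against exhaustive enumeration of all two-stage
  windows.

## The statistical layer

The scientific content of the comparison layer is the model
specification, the effect-size definition, and the correction scheme;
the numerical optimization is deliberately delegated to
`lmerTest`/`lme4`.

- **Group models**: `outcome ~ group + age + sex + (1 | family_id)`.
  The family random intercept absorbs patient–sibling relatedness.
  Satterthwaite p-values; Wald 95% CIs (the CI method for mixed models
  is genuinely open — Wald is the default and is flagged in each
  result's `model_descriptor`).
- **Cohen's d** is defined as the fixed-effect coefficient divided by
  the model's residual standard deviation, and the identity
  `d = β / σ_resid` is asserted for every emitted result.
- **Repeated measures** (split-night): `outcome ~ group × half + age +
  sex + (1 | family_id) + (1 | subject_id)`, followed by four post-hoc
  contrasts — the half effect within each group (participant random
  intercept) and the group effect within each half (family random
  intercept).
- **Log-transform policy.** "Transform when residual diagnostics look
  non-normal" is mechanized as a reproducible rule: under `auto`, apply
  the natural log when the moment skewness exceeds 1 in absolute value
  and all values are strictly positive; otherwise fall back with a
  notice. Visual steps cannot live in a tested pipeline; the threshold
  is configurable and |skew| > 1 is a conventional marker of clear
  asymmetry.
- **Multiplicity.** The per-cell transition-probability grid (25 cells
  × 2 resolutions = 50 models) is corrected jointly by
  Benjamini–Hochberg at FDR 0.05 (`stats::p.adjust`; the rejection set
  is tested against an exhaustive step-up oracle). Cells with fewer
  than 10 complete observations (configurable) or a constant outcome
  are marked unfit and leave the BH family with a logged count; the
  attempted-model count is still reported. Single-outcome predictor
  analyses are exploratory and deliberately uncorrected — results
  should be read accordingly.
- **Degenerate fits.** A random-effect variance estimated at zero
  (singular fit) triggers a documented fallback to the fixed-effects
  model rather than a failure; constant outcomes and rank-deficient
  designs raise errors naming the offending columns.

## The synthetic cohort generator

Real polysomnography cohorts are rarely shareable, so the generator is
a first-class, tested module, not a fixture. Its design principle:
**inject effects on the transition-matrix scale, never on the index
scale**, so every downstream statistic is an emergent consequence that
can honestly fail.

Per subject: the group's half-specific preset matrices are personalized
by Dirichlet row perturbation (concentration `κ·p_row`, default
κ = 400, giving per-cell SDs of roughly `sqrt(p(1−p)/401)`); wake-entry
probabilities (the W column of the four sleep-origin rows) are scaled
by a family-shared lognormal multiplier (σ = 0.2) and the rows
renormalized; a 5-s night of 5760 units (~8 h) is sampled stepwise —
first-half matrix up to the midpoint, second-half matrix after — then
framed by fixed wake padding (5 min before, 2 min after) inside the
lights window; early REM is injected with per-group probability
(patients 0.60, siblings 0.14, the observed prevalences of
early-appearing REM in mini-epochs in the motivating cohort); and the
30-s twin is derived by majority downsampling. Uniform variates are
drawn from R's RNG, so a single seed makes cohorts bit-reproducible;
the compiled sampler only consumes them.

The preset matrices themselves are **synthetic and
plausibility-tuned**, not calibrated to any published matrix (none is
public): diagonal dominance appropriate to 5-s steps, wake stability
0.75 so that wake runs fall in roughly equal thirds of the
short/intermediate/long taxonomy, sibling wake-entry rates giving a
sleep–wake index near 17/h and patient rates near 33/h in mini-epochs,
with the patient wake-entry further elevated (~1.5×) in the second
half. Siblings use one matrix for both halves. The `"null"` preset
gives both groups the sibling matrix — no group or half effect — and is
what the calibration tests run on.

What the generator does **not** emulate: independent human 30-s
scoring (the twin is a deterministic function of the 5-s night),
scorer disagreement and artifact/unscored segments, ultradian sleep
cycles and non-geometric bout-length distributions (a first-order
chain has geometric dwell times), circadian drift beyond the single
matrix switch, and any EEG-level structure. Passing tests therefore
demonstrate that the pipeline measures what it claims on data obeying
its own model assumptions — parameter recovery, calibration, and
direction of injected effects — not that real nights satisfy those
assumptions.

## Numerical choices

- Transition-matrix rows with zero origin totals propagate as `NA` and
  are excluded per cell downstream; nothing is imputed.
- `stationary_distribution()` uses power iteration to tolerance 1e-12;
  tests cross-check it against an eigen-decomposition oracle.
- Matrix order is fixed as (W, N1, N2, N3, R) everywhere, including
  file output.
- Pipeline outputs are written with fixed formatting; rerunning with
  the same configuration and seed reproduces every CSV byte for byte.

## Validation problem sizes

The test suite validates at sizes chosen to make Monte-Carlo noise
small relative to the asserted bounds: brute-force oracle equivalence
on 500 random sequences of ≤ 100 units; matrix recovery on
50,000-step chains (max-abs error < 0.02); type-I error of the
full generate → features → LME path on 200 null cohorts of 30 + 30
subjects with 720-unit nights (accepted band 0.02–0.08 at α = 0.05);
BH behaviour on 20 null cohorts' 50-model grids; and the qualitative
signature checks on one full-scale preset cohort (125 + 100 subjects,
5760-unit nights). The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

- The Markov model is first-order and time-homogeneous within each
  night-half; dwell-time (semi-Markov) structure is not modelled.
- Wake-period counts are not arousal scoring and make no claim of
  equivalence to cortical arousals.
- The EDF+ annotation import is not implemented; the canonical CSV
  dialect (or any converter into it) is the supported path.
- Mixed-model p-values rely on Satterthwaite approximations; for very
  small cohorts a permutation approach would be preferable.
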