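---
title: "Temporal speech parameters: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal speech parameters: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtsp)
```

## The measurement model

Spontaneous speech carries a temporal signature: how fast phones are
articulated, how often the speaker pauses, for how long, and whether the
pauses are silent or filled (hesitation vocalizations such as "umm").
These quantities are sensitive to cognitive load and planning effort, and
altered pause behaviour is a recurring finding in mild cognitive
impairment, dementia and — the case-control setting this package grew out
of — alcohol use disorder (AUD), where subtle cognitive decline often
escapes brief screens like the MMSE.

The raw observation is a *time-aligned token sequence*: a phone-level
recognizer (or a manual Praat annotation) assigns every phone-like unit,
silence and hesitation a start and end time. `speechtsp` represents this
as a `speech_timeline` and reduces it to fifteen **temporal speech
parameters** (TSPs). With $n_p$ phones, $n_s$ silent and $n_f$ filled
pauses, total pause times $P_s, P_f$ and utterance length $U$ (last token
end minus first token start, in seconds):

* utterance length $U$;
* articulation tempo $n_p / (U - P_s - P_f)$ and speech tempo $n_p / U$
  (phones/s — excluding vs. including pause time);
* occurrence rate $100\, n_x / n_p$ (pauses per 100 phones),
* duration rate $100\, P_x / U$ (% of utterance time spent pausing),
* frequency $n_x / U$ (pauses per second), and
* average duration $P_x / n_x$ (s),

each of the last four computed for the silent, filled and total pause
scopes. Average durations of an absent pause category are *missing*, not
zero: coding a pause-free speaker as zero would drag group means toward
zero, which is exactly the direction of the case-control effects under
study.

A pause category is never guessed from a label string: a `label_map`
binds the recognizer's symbol inventory (e.g. `sil`, `fp`, `hes`) to the
three categories, and everything downstream is category-based.

## Normalization choices

Recognizer output needs light post-processing before the formulas above
are meaningful. `normalize_timeline()` applies four rules, in order:
unlabeled gaps become silent pauses (a phone-level recognizer is
exhaustive, so gaps only arise in third-party alignments); adjacent
silent pauses are merged; leading/trailing silence is deleted
(`trim_edges = TRUE` by default — lead-in silence is a property of the
recording session, not of speech planning, and it would otherwise
inflate utterance length and dilute every rate); and internal silent
pauses shorter than `min_pause_s` leave the pause inventory while their
span continues to count as articulation time. The default
`min_pause_s = 0.03` s reflects that an interval of one analysis hop
(10 ms) or two is below the temporal resolution at which a recognizer
can assert a genuine planning pause. Both knobs are configuration, not
doctrine: field conventions for minimal pause duration range from 30 ms
to 250 ms, and the choice changes utterance length, so it is recorded in
every provenance log. Normalization is idempotent, and `compute_tsp()`
refuses unnormalized timelines rather than silently producing
incomparable numbers.

## The synthetic cohort generator

No public corpus accompanies the case-control setting the package
targets, so the generator is a first-class module: it emulates a control
group (n = 31) and an AUD group (n = 34) whose TSP distributions match
published group means and SDs, and it doubles as a sharp oracle for the
feature engine.

**Constructive parameterization.** Rather than rejection-sampling whole
timelines, each subject is a small vector of free parameters — utterance
length, articulation tempo, a pause-count intensity and a mean pause
duration per scope — from which `construct_timeline()` builds a timeline
deterministically: equal-duration phones with the sampled pauses placed
at distinct internal phone boundaries. `compute_tsp()` inverts this
construction exactly (to floating point), which the tests exploit as a
round-trip identity.

**Sampling laws.** Utterance length and articulation tempo are truncated
normals over physiological ranges (15–600 s, 6–25 phones/s). The
underlying location and scale are solved numerically so that the
*truncated* distribution has the target mean and SD — with a target mean
roughly two SDs from a bound, the naive choice would bias the mean by
more than a second. Pause counts are gamma-mixed Poisson: the subject
draws a latent rate (pauses per 100 phones) from a gamma law, counts are
then Poisson with intensity rate/100 × phone count; the latent SD is
deflated so latent-plus-Poisson variance matches the target
occurrence-rate SD. Pause durations are log-normal around a log-normal
subject-level mean with within-subject coefficient of variation 0.6 (a
moderate value for within-speaker pause-duration spread; it affects no
group mean), the subject-level SD again deflated so the *subject-average
duration* has the target SD.

**Unbiasedness ordering.** The phone count is fixed from the
self-consistency equation
$n_p = \mathrm{AT}\cdot U / (1 + \mathrm{AT}\,(r_s d_s + r_f d_f)/100)$
*before* the Poisson counts are drawn, and the utterance length is then
re-derived as $n_p/\mathrm{AT} + \text{realized pause time}$. Drawing
counts first and deriving the phone count afterwards looks equivalent
but is not: the occurrence rate becomes a ratio of correlated variables
and picks up a Jensen-type bias of order +2%, which is large relative to
the Monte-Carlo error the calibration tests resolve. With the chosen
ordering, articulation tempo, occurrence rates and average durations are
exactly unbiased, and utterance length is unbiased up to phone-count
rounding.

**Count–duration coupling.** The published group moments are *jointly
incompatible with independent free parameters*. Per subject the identity
$$\text{duration rate}_x = \text{occurrence rate}_x \times
  \text{average duration}_x \times \text{speech tempo} / 100$$
holds exactly, so the group mean of a duration rate pins
$E[r_x d_x]$; for the AUD filled-pause scope the required value exceeds
what independence provides by ~26%, and even perfect correlation cannot
fully reach it. Each scope therefore couples its count intensity and
mean duration through a Gaussian copula whose correlation is solved in
closed form from the scope's duration-rate target and clipped to
[−0.95, 0.95] (the AUD filled scope sits at the clip; its simulated
duration-rate mean consequently runs ~5% low, the one place where the
printed moments cannot be met by any joint distribution). Beyond this
calibrated within-scope coupling the free parameters are independent —
the marginals are all a summary table identifies, and independence is
the declared default rather than a hidden assumption.

**Reproducibility.** A cohort is seeded once; each subject derives a
substream seed by stable hashing of (seed, group, index), so adding,
removing or reordering subjects never perturbs another subject's draw.

What the generator does *not* emulate: lexical content, within-utterance
tempo drift, serial correlation between successive pauses, recognizer
segmentation errors, or any correlation among free parameters beyond the
calibrated count–duration coupling. Passing calibration tests therefore
show that the *analysis chain* behaves correctly on data with the
published first and second moments — not that real AUD speech is
generated faithfully.

## The statistical chain

`compare_all()` reproduces the conventional case-control reporting
chain, in two modes.

*Raw mode* (per-subject feature table): each variable passes a normality
gate — Shapiro–Wilk by default, Lilliefors-corrected Kolmogorov–Smirnov
as a configured alternative, never mixed silently — failing which the
tie-corrected Mann–Whitney U is used. Normal variables then pass a
variance gate (Levene's test, mean-centered, α = 0.05) choosing between
the pooled t and Welch's t.

*Summary mode* (n/mean/SD per group): raw-data gates are unavailable, so
the variance gate is a two-sided F test on the summary variances at the
same α. On the reference summary table this reproduces the published
pooled/Welch split on all fifteen rows, which is the evidence that the
original analysis used an equality-of-variances gate of this kind.

Two sign conventions coexist in the field's tables and are both kept,
prominently documented: t statistics are reported as control minus case
(control listed first), while Cohen's d is case minus control (elevated
in cases ⇒ positive d). The consistency identity
$|t| = |d|\sqrt{n_1 n_2 / N}$ ties them together and is asserted in the
tests. The Mann–Whitney z uses the tie-corrected variance without
continuity correction — the convention of the major statistical packages
at these sample sizes; an exact-U p-value is available for small
tie-free samples via `exact_limit`.

`prune_correlated()` makes the pre-ROC variable screen explicit: Pearson
correlations on pairwise-complete observations, a greedy scan in a
relevance order, dropping any variable correlated above 0.9 (default)
with an already-kept one. "Most relevant" is operationalized as
descending |Cohen's d| unless the caller supplies an order — the
high-effect variables are what such screens are run to protect, and an
explicit order makes the screen deterministic and auditable. The kept
set is always data-driven output, never a hard-coded list; constant
columns, whose correlations are undefined, are set aside rather than
silently kept or dropped.

## ROC analysis

Each kept variable is evaluated alone (no multivariable classifier —
matching the univariate design this reproduces). The AUC is the
Mann–Whitney probability estimator (ties count one half), computed via
midranks and verified against all-pairs counting in the tests. Its
standard error is Hanley–McNeil's closed form with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$ — the standard nonparametric default;
the estimator behind published AUC "SD" columns is typically unstated,
so agreement is expected in magnitude, not digits. Significance is a
two-sided normal test of AUC = 0.5, gated by Bonferroni at α/m with m
the kept-set size.

Orientation is derived per variable from the group means (case mean
higher ⇒ higher values call the case class), not hard-coded, so
variables depressed in cases (speech tempo) and elevated in cases (pause
loads) are handled symmetrically. Cut-points are the midpoints between
consecutive distinct scores plus ∓∞ sentinels — the "coordinates of the
curve" convention — maximizing Youden's J = sensitivity + specificity −
1; ties prefer higher sensitivity (a screening instrument's priority),
then the lower cut-off. Degenerate inputs (a single distinct score)
return J = 0 with a warning rather than an arbitrary threshold.

## Numerical and interface details

* Token times are validated to be strictly increasing with non-positive
  durations rejected; overlaps are reported with token indices. CTM
  serialization rounds start and end to 3 decimals *before* differencing
  so that written tokens still tile exactly.
* TextGrid reading supports the long and short text formats, interval
  tiers only; empty interval labels are silent pauses by phonetic
  convention, filled pauses must be explicit mapped labels.
* Welch df is computed from summary variances; it always lies in
  [min(n)−1, N−2] and collapses to the pooled df for equal n and SD.
* `bonferroni()` returns the exact threshold with the 4-decimal reported
  form as an attribute, so 0.05/11 prints as 0.0045 without the exact
  value being lost.
* All generator validity constraints (pauses fit between distinct
  internal phone boundaries, every pause ≥ `min_pause_s`, at least one
  phone) are enforced by bounded resampling; an unsatisfiable
  configuration errors out rather than looping.

## Problem sizes used by the test suite

The shipped tests run the summary-statistic chain at the reference sizes
(31/34), calibration checks at 10,000 subjects per group (free-parameter
means within 3 Monte-Carlo SEs; large-n effect-size recovery), direction
recovery at 2,000 per group, the type-I calibration of the pooled t over
4,000 null replicates at n = 31/34, and oracle equivalence sweeps over
randomized small inputs (timelines up to 12 tokens, score sets up to
50). These sizes were chosen so that Monte-Carlo error is small relative
to each asserted tolerance while the whole suite stays interactive.

## Known limitations

Summary mode can only reproduce t-family results — rank tests need raw
data. The Hanley–McNeil SE is an approximation whose finite-sample
behaviour degrades near AUC = 1 (it returns 0 there, making perfectly
separated tiny samples look infinitely certain; interpret small-n ROC
output accordingly). The generator matches first and second moments and
one within-scope correlation, nothing higher. And the pipeline starts at
the alignment: recognizer quality, recording conditions and the speech
elicitation protocol are all upstream of what this package can check.
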