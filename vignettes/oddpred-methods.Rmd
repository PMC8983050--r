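---
title: "Methods: oddball design, index decomposition, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oddball design, index decomposition, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddpred)
```

This vignette documents the models, parameters, and numerical choices behind
`oddpred` — the stimulus generators for the frozen oddball / cascade /
many-standards paradigm, the iMM/iPE/iRS index decomposition, the synthetic
Poisson benchmark, and the classification and site-parsing procedures — in
the order data flow through the pipeline.

## 1. Stimulus design

### Frozen oddball pair

An oddball sequence presents a common standard and a rare deviant
(90:10) separated by half an octave, as 50 ms tones (1 ms cosine-squared
ramps, stored as metadata; no audio is rendered) every 250 ms (4 Hz). The
sequence is divided into blocks, each ended by its single deviant, with the
number of preceding standards varying over 3–17. Laser pairings rotate over
blocks — deviant-laser, last-standard-laser, no-laser — with 45 blocks per
condition and 1250 tones in total, and `make_oddball_pair()` emits the two
sequences of the frozen pair: identical block/laser pattern, standard and
deviant frequencies exchanged.

**Counterbalancing.** The printed totals over-determine the design: 1250
tones over 135 blocks leave 1115 standards, which is not divisible by three,
so the three laser conditions cannot carry literally identical count
multisets. `allocate_block_counts()` therefore splits the standards into
per-condition sums differing by at most one (372/372/371 at the defaults)
and builds each condition's multiset as: one block at every count from 3 to
17 (so both endpoints — indeed every run length — occur in every
condition), with the remaining blocks filled as uniformly as the sum budget
allows. When the block budget cannot cover the whole range (fewer blocks
than distinct counts), the allocator falls back to cycling the range and
walking the sum to its target by unit steps while protecting one copy of
each endpoint; infeasible totals raise an error naming the feasible
interval. Block order within a condition is shuffled under the design seed,
so the pattern is frozen but not systematic.

### Cascade and many-standards controls

The cascade is a monotone sweep of 10 tones at exactly 0.5-octave spacing;
the two oddball frequencies always occupy adjacent positions (default
positions 5–6, configurable — in the recorded experiments their position
was varied). How many cycles were presented, and how laser trials were
arranged within the cascade, is not part of the printed design; the package
defaults to 90 cycles with the laser paired to the two oddball-frequency
tones on alternating cycles, which yields 45 laser and 45 baseline cascade
trials per frequency and mirrors the oddball design's trial counts. Both
choices are arguments of `make_cascade()`.

The many-standards control shuffles each cascade cycle under the constraint
that no two consecutive tones anywhere in the output share a frequency
(including across cycle boundaries). The shuffle is a seeded Fisher–Yates
draw with adjacent-repeat rejection and a local-swap repair pass, bounded at
200 retries per cycle before erroring; with 10 distinct tones per cycle the
constraint is loose and retries are rare. Each tone keeps its laser pairing
through the shuffle, and the presentation grid is untouched.

## 2. Synthetic recordings

`simulate_unit()` emulates an extracellularly recorded IC unit as an
inhomogeneous Poisson process. Per tone, the driven rate is

    context_rate(context) x tuning_factor(frequency) x laser_gain(context)

where the tuning factor is Gaussian in log2 frequency around the unit's
best frequency (sigma 0.3 octaves for central-like units, 1.5 for
shell-like, per the site defaults), the laser gain applies on laser-paired
tones only, and negative effective rates are clipped to zero with a
counter. Spikes fall uniformly within the unit's temporal kernel; the
spontaneous `baseline_rate` (default 2 Hz) fills the rest of the peri-tone
window. Kernels follow the profile taxonomy the classifier is built for:
onset = 0–10 ms boxcar, sustained = 0–50 ms, offset = 50–100 ms, biphasic
= two 10 ms boxcars, mixed = three, inhibited = rate below baseline during
the tone. Generic search stimuli (frequency-response function and tuning
curve) are driven at the neutral cascade-context rate.

`make_population()` adds the population structure the site classifier
exploits: central sites place log2 best frequency on a linear depth
gradient (default 0.0025 octaves/µm across 400–2000 µm, 0.1-octave jitter)
with narrow tuning; shell sites draw best frequencies uniformly over ±3
octaves with broad tuning. Unit classes follow `class_mix` (default 25 %
adapting, 10 % facilitating, 65 % nonadapting, in the range reported for
awake IC); adapting units respond twice as strongly to the deviant as to
the standard with the cascade at the geometric mean, facilitating units the
reverse. Standard-context rates draw uniformly from 10–50 Hz, the range
spanned by the published population means of tone-evoked IC rates.

**What the generator does not emulate.** Counts are exactly Poisson — no
overdispersion, serial correlation, bursting, or adaptation *within* the
standard run (position effects must be constructed explicitly, as the
`standards_by_position` tests do); noise is independent across units (no
shared state or probe drift); laser effects are purely multiplicative and
instantaneous. Passing recovery tests therefore demonstrates that the
analysis code is unbiased and correctly wired at realistic rates and trial
counts, not that it is robust to every pathology of real recordings.

## 3. Response windows and firing rates

Trial firing rates are spike counts in a half-open window
`[onset + a, onset + b)` divided by the window length. The index analysis
defaults to 0–100 ms (tone plus offset window) so genuine offset responders
contribute, and is configurable to the 0–50 ms tone window; the packaged
experiments (`recovery_experiment`, `laser_scenario_experiment`) use
0–50 ms because the synthetic kernels confine context-driven spikes to the
tone window, and the longer window would only add baseline noise. The
response window used for the original published index values is not stated;
both readings are one argument away.

FR_Stan uses the *last-standard* trials only, and baseline context means
use only no-laser blocks (45 trials per context at the defaults). This is
the trial-matched reading of the design — the laser is paired with the last
standard before the deviant, so the matched baseline is the same tone
position in no-laser blocks. Pooling all standards would shrink the
variance of FR_Stan but break that matching; the choice is confined to
`label_contexts()`.

## 4. The index decomposition

`compute_indices()` normalizes the context rates by their Euclidean norm N
and returns iPE = (FR_Dev − FR_Casc)/N, iRS = (FR_Casc − FR_Stan)/N, iMM =
(FR_Dev − FR_Stan)/N. The identity iMM = iPE + iRS is algebraic and is
asserted to 1e-12 across random nonnegative rate triples; each index is
bounded by 1 in magnitude, attained only when two of the three rates
vanish, and the whole set is invariant to rescaling all three rates. The
all-zero triple is undefined (`defined = FALSE`) and such rows are excluded
downstream rather than imputed.

Adapting/facilitating classification is a two-sided Wilcoxon rank-sum test
between the 45 baseline last-standard and deviant trial rates at alpha =
0.05 (the original analyses state significance but no level; 0.05 is the
convention used by their other tests). Exact enumeration is used for
samples of 10 or fewer without ties; otherwise the normal approximation
with tie correction — trial rates are scaled counts, so ties are the rule
at n = 45. All-tied inputs return p = 1 (nonadapting) rather than an error.

## 5. Response-profile classification

PSTHs are trial-aligned histograms at a default 5 ms bin width with no
smoothing (neither the bin width nor any smoothing of the original
peak-finding is stated; 5 ms resolves the 10 ms onset criterion with two
bins, and both are arguments). Significant extrema must clear the baseline
mean (from the 50 ms before onset) by strictly more than 3 baseline SDs;
the trough threshold floors at zero, and the baseline SD floors at 1e-6 Hz
so a silent baseline does not make every bin significant. A local extremum
is a bin strictly greater (lesser) than both neighbours, with plateaus
taking their leftmost bin — a deterministic reading of common peak-finder
behaviour. The taxonomy over the 0–50 ms tone window then assigns onset
(single maximum in the first 10 ms), sustained (single maximum later), E-I
/ I-E (one maximum and one minimum, ordered), biphasic (two maxima), mixed
(more than two extrema); offset-window (50–100 ms) responses append a
combination label. Units with no tone-window maximum — unresponsive,
inhibited-only, or offset-only — are not sound-responsive and never enter
the index tables.

## 6. Recording-site parsing

The published procedure clusters recordings on the R² of a robust linear
fit of best frequency against depth and the mean sparseness of their units,
without stating the sparseness formula or the robust estimator. The package
uses lifetime (Rolls–Tovée) sparseness, S = (1 − (mean r)²/mean(r²)) /
(1 − 1/n), over the tone-window rates at the 50 frequency-response-function
frequencies — the standard single-unit sharpness measure with exactly the
required reading (low = broad tuning) — and iteratively reweighted least
squares with bisquare weights (`MASS::rlm`) for log2(BF) on depth, with R²
computed on the robust weights so isolated outliers barely dilute it
(clamped to [0, 1]). Best frequency is the rate-maximizing frequency, ties
to the lower; all-zero tuning curves are excluded, and sites with fewer
than three usable units are flagged unclassifiable. k-means (k = 2, 50
restarts under a fixed seed, best inertia) runs on z-scored features; the
higher-sparseness cluster is labelled central. Exactly two sites split
trivially; identical feature rows are degenerate and labelled
unclassifiable.

## 7. Statistical dispatch

`dispatch_test()` reproduces the reporting pipeline: Shapiro–Wilk at 0.05
per sample (on differences for paired data) routes to t-tests or Wilcoxon
rank-sum / signed-rank tests; one-sample contrasts test against zero.
Unpaired t-tests use the Welch form — the published tables label them
Student's t-tests but report fractional and reduced degrees of freedom,
which identifies the Welch correction. Effect sizes are Cohen's d (pooled
SD unpaired, SD of differences paired) for t-tests and r = |z|/√n for
Wilcoxon tests, with z recovered from the two-sided normal-approximation
p-value. The CI column is a 95 % half-width, t-based when a t-test was
selected and normal-approximation otherwise (the original CI construction
is unstated). Zero-variance samples fall back to the nonparametric route;
identical paired samples return p = 1 with effect size 0. Report tables
round to 2 significant figures, matching the published style, with df
shown as NA for rank tests.

## 8. Packaged experiments and problem sizes

The experiments behind the test suite and `scripts/acceptance.R` use these
sizes, chosen to mirror the recorded design while keeping a full run in the
tens of seconds:

- **Parameter recovery**: 200 units with independently uniform 10–50 Hz
  context rates (covering the index range), the full 1250-tone pair plus a
  90-cycle cascade, 45 baseline trials per context, errors measured against
  the analytic `expected_indices()` oracle; 100 further units at a 2×
  deviant/standard ratio for the classification confusion matrix.
- **Type-I error**: 2000 null units, 45 equal-rate Poisson trials per
  context.
- **Site-label recovery**: 100 replicates of 2 central + 2 shell sites,
  12 units each, tuning estimated from the simulated 1000-tone
  frequency-response function.
- **Laser scenario**: 60 adapting units with gains (standard 1.3, deviant
  0.75, cascade 1.0) — the directionality reported for cortico-collicular
  inactivation, where removing cortical feedback raises standard responses,
  lowers deviant responses, and thereby abolishes prediction error while
  leaving repetition suppression intact. The experiment reports population
  signs, not magnitudes: the gains are a scenario, not an estimate.

## 9. Known limitations

- The counterbalancing scheme is one defensible resolution of
  over-determined printed totals; the original allocation is unknown.
- Sparseness formula, robust estimator, response window, PSTH bin width and
  the cascade's cycle count/laser arrangement are reconstructions of
  unstated choices; all are exposed as arguments rather than constants.
- Population-level values from the recorded datasets (group means, medians,
  p-values of the published tables) depend on those recordings and are out
  of scope here; the synthetic benchmark checks recovery, calibration and
  directionality instead.
- The simulator's Poisson assumption understates the trial-to-trial
  variability of real multiunits; recovery errors quoted by the experiments
  are best-case floors.
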