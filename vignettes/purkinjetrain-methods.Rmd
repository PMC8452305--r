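---
title: "Methods: spike-train statistics and the electrophysiological pseudo-timeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train statistics and the electrophysiological pseudo-timeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model of the data

`purkinjetrain` analyzes in vivo extracellular recordings of cerebellar
Purkinje cells during the second postnatal week, a period in which their
spontaneous firing reorganizes from slow, continuous and irregular into
fast, burst-like and rhythmic-within-bursts. The package starts *after*
spike sorting: its input is, per cell, an ordered table of detected events
(time in seconds, peak amplitude in arbitrary units, spikelet count) plus
metadata (analyzed recording duration, age-by-genotype group, genotype).
Raw-voltage processing, template sorting and artifact rejection are out of
scope.

Analysis proceeds in four stages:

1. **Classification** of events into simple spikes, complex spikes,
   doublets (an immature complex-spike-like event) and complex-spike
   trains.
2. **Per-cell statistics** of the simple-spike train: frequency, frequency
   mode, CV, CV2, pause percentage and an autocorrelogram-based
   rhythmicity index, plus complex-spike/doublet event frequencies.
3. **Population analysis**: z-scored clusterogram over cells, a 2-D tSNE
   "pseudo-timeline", hierarchical linkage over PCA-reduced group means,
   and per-feature one-way ANOVA with Tukey-Kramer post-hoc comparisons.
4. **Synthetic data**: generators that emulate the firing phenotypes with
   ground-truth labels, so the full pipeline is testable without
   recordings.

## Event classification

Rules are applied in precedence order **complex > doublet > simple**,
because a complex spike trivially also matches the doublet time-window
pattern:

* an event with `spikelet_count >= 3` (classical complex spikes carry a
  train of roughly three to five trailing spikelets) is **complex**;
* scanning in time order, an unlabeled event followed within **20 ms** by
  one or more unlabeled events of smaller amplitude is a
  **doublet primary**, and those followers **doublet secondaries**;
* everything else is **simple**.

"Smaller" is operationalized as an amplitude ratio strictly below 0.9
(configurable): amplitude jitter in real recordings makes near-equal
amplitudes uninformative, and exact ties are deliberately "not smaller".
The 20 ms window is inclusive; window comparisons carry a 1 ns guard so
that floating-point representation error — far below the 1 µs resolution
at which times are stored — cannot flip a boundary decision.

A **complex-spike train** is a maximal run of three or more complex
spikes whose successive gaps do not exceed `cs_train_max_gap_s`. "Close
succession" is not quantified in the source literature; the default of
100 ms is this package's choice, is configurable, and is recorded in run
provenance. A cell firing both complex spikes and doublets is flagged
`heterogeneous_cs`.

## Simple-spike statistics

All six statistics are computed on the simple-spike-only time sequence.
When a complex spike or doublet is removed, the interval between the two
flanking simple spikes is retained as a single ISI. This preserves
total-time conservation (`sum(ISIs) == span`), at the cost of a small
number of artificially long intervals; with complex-spike rates around
1 Hz against simple-spike rates of 40–150 Hz, the contamination is below
2 % of intervals. Cells with fewer than 10 simple spikes are flagged with
an insufficient-data error rather than silently dropped, and recordings
shorter than 75 s (inclusive bound) are excluded up front. The analyzed
duration always comes from metadata; the spike span is only a fallback
(with rebasing to zero and a warning), since the total analyzed recording
time is what the acquisition chain actually certifies.

| statistic | definition | default parameters |
|---|---|---|
| frequency | spike count / analyzed duration | — |
| frequency mode | center of fullest bin of the ISI⁻¹ histogram | 2.5 Hz bins, left-closed, anchored at 0; ties to the lowest bin |
| CV | sd(ISI)/mean(ISI), population (÷N) SD | — |
| CV2 | mean of 2·abs(ISIₙ−ISIₙ₋₁)/(ISIₙ+ISIₙ₋₁) | — |
| pause percent | sum of ISIs strictly above k·mean(ISI), over duration | k = 5 |
| rhythmicity index | see below | 5 ms bins, 1 s max lag |

The population-SD convention for CV and the left-closed/low-tie-break
binning for the mode are choices on points the defining formulas leave
open; both differ from the alternatives by O(1/N) or by at most one bin
width, respectively.

## Autocorrelogram and rhythmicity index

The autocorrelogram counts ordered spike pairs by lag in bins
`(b·Δ, (b+1)·Δ]` with Δ = 5 ms up to 1 s. Its expected per-bin count for a
memoryless train of the same rate is `baseline = N²/(T/Δ)`, and the noise
floor `tail_sd` is the sample SD of the counts over lags in (0.96, 1] s —
the last 8 bins — where the rhythmicity of any real cell has damped out.
The implementation accumulates pairs by lag order but is exactly equal to
O(n²) enumeration (tested for n ≤ 500).

Peaks and troughs are found iteratively, with lags taken at bin centers
and windows including every bin whose center falls inside them:

* first peak: highest bin between 10 ms and 1.5× the cell's mean ISI
  (its lag is `a₁`);
* trough *n*: lowest bin between peak *n* and peak *n* + `a₁`;
* peak *n*+1: highest bin between trough *n* and peak *n* + `a₁` + 10 ms.

Iteration stops at the first rejected pair, at an empty window, or when
the next window's nominal upper edge would pass the maximum lag (the
first-peak window is clipped to the maximum lag for very slow cells). The
index is `RI = Σ(peak − trough)/baseline` over accepted pairs, 0 when no
pair is accepted.

**Acceptance rule.** A pair is accepted when its excursion exceeds the
tail noise floor, `peak − trough > 4·tail_sd` (the default, `"deviation"`),
or when the peak exceeds `baseline + 2·tail_sd` while the trough falls
below `baseline − 2·tail_sd`. A literal `"sum"` variant of the first
clause — comparing `peak + trough`, two raw counts of order baseline, to
a dispersion — is provided for comparison but is *not* the default: on a
homogeneous Poisson train it accepts pair after pair (peak + trough ≈
2·baseline always dwarfs 4·tail_sd ≈ 4·√baseline), yielding a
rate-dependent index near 1.5 at 60 Hz for a train with *no* rhythmicity,
which contradicts the empirical finding the measure exists to express
(irregular immature cells score low, rhythmic mature cells score high).
The deviation form rejects flat autocorrelograms, as verified by the
acceptance suite.

**Limits of the rhythmicity index** (all verified by tests and recorded
honestly rather than patched):

* A *noiseless* periodic train scores 0, not high: its autocorrelogram
  never decays, so the 0.96–1 s tail contains full-height peaks and
  `4·tail_sd ≈ 1.7–1.9 N` exceeds any possible excursion (≤ N). The
  measure presupposes rhythmicity that damps out before the tail — true
  of every real recording. A realistically jittered rhythmic train
  (gamma renewal, shape 20, 50 Hz) scores ≈ 1.4–1.6, and the index is
  non-decreasing in the gamma shape over k = 1…64.
* A *fixed-phase* sinusoidally rate-modulated Poisson train also scores 0
  at any modulation depth, for the same reason: its autocorrelogram
  oscillation is undamped, so the tail oscillates at full amplitude.
  Renewal-type rhythmicity (phase diffuses, oscillation damps) is the
  phenomenon the index measures.
* Cells whose mean ISI is at or below 8.3 ms have an empty first-peak
  window (no 5 ms bin center inside (10 ms, 1.5×meanISI]) and score 0 by
  construction. In the bursty synthetic phenotype this caps how many
  fast-firing cells can express a positive index, which is why the
  package's cohort test compares the count of cells with positive index
  between phenotypes rather than medians.

## Population analysis

The clustering inputs are exactly the six simple-spike statistics —
event-class frequencies and the heterogeneity flag are excluded. Features
are z-scored across cells (a constant feature is zeroed with a warning).
Cells are clustered on Euclidean distances with average linkage (methods
configurable; the source analysis names only the library routines, not
the methods), and labels are attached only after clustering. tSNE runs on
the same z-scored matrix with Euclidean distances; the implementation is
exact (non-Barnes-Hut) t-SNE, adequate and fast for populations of
O(10²) cells, with a mandatory recorded seed — the same seed reproduces
coordinates bitwise. Perplexity defaults to 30 and is validated against
the population size. Group-level structure uses the first two principal
components of the z-scored group-mean table (covariance-PCA available via
`scale = FALSE`), clustered with the same linkage.

Per-feature group differences use one-way ANOVA followed by
`stats::TukeyHSD`, which implements the Tukey-Kramer procedure and
therefore supports unequal group sizes; groups with fewer than two cells
are excluded with a warning. Calibration (type-I error 5 % ± 2 on a
six-group global null; familywise error ≤ 7 %; power ≥ 95 % for a 3-SD
shift at n = 15) is verified by simulation in the acceptance suite.

## The synthetic world

The generators state, once, what each phenotype looks like:

* **young_control** — continuous, slow, locally irregular: gamma-renewal
  trains, rate ~ U(40, 80) Hz, shape ~ U(1.5, 3) (ISI CV ≈ 0.58–0.82);
  doublets at 0.3 Hz, complex spikes at 0.2 Hz.
* **old_control** — fast, bursty, rhythmic within bursts: alternating
  exponential burst (mean 1 s) and pause (mean U(0.2, 0.5) s) states;
  gamma-renewal firing inside bursts at U(120, 180) Hz with shape
  U(10, 20); complex spikes at 0.8 Hz, doublets at 0.05 Hz.
* **mutant** — drawn from the *same* distributions as young_control
  (the arrested-maturation phenotype), except doublets at 0.8 Hz.

Each cell's recording lasts 186 s, the typical analyzed duration of the
real recordings. The burst-duration mean (1 s) and the per-preset
injection rates not constrained above are package choices fixed before
any cohort-level test was run. Injected events respect the classifier
thresholds with margin — complex spikes at amplitude 2 with 4 spikelets,
doublet primaries at amplitude 1 with a 0.5-amplitude secondary after a
uniform 2–18 ms gap, trains of 3–5 complex spikes with 20–80 ms gaps —
and injected structures keep 150 ms apart, with base simple spikes
cleared within the doublet window + 2 ms of each structure. (A bare 2 ms
refractory clearance is insufficient: a base spike less than 20 ms before
an injected primary would see the small secondary inside its own window
and become a spurious doublet primary.) Consequently classification on
synthetic data is provably exact, and the test suite asserts label-level
precision and recall of 1.0.

What the generators do **not** emulate: amplitude drift and noise
(a Gaussian-jitter option exists but defaults off), electrode instability,
censored segments within a recording, true climbing-fiber statistics
(complex-spike timing is Poisson here), refractory interactions between
simple and complex spikes beyond a clearance margin, and slow
nonstationarity of firing rate. A green pipeline test therefore
establishes the correctness of the *computations* on well-posed inputs,
not robustness to sorting errors upstream.

## Numerical and degenerate-input choices

* Times are stored in seconds at ≥ 1 µs precision; events closer than
  1 µs are duplicates (rejected on load, thinned by generators).
* Serialization writes 9 decimal places; a save/load round trip
  reproduces the decimal representation exactly, and rerunning the
  pipeline with an identical configuration and seed reproduces every
  output byte for byte.
* CV/CV2/pause are exactly 0 on exactly-equal ISIs; through the
  generator chain the only deviation from 0 is the floating-point
  representation of the spike times (≤ 1e-11 relative).
* An all-zero autocorrelogram yields RI = 0 without error; empty search
  windows terminate the peak iteration quietly.
* Ties in the frequency-mode histogram resolve to the lowest-frequency
  bin; ties in peak/trough searches resolve to the earliest bin.

## Known limitations

The rhythmicity index inherits the resolution limits described above
(5 ms bins cannot resolve intra-burst rhythms faster than ~100 Hz, and
the 10 ms window floor excludes the fundamental peak of cells firing
above ~150 Hz within bursts). Exact reproduction of any published
embedding geometry is impossible — perplexity, seed and linkage method
of the original analyses are unreported — so only qualitative cluster
structure is asserted: the two-way cut of the cell clusterogram separates
immature-like from mature-like phenotypes, mutant-like cells sit nearer
the young centroid in the embedding, and mutant groups join the young
clade in the group-mean dendrogram.
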