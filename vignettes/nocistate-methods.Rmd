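---
title: "Methods: nociceptive-evoked features and unsupervised anesthesia-state identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nociceptive-evoked features and unsupervised anesthesia-state identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anesthesia monitoring usually tracks sedation (loss of consciousness) and
largely ignores nociception. Stimulus-locked cortical responses to noxious
stimuli — laser-evoked potentials (LEPs, with their dominant N2 wave) and
evoked gamma-band oscillations (GBOs, ~55–90 Hz) — carry exactly that missing
analgesic dimension, while complexity (permutation entropy, PE) and
ordinal coupling (permutation cross-mutual information, PCMI) track the
hypnotic dimension. `nocistate` implements the full analysis chain that turns
multichannel stimulus-locked ECoG into a latent-state assignment per trial:

1. **preprocess** — zero-phase Butterworth band-pass 1–100 Hz plus 49–51 Hz
   notch, epoching −1000…2000 ms around each stimulus (inclusive endpoints:
   3001 samples at 1000 Hz), full pre-stimulus baseline subtraction, and
   rejection of trials exceeding ±500 µV;
2. **tfd** — 30 Hz low-passed LEP waveforms with the N2 quantified as the
   signed mean over 250–400 ms at the central electrodes (FL2, FR2, PL1,
   PR1), and an STFT time-frequency map (200 ms Hanning window, 1 ms step,
   1 Hz bins) cropped to −500…1000 ms, baseline-corrected at −400…−100 ms per
   trial, with the GBO ROI at 55–90 Hz × 200–500 ms;
3. **ordinal** — PE and PCMI (`PE_X + PE_Y − PE_XY`) with embedding order
   m = 3, delay τ = 1, window 256 samples;
4. **featmat** — a per-trial vector of 1134 features: 504 spectral
   (14 electrodes × 6 bands × 6 time bins), 84 PE (14 × 6), 546 PCMI
   (91 pairs × 6), z-scored per column;
5. **consensus** — k-means repeated 100 times, labels aligned to the
   best-within-sum run by the Hungarian algorithm, unweighted majority
   voting, leave-one-subject-out validation, and subject-level bootstrap
   comparison of k ∈ {3, 4, 5};
6. **quality** — Davies–Bouldin, mean silhouette, Dunn, adjusted Rand index,
   per-trial vote fractions, and cluster-overlap tables;
7. **infoshare** — per-family PCA to 3 components, Kraskov (KSG) k-NN mutual
   information (k = 5), and the relative-information-sharing matrix
   `R[i, j] = I(i, j) / I(i, i)` with `I(i, i)` the MI between the
   overlapping `[PC1, PC2]` and `[PC2, PC3]` subspaces.

No public recordings accompany the approach, so the package ships a
first-class synthetic-data module that generates four-state cohorts with
ground-truth labels; every pipeline stage is tested against it.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band-pass | 1–100 | Hz | recording band; 4th-order Butterworth, zero phase |
| notch | 49–51 | Hz | power-line removal (50 Hz mains) |
| epoch window | −1000…2000 | ms | inclusive endpoints, 3001 samples at 1 kHz |
| broadband baseline | −1000…0 | ms | full pre-stimulus interval |
| rejection threshold | 500 | µV | absolute amplitude, any channel/sample |
| STFT window / step / bins | 200 / 1 / 1 | ms / ms / Hz | Hanning window |
| TFD crop | −500…1000 | ms | discards window-edge artifacts before any ROI |
| TFD baseline | −400…−100 | ms | per-trial subtraction |
| N2 ROI / electrodes | 250–400 ms / FL2 FR2 PL1 PR1 | | signed mean; more negative = larger N2 |
| GBO ROI | 55–90 Hz × 200–500 ms | | an alternative 55–99 Hz × 100–500 ms ROI is config-selectable |
| ordinal m, τ, window | 3, 1, 256 | —, samples, samples | Bandt–Pompe, ties by order of occurrence |
| PE summary | 0–1000 ms, PL1 PR1 PL2 PR2 | | mean over windows fully inside the interval |
| PCMI summary | 0–500 ms, FL1 FR1 FL2 FR2 | | mean over the 6 frontal pairs |
| k-means runs | 100 | | k-means++ (greedy variant), Lloyd iterations |
| bootstrap | 1000 resamples (100 at desk scale) | | subjects drawn with replacement |
| KSG neighbors | 5 | | variant 1, max-norm |

Entropies are reported in bits (base 2), unnormalized; a `normalize` flag
divides by `log2(m!)`. Mutual information from the KSG estimator is in nats;
the sharing matrix R is unit-free.

## Numerical and convention choices

- **Epoch endpoints** are closed intervals at 1 ms resolution; a "3000 ms"
  epoch therefore holds 3001 samples. All time windows in the package are
  closed `[lo, hi]` in ms; sample indices in event tables are 0-based.
- **Filter realization.** No DSP package is assumed: the Butterworth design
  (analog prototype → band transform → bilinear transform → second-order
  sections) is implemented in the package and applied forward–backward with
  odd-reflection padding. The 4th-order default matches the conventional
  EEG-toolbox choice; the order is a config knob.
- **STFT crop.** Maps are defined on the full epoch and cropped to
  −500…1000 ms before any ROI statistic (`roi_power` refuses uncropped
  maps). Because each STFT value depends only on the samples inside its own
  200 ms window, evaluation is restricted to the retained time points —
  identical values, half the work.
- **Power** is the squared magnitude of the Hanning-windowed DFT, one-sided,
  linear units (no dB), as required by a subtractive baseline.
- **Ordinal ties** are broken by order of occurrence (earlier sample ranks
  lower) — the standard Bandt–Pompe convention. The fast pattern encoder is
  a vectorized Lehmer code; tests require exact (1e−12) agreement with a
  naive argsort-and-histogram oracle, including tied inputs.
- **PCMI per time bin.** The feature matrix demands PCMI in 250 ms bins, but
  the nominal estimation window is 256 samples — it cannot fit. The bin
  structure wins: PCMI is estimated from the 248 ordinal patterns available
  in each 250-sample bin. The sliding-window estimates (window 256) remain
  available for time-resolved summaries; `windowed_pcmi(allow_short = TRUE)`
  marks the short-window path explicitly.
- **Sliding PE step** defaults to 10 ms (no step is canonically stated);
  window positions are stamped at the window end. Binned PE features are
  means over window positions whose end falls in the bin.
- **Frequency bands** are half-open `[lo, hi)` except high gamma, closed at
  90 Hz; the 45–55 Hz gap between low and high gamma is an intentional notch
  guard band. Time bins are half-open 250 ms intervals; the final sample at
  exactly +1000 ms joins the last bin.
- **z-scoring** uses the sample SD (n − 1); zero-variance columns are set to
  0 and flagged. Out-of-sample projection (leave-one-out) always applies the
  stored training scaling, never test statistics.
- **k-means** uses Euclidean distance on z-scored features, greedy k-means++
  initialization (2 + ⌊log k⌋ candidate seeds per step, keep the
  potential-minimizing one) and Lloyd iterations; plain D² seeding
  double-seeds a well-separated cluster a few percent of the time, which
  would contaminate run-to-run stability with pure optimizer noise. Runs
  that converge with an empty cluster are re-initialized and counted.
- **Reference run and alignment.** The reference labeling is the run with
  the smallest within-cluster sum of squared distances (ties → lowest run
  index); every run's labels are mapped to it by the Hungarian assignment on
  the centroid-distance matrix (a greedy matcher is available as a fallback
  flag). Vote ties go to the smaller cluster index and are logged.
- **Consensus for the main analysis and the bootstrap both use the
  best-within-sum reference rule** — the description of the main analysis
  mentions "predefined reference centroids" without defining them, so the
  two sections are unified on the explicit rule.
- **k selection.** The Ward dendrogram (`ward_tree`) is auxiliary; the
  authoritative selector is the subject-level bootstrap (`bootstrap_k`),
  which scores consensus partitions per replicate with DBI, silhouette,
  Dunn, and the median vote fraction, and prefers the k with the best median
  silhouette (Dunn breaks ties). Replicates where a k's consensus leaves an
  empty cluster are flagged and excluded from paired comparisons.
- **Silhouette for singleton clusters** is 0; Dunn with a zero maximal
  diameter returns a flagged large sentinel (1e12); DBI with coincident
  centroids is an error.
- **KSG estimator**: variant 1, max-norm, k = 5. Duplicate joint points get
  a deterministic jitter of 1e−10 × column SD (seeded, logged). Negative MI
  estimates (possible at small n) are clamped to 0 only inside R;
  raw values are preserved in `I_cross`. Rows with non-positive internal
  coupling are flagged invalid rather than divided by.
- **PCA sign convention**: the largest-magnitude loading of each retained
  component is positive, so embeddings are reproducible across runs.
- **Seed discipline**: one master seed fans out to per-stage and per-run
  seeds through a fixed hash-and-offset scheme (`derive_seed`), so any stage
  can be re-run in isolation with identical results and no stream collisions.

## The synthetic world

`generate_cohort()` emulates what the analysis assumes about
stimulus-locked anesthesia ECoG; it is a stated world, not a fit to data:

- **Background**: per channel, 1/f^α Gaussian noise (α per state) plus a 15%
  broadband floor, both shaped by a Gaussian low-pass whose cutoff
  `50 · entropy_level³` Hz realizes the state's ordinal diversity. The
  slowly varying, low-diversity process of deep states is this heavily
  low-passed background itself. (A white-noise variance share was tried
  first and discarded: at τ = 1 under a 1–100 Hz band-pass it barely moves
  PE, because millisecond-scale increments are governed by the upper cutoff,
  not the variance mix.) Background amplitude is state-dependent
  (awake 20 µV RMS, shallow 30, moderate 38, burst suppression 38):
  awake cortex is low-amplitude and desynchronized, anesthesia raises
  slow-wave amplitude.
- **Coupling**: a shared source mixed into every channel with weight
  `coupling_strength` (variance-preserving), which PCMI picks up.
- **Evoked components**, post-stimulus only, strongest at the central
  electrodes (spatial weight 1 vs 0.3 elsewhere): an N2–P2 complex (an
  N2-like half-cosine deflection, width 150 ms, state-specific amplitude and
  latency, followed ~230 ms later by an opposite-polarity P2 slow wave at
  60% of the N2 size) and a gamma burst (70 ± 10 Hz carrier with random
  phase, Gaussian envelope, SD 60 ms, gain 35 µV per unit, state-specific
  gain and latency).
- **Burst suppression**: the background is amplitude-gated (suppression gain
  0.1); spontaneous bursts arrive as a Poisson process and stimuli trigger a
  burst 60–120 ms post-onset with probability 0.95; bursts are 250–450 ms
  raised-cosine envelopes reaching gain 2.5.
- **States**: awake has the largest N2 (−140 µV) and gamma gain (3.5) and
  the lowest coupling (0.05); shallow has diminished *and delayed* evoked
  responses (N2 −60 µV at 380 ms, gamma gain 1.8 at 430 ms) with coupling
  0.55; moderate is nearly unresponsive (gamma gain 0.1) with the highest
  coupling (0.7); burst suppression has the strictly lowest entropy level
  (0.3), intermediate coupling (0.25 — inter-channel coupling is
  deliberately non-monotone in depth, as the coupling measure itself is),
  and is the only bursting state. The realized normalized PE spread
  (≈ 0.62 / 0.55 / 0.46 / 0.30 across the four states, with per-trial SDs
  below 0.04) mirrors the very large complexity effects reported for real
  anesthesia levels.
  Cohorts progress awake → shallow → moderate during induction and
  burst-suppression/moderate → shallow → awake during emergence, so burst
  suppression appears only after anesthetic cessation. Class balance is
  equal by default (per-state trial counts are not reported in the source
  material). Background RMS is 40 µV, calibrated so well under 1% of default
  trials cross the 500 µV rejection threshold; an `artifact_trials` flag
  plants 800 µV low-frequency artifacts for rejection tests.

The defaults were calibrated once so that the four states carry pronounced,
realistic signatures, and then frozen. What a green test establishes: the
pipeline recovers latent structure *of the kind the generator produces* —
stationary-within-trial backgrounds, additive evoked templates, Gaussian
noise, equal class balance. What it does not establish: robustness to
non-stationary drift, movement or electrode artifacts beyond a hard
amplitude threshold, volume-conduction-realistic spatial mixing, subject
heterogeneity in evoked latencies, or the empirical effect sizes of real
rat ECoG (the published F statistics, cluster compositions, and R
off-diagonal percentages depend on data available only on request and are
deliberately not asserted anywhere in the test suite).

## Scaling choices in the test suite

The acceptance suite runs the stated desk-scale reductions: the bootstrap
criterion uses 100 replicates (not 1000) on a 6-subject × 48-trial cohort,
and end-to-end recovery averages 5 cohorts of the default 6 × 32 size.
Unit tests run on memoized 2-subject fixtures. One full cohort's feature
extraction takes on the order of two minutes on one CPU; the two heavy
acceptance criteria dominate the suite by design.

## A negative result the tests report honestly

One acceptance-grade property of the source analysis does **not** hold in
this synthetic world, and the corresponding test is left failing rather than
weakened: the subject-level bootstrap's *median silhouette* prefers k = 3
over k = 4 on the default four-state cohort (≈ 0.17 vs ≈ 0.14). The reason
is structural, not a bug. Baseline-subtracted spectral features carry no
tonic state information (any stationary background has zero mean after
subtraction), so 504 of the 1134 columns discriminate states only through
evoked components; per-bin PCMI from 248 ordinal patterns and χ²-distributed
band-power estimates put an irreducible within-state noise floor of ~20–25
z-units under every trial; and with four states whose pairwise centroid gaps
span 20–45 z-units, merging the closest pair always raises the mean
silhouette — the well-known coarseness bias of the silhouette when the
minimum gap-to-dispersion ratio is below ≈ 1.5. Pushing the generator's
separations beyond their current (already pronounced) values would have no
physiological reading. The end-to-end consensus clustering at k = 4 still
recovers the ground-truth states with ARI ≈ 0.95, so the pipeline itself is
sound; what fails is the claim that the silhouette-based selector would pick
k = 4 on data of this geometry. A related directional check fails for the
same reason: because baseline subtraction caps the spectral family's tonic
information and the band limit caps PE, much of the realizable state
separation is carried by the coupling (PCMI) ladder — so the PCMI-only
clustering is *strong* in this world (its own-space silhouette slightly
exceeds the all-features one), whereas on the real data it was reported
weak. The stability direction (all-features median vote fraction at least
that of PCMI-only) does hold.

## Known limitations

- PCMI is implemented exactly as `PE_X + PE_Y − PE_XY` with simultaneous
  patterns (no cross-delay), matching the stated formula; directed or
  delayed variants are out of scope.
- The KSG estimator is O(n²); fine for thousands of trials, not for raw
  sample-level series.
- `I(i, i)` uses raw PC scores (not variance-weighted); an open question in
  the source description, resolved here and documented.
- The CLI's resumability is digest-based per stage; recordings are
  regenerated deterministically rather than cached to disk unless
  `write_recordings = TRUE` (plain-text recordings are large).
- HDF5/EDF containers are replaced by TSV/JSON across all external
  interfaces (no HDF5 bindings in the supported environment).
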