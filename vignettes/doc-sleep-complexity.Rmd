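---
title: "Data-driven sleep characterization by permutation entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven sleep characterization by permutation entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standard AASM sleep staging assigns each 30 s polysomnography (PSG) epoch to
wake, N1, N2, N3 or REM by looking for a handful of well-defined graphoelements
(spindles, K-complexes, rapid eye movements). In patients with disorders of
consciousness (DOC) — unresponsive wakefulness syndrome (UWS) and minimally
conscious state (MCS) — severe brain injury distorts the topography, power and
morphology of these patterns so badly that rule-based staging becomes
unreliable. `docsleep` implements an alternative, data-driven route:

1. reduce every 30 s epoch of every channel to a single **complexity** number
   — normalized permutation entropy (PE) — which is robust to amplitude
   distortions and environmental noise because it only looks at rank
   orderings;
2. explore group structure with unsupervised **agglomerative hierarchical
   clustering** of stratified, cross-subject-averaged epochs, anchoring a
   dissimilarity cut-off on healthy sleepers where five stages are expected;
3. train a supervised five-class **stage classifier** (random forest or a
   feedforward net) on healthy, expert-labeled nights, validated
   leave-one-subject-out (LOSO);
4. apply the classifier epoch-by-epoch to 24 h patient recordings and
   validate the collapsed sleep/wake output against the only behavioral ground
   truth available at the bedside: **eye state** (open/closed) scored from
   video in 5 min blocks, via a binary F1 statistic with sleep-and-eyes-closed
   as the positive class.

Because the clinical recordings this design targets are not publicly
deposited, the package ships a synthetic PSG generator that reproduces the
statistical structure the analysis relies on; every stage of the pipeline is
exercised and tested against it.

## Permutation entropy

A window of $n$ samples spaced $\tau$ apart is mapped to the permutation that
sorts it ascending; sliding the window over a 30 s epoch gives a distribution
$p_\pi$ over the $n!$ patterns, and

$$H = -\frac{1}{\ln n!}\sum_{\pi:\,p_\pi>0} p_\pi \ln p_\pi \in [0,1].$$

Choices that the literature leaves open, fixed here:

* **Logarithm base.** Natural log, normalized by $\ln n!$; the base cancels
  under normalization.
* **Ties.** Equal amplitudes are ranked earlier-index-first (a stable
  argsort). Ties are measure-zero after band-pass filtering but the rule makes
  integer-valued and constant inputs deterministic: a constant epoch has a
  single (tie-broken) pattern and PE exactly 0.
* **Parameters.** $n = 3$ throughout (6 patterns, well-estimated from the
  ~7500 samples of one epoch at 250 Hz); $\tau \in \{1, 3\}$ samples *at the
  post-downsampling rate* of 250 Hz. $\tau = 3$ probes slower temporal
  structure and is the default for patient analysis because it separates N3
  best.
* The per-epoch feature vector keeps **all 14 canonical channels** — EMG and
  EOG included, since muscle atonia and eye movements are exactly what
  separates REM from wake when EEG complexity alone is ambiguous.

The implementation encodes each window by its rank vector in compiled code
and tabulates pattern codes; the test suite pins it to a brute-force window
enumeration (plain `order()` per window) at $10^{-12}$ on a hundred random
signals, including heavily tied ones.

## Signal conditioning

The chain is fixed: resample to 250 Hz → band-pass 1–30 Hz → common average
reference → ocular regression → canonical 14-channel selection → 30 s
segmentation.

* **Resampling** is integer-factor decimation with a zero-phase Butterworth
  anti-alias low-pass at 80 % of the new Nyquist; the acquisition-to-analysis
  case is 500 → 250 Hz. Non-integer ratios are rejected rather than
  approximated.
* **Band-pass**: Butterworth of design order 4, applied forward–backward, so
  the effective magnitude response is squared and the phase is zero. With
  these choices a 60 Hz mains tone is attenuated by >60 dB and DC by far more
  than 99 %. Start-up transients are controlled by odd-reflection padding with
  steady-state initial conditions.
* **Reference.** The montage's reference electrode is not part of the design;
  the common reference is implemented as the average over EEG channels only
  (EMG/EOG excluded), exposed as a config choice. After it, the EEG-channel
  mean is numerically zero at every sample.
* **Ocular correction** follows the classical regression approach: one
  ordinary least-squares fit of each EEG channel on the EOG channel(s) over
  the *whole recording* (the cited technique is a global regression, not
  per-epoch), subtracting the fitted EOG contribution. The EOG channel itself
  is kept raw, because its complexity is a feature downstream. A planted
  leakage coefficient of 0.3 is recovered to ±0.01 in the tests.
* **Epochs** are half-open, contiguous, 0-indexed; a trailing partial epoch is
  dropped. Day/night membership of an epoch is decided by its midpoint, which
  makes boundary epochs unambiguous. 5 min video labels are replicated onto
  their ten 30 s epochs; anything outside the annotated span becomes NA
  (unscorable) and is excluded from quantitative scores.

## Clustering

Group-level analysis compresses each subject to 100 stratified epochs —
healthy: 48 wake + 13 from each sleep stage; DOC: 50 day + 50 night — sampled
without replacement and averaged across subjects. The averaging rule pairs
epochs *position-wise within stratum* after sorting each subject's sample by
recording time; the stratified averaging leaves this pairing open, so the rule
is recorded here as the package's choice, not asserted as anyone else's.
Subjects shorter than a quota are resampled with replacement with a warning
(strict mode errors instead).

Average-linkage agglomeration on Euclidean distances (via `stats::hclust`,
pinned in the tests to an exhaustive hand agglomeration) produces the
dendrogram. The five-class cut-off is the midpoint of the open interval of
heights between the $(n-k)$-th and $(n-k+1)$-th merges — any value in the
interval yields the same partition, and the midpoint is deterministic. The
healthy cut-off is applied *unchanged* to the MCS and UWS trees; "distance
between the two most distinct clusters" is operationalized as the root merge
height, which for average linkage equals the mean pairwise distance between
its two child clusters exactly.

## Classification

* Random forest (500 trees by default; `mtry` searched over {2, 4, 8}) and a
  single-hidden-layer feedforward net (width {16, 32} × decay {0, 0.1}) are
  supported. `nnet` provides only one hidden layer, so network depth is not a
  search axis here; the forest is the model of record for patient analysis
  anyway.
* The inner search is a 10-fold cross-validation on the pooled training
  epochs, optimizing **weighted F1** (class-support-weighted mean of
  per-class F1) — the appropriate summary when N2 alone can occupy half of
  sleep. Whether the original design optimized weighted F1 or accuracy in the
  inner loop is not documented; weighted F1 is used here for consistency with
  the outer metric.
* LOSO: each subject is scored once by a model whose fitting *and*
  hyperparameter selection never saw that subject's epochs (asserted by
  construction in the tests). Cohort summaries use median and MAD.
* Chance level is a dummy drawing predictions from the training class
  distribution; its expected weighted F1 has the closed form $\sum_c p_c^2$,
  which the Monte-Carlo estimate must match in the tests.
* Predicted hypnograms are raw epoch-by-epoch outputs — no temporal
  smoothing.
* MAD is reported unscaled (`constant = 1`): it is used as a descriptive
  robust spread, not as a normal-consistent scale estimate.

## Binary validation against eye state

Five-class predictions collapse to sleep (N1/N2/N3/R) vs wake; the positive
class of the F1 is *predicted sleep while eyes closed*. Unscorable (NA)
epochs are always excluded — the tests prove the score is invariant to
predictions on them. Epochs with switching eyes (O/C) are excluded by default
because the design validates against sustained eye closure only; a strict
mode counts them as not-closed. One caveat is attached to every report: a
patient lying awake with closed eyes makes a correct sleep=no prediction look
like a false negative, so the proxy systematically underestimates specificity
— it is surfaced, not corrected.

## The synthetic generator

Each stage is a spectral recipe: band-limited Gaussian noise in the four
classical bands (delta 1–4, theta 4–8, alpha 8–12, beta 12–30 Hz) mixed by
per-stage power fractions, over a band-limited 1/f background (an AR(0.99)
process low-passed at 35 Hz). Wake is beta/alpha-heavy, N3 is delta-dominated,
REM sits between wake and N1. EOG carries stage-dependent bursts (blinks in
wake, rapid movements in REM) and leaks into EEG channels with a
front-to-back coefficient profile, so the ocular regression has something
real to remove; EMG is a broadband tone over a fixed colored baseline, so its
*spectrum* (hence its PE) tracks muscle tone — high in wake, collapsed in REM
atonia.

Two design points deserve emphasis:

* **No broadband white floor.** A white noise floor dominates
  adjacent-sample ordinal patterns and *inverts* the intended complexity
  ordering at $\tau = 1$; physically the acquisition anti-alias filter
  removes such a floor anyway. With band-limited backgrounds the generated
  ordering is W > R > N1 > N2 > N3 at $\tau \in \{1,3\}$ at both 250 and
  500 Hz, verified once during calibration and enforced by the tests.
* **DOC subjects as blends.** A latent state machine alternates wake-like day
  periods and night periods with two distinct sleep-like sub-states (N2-like
  and REM-like) plus brief arousals. The emitted signal is a convex blend of
  the wake model and the current sub-state model with blending weight
  $0.5 + m(\lambda - 0.5)$, where $m$ is the **modulation depth**: MCS
  defaults to 0.9 (strong day/night complexity modulation, distinct night
  sub-states), UWS to 0.05 (almost no modulation). Eye states latch to the
  *latent* state with a 5 % error rate — deliberately, even for UWS, where
  behavioral eye cycling persists while cortical complexity stays flat. This
  is what makes the eye proxy informative for MCS-like subjects and poor for
  UWS-like ones, and it leaves the achievable validation F1 below 1.
* Unscorable video fractions default to the realistic regime of 15 % of
  day-time and 62 % of night-time blocks.
* Healthy hypnograms are first-order Markov chains on the 30 s grid with
  sticky, routed transitions (wake enters sleep through N1, N3 through N2);
  the empirical stage fractions are tested against the chain's stationary
  distribution (eigenvector oracle) on pooled nights, because single sticky
  nights fluctuate by design. Cohort simulation re-draws a subject's chain
  from a fresh substream if some stage is entirely absent — a training cohort
  must exhibit every stage (an inclusion criterion, not a change to the
  chain).

What the generator does *not* emulate: spindle/K-complex morphology, cardiac
and respiratory channels, pathology-specific slowing or hemispheric
asymmetry, and real between-subject montage variation. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that its
contrasts (stage ordering, MCS vs UWS modulation) are recovered when present
— they do not certify clinical performance on real DOC recordings.

## Determinism and problem sizes

Every stochastic step derives its seed from one master seed through a
counter (`derive_seed`), and all generators restore the caller's RNG state.
Re-running the full pipeline with an identical configuration reproduces the
JSON reports byte for byte; this is part of the test suite.

The test and acceptance cohorts are deliberately compact — e.g. 1 h synthetic
subjects, 100-epoch DOC recordings with a 50/50 day–night split, a 10-subject
feature-level LOSO cohort, 20 replicates for the MCS/UWS contrast — sizes
chosen so the full suite exercises every claim in a few minutes on one core
while keeping all statistical margins wide (binomial tolerances, 3-SE
windows) rather than tuned.

## Known limitations

* The five-class cut-off and cluster summaries on *real* healthy data
  (cut-off 0.035, cluster mean PE 0.83–0.88, root dissimilarities
  0.07–0.13 in the study this design follows) require the original
  recordings, which are not deposited; the package reproduces the procedure,
  and its synthetic analogues land in the same numeric neighbourhood, but
  those published values are reference magnitudes, not regression targets.
* Ocular correction is a global linear regression; it does not model
  nonstationary artifact coupling.
* The feedforward-net route searches width and weight decay but not depth.
* EDF I/O is not provided; recordings exchange as plain numeric matrices with
  a JSON sidecar, plus CSV/YAML for annotations and configuration.
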