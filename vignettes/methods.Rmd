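---
title: "Models and methods behind mifcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mifcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifcdyn)
```

mifcdyn implements a task-fMRI analysis chain for parcellated BOLD
timeseries in a two-group design (a healthy-control-like group A and a
patient-like group B): mutual-information functional connectivity (miFC)
with condition masking and contrasts, phase-coherence brain-state dynamics
with complexity metrics, edge-wise max-T permutation inference, and a
receptor-availability partial least squares (PLS) with spatial spin nulls.
Every stage can be exercised on a synthetic cohort whose planted effects
are known, so the whole chain is verifiable without imaging data. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not show.

## Mutual-information functional connectivity

Each region's timeseries is z-scored (mean 0, sample SD 1) and each pair
is scored with the plug-in mutual information

$$ I(X;Y) \;=\; \sum_{i,j} \hat p_{ij}\,
   \log_2\!\frac{\hat p_{ij}}{\hat p_{i\cdot}\,\hat p_{\cdot j}} \quad
   \text{(bits)}, $$

where the cells are an equiprobable (quantile) binning of each marginal
into `n_bins` bins (default 8). Quantile binning uses average-tie ranks and
deterministic rank-quantile edges, which makes the estimate exactly
invariant under strictly monotone transforms of either input — a property
the test suite asserts. The estimator floor is `8 * n_bins` volumes for
whole runs; the pipeline relaxes it to `4 * n_bins` for condition-restricted
segments, which cover only part of a run by construction.

Two estimator facts matter for interpretation:

* **Plug-in bias.** For independent inputs of length $T$ the estimate is
  biased upward by roughly $(B-1)^2 / (2T\ln 2)$ bits ($B$ bins). At
  $T = 300$, $B = 8$ this is about 0.12 bits; it is common to every edge
  and largely cancels in group contrasts.
* **Discretization gap.** The estimator converges to the mutual
  information *of the binned pair*, which is strictly below the continuous
  MI (data-processing inequality). For a bivariate Gaussian with
  $\rho = 0.8$, the exact octile-binned MI is 0.6343 bits versus the
  continuous $-\tfrac12\log_2(1-\rho^2) = 0.7370$ bits — an irreducible
  13.9% gap at 8 bins. The test suite verifies the estimator against the
  binned limit (its true target), and separately documents the gap against
  the continuous closed form. Comparisons *between* conditions or groups
  use the same binning and are unaffected.

Condition-restricted segments are re-z-scored after restriction:
restriction changes the moments, and the estimator's contract takes
standardized input. Because of the monotone-invariance this affects
nothing numerically; it keeps the input contract honest.

## Task design and volume selection

A condition's "task timeseries" is a per-second 0/1 boxcar built from the
event table (onset/duration/condition, seconds, 0-based onsets). It is
convolved with the canonical double-gamma haemodynamic response
(response gamma shape 6 rate 1, undershoot shape 16 rate 1 scaled 1/6,
32 s support, unit peak; peak at ~5 s), truncated to the acquisition,
and sampled at volume timestamps $v \cdot TR$ (start-of-volume
convention, slice timing assumed corrected upstream). After convolution
the regressor is continuous, so a condition's volumes are those at or
above 50% of the regressor's maximum (configurable): this captures the
HRF-lagged plateau of each block or trial. Thresholding the raw,
unconvolved boxcar is supported as an alternative
(`condition_volumes(convolved = FALSE)`). Unit-peak normalization of the
kernel is irrelevant to a fraction-of-max threshold and to miFC on
z-scored data.

## Edge-wise group inference

Per edge, a pooled-variance two-sample t statistic (group A minus B;
Welch available by flag) compares the subjects' matrices. Familywise error
across the ~23k edges is controlled by max-T permutation: group labels are
shuffled `n_perm` times, the maximum |t| over edges recorded per shuffle,
and each edge's corrected p-value is $(1 + \#\{\max|t| \ge
|t_{obs}|\})/(n_{perm}+1)$ — never exactly zero, monotone in $|t|$, and
valid under exchangeability. Defaults: `n_perm = 10000` for direct calls
(1000 in the pipeline's test-scale defaults), $\alpha = 0.05$.

Derived summaries follow the field's conventions: direction proportions
(percent of significant edges stronger in each group), per-region degree
(row sums of the significance mask), eigenvector centrality of each
subject's whole-task miFC matrix (leading eigenvector, unit norm, oriented
nonnegative — well-defined by Perron–Frobenius since miFC is nonnegative),
and the per-region group difference of mean centrality in A − B
orientation, recorded in the output metadata. Whole-task matrices are used
for centrality and degree because they are the only per-subject matrices
defined for both tasks.

## Brain-state dynamics (HBSD)

Each region's timeseries is demeaned, band-passed with a 2nd-order
Butterworth (0.02–0.1 Hz, applied forward-backward so the phase is not
shifted), and Hilbert-transformed to an analytic signal
$X(t) = A(t)\cos\theta(t)$. The instantaneous phase-coherence between
regions $n, p$ at volume $t$ is $\cos(\theta_{n,t} - \theta_{p,t})$. For
each of nine template networks (eight canonical cortical networks plus the
ventromedial reward/anti-reward network, VMN), the mean coherence over the
template's within-network pairs (upper triangle, diagonal omitted) is
computed in O(regions) per volume via
$(|\sum_k e^{i\theta_k}|^2 - m)/(m(m-1))$; the volume is labelled with the
argmax network. Near-exact ties (within 1e-10 of the maximum) resolve to
the first template in the fixed order and are logged. Negative coherence
values enter the mean as-is.

Dynamics metrics per subject and task:

* **Probability** — fraction of volumes carrying a state's label;
  **lifetime** — that count times TR, i.e. total assigned duration. By
  construction lifetime equals probability × total duration, exactly; the
  mean consecutive dwell time is reported alongside as a distinct column
  (`mean_dwell`) because the two are often conflated.
* **LZ76** — Kaspar–Schuster exhaustive-history phrase count of the
  4-bit binarized label sequence (state index in fixed template order,
  big-endian, concatenated). Verified against a brute-force parser.
* **BDMC** — block decomposition: the sequence is cut into
  non-overlapping 12-bit blocks (remainder dropped) and scored
  $\sum_{\text{unique blocks}} [\mathrm{CTM}(b) + \log_2 m_b]$. The
  packaged CTM table is a synthetic, entropy-based stand-in
  ($\mathrm{CTM}(b) = 12\,H_2(p_1)$), generated in code and labelled in
  the output metadata (`ctm_provenance`); a table of true coding-theorem
  values can be passed via `bdmc(table = ...)`. The stand-in preserves
  the orderings the analyses use (incompressible sequences score far above
  periodic ones, via the multiplicity term), but absolute BDMC values are
  not comparable to published CTM-based numbers.
* **Transition entropy**, orders 0–4 — Shannon entropy of the empirical
  distribution of contiguous (N+1)-length label blocks (the
  "block entropy" reading); a conditional-entropy variant is available
  behind a flag.

## Receptor PLS with spin nulls

Molecular predictors (per-region MOR and D2DR availability) are z-scored
across regions then min-max rescaled to [0, 1]. Functional responses (per
task: eigenvector-centrality group difference and degree) are
column-standardized before fitting because they live on incommensurate
scales. A deflation-based NIPALS PLS2 regresses responses on predictors;
per component the package reports *both* the share of total X–Y
cross-covariance (squared singular-value share of the cross-covariance
matrix) and the share of Y variance explained, since published "percent
variance" figures are ambiguous between the two. VIP scores follow
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}$
with $\sum_j \mathrm{VIP}_j^2 = p$ as an exact identity (asserted in
tests); VIP > 1 marks an important predictor.

Significance uses spatial spin permutations: per iteration a Haar-random
3D rotation is applied to one hemisphere's cortical centroids and its
mirror image to the other, and each parcel maps to the nearest rotated
parcel within its hemisphere, conflicts resolved greedily in order of
increasing distance (deterministic given the rotation; the identity
rotation yields the identity map). Subcortical regions cannot be
spherically rotated and are uniformly permuted among themselves — the
conventional fallback, recorded in metadata. Spin p-values are two-tailed
permutation p-values with the +1 correction. Spearman correlations between
the component-1 predictor score and each response get parametric and spin
p-values side by side.

## The synthetic cohort: what it emulates

`generate_cohort()` realizes, per subject and task:

1. a hidden semi-Markov state sequence over the nine networks
   (gamma-distributed dwells, shape 4, mean `state_mean_dwell = 30` s,
   8 s floor — dwell lengths in the range dynamic-FC studies report);
2. per network, a band-limited (0.02–0.1 Hz) unit-variance latent at 1 s
   resolution, synthesized spectrally; its amplitude is multiplied by
   `state_boost` while its network is the hidden state;
3. region neural signal = loading-weighted sum of its networks' latents
   (loadings uniform in 0.8–1.2), plus a region-private band-limited
   fluctuation of SD `private_sd`, plus planted network-pair latents of
   amplitude `coupling_base` × group coupling gain × condition-window
   gain;
4. convolution with the canonical HRF, per-region standardization (BOLD
   units are arbitrary, so the signal is defined at unit SD), sampling at
   TR, and white measurement noise of SD `noise_sd`.

The defaults are the package's study conditions, chosen once on
mechanism: `private_sd = 1.5` sets the baseline within-network coupled
variance share to $1/(1+1.5^2) \approx 0.31$, in the range of empirical
within-network FC; `state_boost = 5` raises the dominant network's share
to $\approx 0.92$, a strong episodic dominance — the planted effect the
state-assignment method is supposed to find; `noise_sd = 0.5` (SNR 2
against the unit-SD signal) reflects the high temporal SNR of
parcel-averaged task data. The private neural fluctuation is part of the
neural model rather than the measurement model because without it every
region of a network would be a noiseless copy of the same latent and
*all* templates would sit at coherence 1 — no state could dominate.
Group and condition effects multiply the coupling amplitude of named
network pairs, at 1 s neural resolution *before* HRF convolution,
matching the causal ordering the convolved regressor assumes.

Default acquisition geometry: TR 2 s (configurable everywhere), a 10 min
event-related MID run (300 volumes; 60 trials of 4 s anticipation with
reward/neutral/loss drawn evenly, 0.5 s target, 2 s outcome, 2.5 s ITI)
and an 8 min block cue-reactivity run (240 volumes; 20 s drug/neutral
blocks, 10 s rest). These timings are stand-ins, not reproductions of any
study's protocol; event counts auto-fit shorter acquisitions.

Receptor maps are Gaussian-process draws on the parcel centroids
(covariance $e^{-d/\ell}$, great-circle distance between cortical
centroids), shifted positive, with VMN regions multiplied by an
enrichment factor (3 for MOR, 1.5 for D2DR) — emulating the
disproportionate subcortical availability of opioid receptors. The
synthetic parcellation places 200 cortical parcels hemisphere-symmetrically
on the unit sphere (low-discrepancy lattice) and 14 subcortical regions at
interior points; the VMN overlaps the default-mode network in six medial
cortical parcels, so overlapping membership is exercised throughout.

**What passing on this cohort does not show.** The generator has no
head-motion, physiological noise, scanner drift, spatial smoothing or
inter-subject anatomical variability; its "networks" are block-structured
by construction rather than estimated; and its receptor maps share the
GP smoothness family with the spin null. Recovery results therefore
demonstrate that the implementations are correct and calibrated under the
model's assumptions — not that the method is robust to real acquisition
artefacts.

## Validation design choices

* **FWER calibration** uses 500 independent null cohorts (22 vs 25
  subjects, 50 regions, 240 volumes, 1000 permutations each) and checks
  the empirical familywise error against [0.02, 0.09] at α = 0.05 —
  the two-sided binomial range around 0.05 at this replicate count.
* **Power simulation** plants 20 edges at Cohen's d = 1.2 among 15
  regions (105 edges) with a subject-level common factor carrying 50% of
  edge variance — the global-connectivity component real FC matrices
  show, which is also what gives the max-T statistic its power advantage
  over Bonferroni. A sobering arithmetic fact is worth recording: at
  22 vs 25 subjects, d = 1.2 has noncentrality ~4.1, while familywise
  max-T thresholds run ~3.3-4.6 depending on the effective number of
  independent edges, so expected sensitivity at this design is ~0.67
  (long-run estimate over 100 replicates) and ~0.38 under fully
  independent edges. Reaching 80% sensitivity at this sample size would
  require an edge-correlation structure with fewer than ~25 effective
  tests — a dial this package refuses to turn to make a validation look
  better; the simulation reports what familywise correction actually
  costs, and the false-positive side of the check (familywise consistency)
  holds throughout.
* **State recovery** scores assigned labels against the generator's
  hidden sequence shifted by the canonical ~5 s haemodynamic delay
  (`round(5 / TR)` volumes) — the generator convolves the neural state
  signal with the HRF, so the BOLD signature of a state change arrives one
  HRF peak later — and excludes volumes within 2 volumes of a hidden
  transition, where the smeared response makes the label genuinely
  ambiguous. Threshold: mean accuracy ≥ 0.80.
* **PLS planted recovery and calibration** use GP maps with
  autocorrelation length 0.3 rad. Much smoother maps (length ≈ 1 rad)
  carry so few spatial degrees of freedom that *any* map-level
  correlation is well explained by smoothness alone and the spin test
  correctly withholds significance — worth remembering when interpreting
  spin p-values on very smooth maps.
* **Problem sizes.** The default pipeline scale (47 subjects, 214
  regions, two tasks, 1000 permutations, 1000 spins) completes in about a
  minute on one CPU; the calibration suites use the sizes above so the
  full test suite stays in the tens of minutes.

## Degenerate inputs and numerical conventions

Zero-variance regions are rejected by name; all-zero condition regressors
yield empty volume sets, and empty significance masks yield empty (not
error) direction tables; constant response columns are left at zero after
centering with a warning; sequences shorter than one BDMC block score 0
with a warning; the all-zero connectivity matrix has no centrality and is
rejected. Permutation p-values use the +1 estimator and can never be 0.
All randomness flows from one master seed through named substreams
(`derive_seed`), so enabling or disabling a stage never shifts another
stage's draws, and identical configurations are bit-identical.
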