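---
title: "Dynamic inter-brain synchrony states: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic inter-brain synchrony states: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dibs)
```

## Overview

`dibs` implements a complete analysis chain for *dynamic inter-brain
synchrony* (IBS) in dyadic fNIRS hyperscanning. Two people perform
communication tasks while oxyhemoglobin (HbO) concentration changes are
recorded over matched cortical regions of interest (ROIs). The pipeline
quantifies moment-to-moment synchrony between the two brains, identifies a
small set of recurring inter-brain network states, and relates the temporal
expression of those states to communication behavior:

1. **Preprocessing** — global PCA spatial filtering of systemic physiology,
   correlation-based signal improvement (CBSI) for motion, and removal of
   the unsteady first and last 30 s of each task session.
2. **Coherence** — Morlet wavelet transform coherence (WTC) between every
   cross-participant ROI pairing, Fisher z-transformed.
3. **ROI pairing and band selection** — reciprocal cross-participant
   pairings averaged into `n(n+1)/2` unordered ROI combinations (91 for 13
   ROIs); a frequency band of interest (FOI) selected where task-period
   synchrony exceeds rest-period synchrony by paired t-tests across dyads.
4. **Sliding windows** — FOI-averaged coherence in 10-s windows advanced
   in 1-s steps over the concatenated 480-s task period (471 windows).
5. **State clustering** — two-level Manhattan-distance k-means: group-level
   centroids at the elbow-selected k, then per-dyad clustering seeded from
   the group centroids; states ordered by descending global efficiency.
6. **Metrics and inference** — weighted-graph global efficiency and
   characteristic path length of state centroids; occurrence rates and
   transition counts; repeated-measures ANOVA with partial eta squared and
   Bonferroni post-hocs; Pearson brain-behavior correlations; and a
   pseudo-dyad permutation null.

Because raw hyperscanning recordings are rarely shareable, the package
carries a first-class synthetic-data module (`sim_config()`,
`generate_cohort()`) that plants known coupling states in realistic
hemodynamic noise. Every downstream stage is validated by recovering what
was planted.

## The synthetic dyad model

### Signal layers

Each participant's ROI signal is a sum of layers:

* **Broadband neural background** — band-limited (0.01–0.5 Hz) Gaussian
  noise, independent per ROI, amplitude `neural = 0.6`.
* **Systemic physiology** — one time course per layer per participant,
  projected onto all ROIs with a smooth random spatial gain (0.6–1.4):
  very-low-frequency drift (< 0.01 Hz, amplitude 1.0), Mayer waves
  (~0.1 Hz, 0.3), respiration (~0.3 Hz, 0.4), and cardiac pulsation
  (~1.2 Hz, 0.5). Modeling these as *whole-head* components is what gives
  the PCA spatial filter a real target; the Mayer amplitude is kept small
  because it sits inside the usual synchrony band and acts as a deliberate
  confound knob.
* **Motion** — Poisson spikes (0.5/min) with exponential decay, shared by
  both chromophores of a participant across channels. Because motion moves
  HbO and HbR in the *same* direction while hemodynamics move them in
  opposite directions, CBSI can cancel it.
* **HbR** — `hbr_ratio` (-0.5) times the ROI's HbO content plus
  independent white noise, reproducing the physiological anti-correlation.

### Planted coupling states

A latent state sequence (1-s resolution) runs through the recording. Each
state `s` carries a symmetric coupling matrix; every connected component of
its positive entries forms a *module* driven by a single dyad-common
band-limited source confined to `coupling_band` (0.10–0.19 Hz). Member
ROIs of both participants receive the source scaled by
`sqrt(mean edge strength)` with a random per-participant gain *and sign*.
Three design points deserve emphasis:

* **Low-rank coupling.** An early per-pair formulation (an independent
  shared source for every coupled ROI pair) fails structurally: in a dense
  state each ROI accumulates many independent sources, so every pair's own
  source is drowned by the others and measured coherence *falls* as
  density rises. One source per module matches both the physics (shared
  engagement driving a network) and the dense-state/high-synchrony
  structure that state clustering is supposed to find.
* **Signed loadings.** With all-positive loadings a fully-coupled state is
  spatially indistinguishable from a global systemic component, and the
  PCA filter removes it. Coherence is invariant to loading sign, so signed
  loadings decouple the coupling subspace from the global direction
  without changing any pairwise synchrony. Empirically the z-coherence
  tiers survive preprocessing nearly unchanged only with signed loadings.
* **Amplitude tiers.** Default states form tiers mirroring the
  dense-efficient / sparse-inefficient structure reported for group
  communication: state 1 couples every ROI at strength 0.8, later states
  couple progressively smaller, staggered ROI subsets at strengths
  decreasing geometrically to 0.1.

During rest sessions the coupling amplitude is multiplied by
`rest_coupling_scale` (0.05): synchrony is a task phenomenon, which is what
the FOI selection exploits.

### State dynamics

Dwell times are exponential with per-state means rescaled by
`(1 - sum(p^2)) / (1 - p[i])` so that long-run occupancy converges exactly
to the configured targets `p` — without this correction a semi-Markov chain
with uniform dwells visits rare states too often. Defaults mirror the
study conditions: occupancy targets (0.08, 0.33, 0.59) during the creative
task and (0.06, 0.19, 0.75) during the control task, and mean dwells of
25 s / 40 s, which reproduce the direction and rough size of the reported
transition counts (about 9.6 vs 5.9 switches per 240-s task).

`generate_cohort()` additionally draws a cohort-level *master* sequence
that each dyad follows per dwell segment with probability `state_share`
(default 0.5). All dyads experienced the same session timeline, and the
group-level clustering stage averages windowed matrices *across dyads*
before clustering — an operation that presupposes partial temporal
alignment. With fully independent sequences the group average is a
near-constant blend and carries no recoverable centroids at any coupling
strength; with realistic partial alignment the group centroids become
informative. The parameter makes this assumption explicit and tunable.

### Behavior

Response logs emulate turn-taking idea generation: alternating speakers,
exponential inter-response gaps, occasional "pass" turns. With probability
`convergence_prob` a response stays in the previous response's category
(the basis of the index of cooperation); response keys are drawn without
replacement from a Zipf-weighted inventory so that cohort-level
originality (responses produced by at most 5% of participants) is
meaningful. In cohorts, a dyad's convergence probability and rare-item
bias increase with its realized state-1 occupancy (`behavior_link`), which
plants the positive brain-behavior correlation direction.

## Numerical choices

* **Wavelet transform.** Morlet with `omega0 = 6`; geometric scale grid at
  8 or more voices per octave spanning periods 1/0.7 Hz to 1/0.01 Hz;
  FFT-based transform padded to at least twice the series length so that
  long-scale wavelets never wrap circularly (with shorter padding the
  transform disagrees with a direct time-domain convolution oracle).
  Scale-to-frequency conversion uses the Morlet Fourier factor
  `4*pi/(omega0 + sqrt(2 + omega0^2))`.
* **Coherence smoothing.** Gaussian in time with standard deviation equal
  to the scale, boxcar across scales 0.6 octaves wide. With identical
  non-negative weights on cross- and auto-spectra, Cauchy-Schwarz bounds
  the squared coherence by 1 up to rounding; values are clamped to [0, 1]
  and a warning fires if the overshoot ever exceeds 1e-9.
* **Cone of influence.** Points within one e-folding time (`sqrt(2) * s`)
  of the recording edges are flagged. Sliding windows use all points (the
  windows sit mid-recording), but the task/rest scale profiles used for
  band selection exclude flagged points: the short rest blocks sit at the
  recording boundaries where edge-padded smoothing inflates coherence,
  which would otherwise bias the task-rest contrast downward.
* **Fisher transform.** Applied to the coherence value `R` (not `R^2`),
  clipped at `1 - 1e-7`. Everything downstream of clustering is monotone
  in this choice.
* **L1 k-means.** Median centroid updates (the exact L1 minimizer);
  assignment by Manhattan distance; 1,000 random-initialization restarts
  by default, reading the method description's "iterated 1,000 times" as
  restarts (the standard local-minimum remedy) rather than Lloyd
  iterations, which are capped at 300 with label-stability convergence.
  Empty clusters are reseeded at the farthest point that does not orphan
  another cluster. The objective is asserted non-increasing whenever no
  reseeding occurred.
* **Elbow rule.** The validity index (mean within-cluster distance over
  mean between-centroid distance) is computed for k = 2..8 and extended on
  the left with a k = 1 pseudo-index (within-distance to the global
  median over the k = 2 between-distance) so the smallest k is selectable.
  The elbow is the point of maximum curvature located by the standard knee
  rule: normalize the curve to the unit square and take the k farthest
  below the endpoint chord; curves whose maximum below-chord deviation is
  under 0.12 (featureless declines, as produced by unstructured data) fall
  back to the smallest k. A literal second-difference argmax was measured
  first and recovered a planted k = 4 in 0 of 10 seeds while the knee rule
  recovered planted k = 2, 3, 4 in 10 of 10 each; the knee rule is the
  package's operationalization of "the elbow of the curve".
* **Two-level clustering.** Group-level centroids come from clustering the
  dyad-averaged window series. How the dyad level uses them is genuinely
  open (the method descriptions in this literature say only that group
  centroids initialize the individual analysis), so both readings are
  implemented: `dyad_update = "none"` labels each dyad's windows by the
  nearest group centroid and takes per-state medians as dyad centroids,
  while `dyad_update = "kmeans"` runs full per-dyad k-means from the group
  initialization. Labeling-only is the default because, measured on
  planted-state cohorts, the full update drifts toward dyad-specific
  noise: from a truth-centroid initialization full Lloyd iteration
  *reduced* label accuracy from about 0.90 to 0.77, and across cohorts
  labeling-only recovered planted states better. The centroid drift
  between levels is reported either way. States are relabeled by
  descending group-centroid global efficiency, so state 1 is always the
  densest network.
* **Graph metrics.** Fully weighted graphs (no sparsity threshold — any
  threshold would be an invented constant); edge length is the reciprocal
  weight; global efficiency is the mean inverse shortest-path length and
  the characteristic path length is the harmonic mean of shortest paths,
  with the arithmetic-mean variant attached for audit. Published
  magnitudes for these metrics depend on unreported network-construction
  settings, so they serve as ordering references (state 1 highest
  efficiency, lowest path length), not numeric targets.
* **RM-ANOVA.** Classical within-subject decomposition; sphericity is not
  corrected in the reported test (matching the conventional df report) but
  the Greenhouse-Geisser epsilon is computed and returned. Degenerate
  tables with zero residual variability return F = 0 (no effect) or
  F = Inf (pure effect) explicitly.
* **Pseudo-dyad permutations.** Participants are re-paired into perfect
  matchings that never reproduce a real dyad; per-participant wavelet
  transforms are cached once, so each permutation costs only the cross
  smoothing. Permutations reuse the real analysis's FOI and k (re-deriving
  a band per sham cohort would mostly yield empty bands and leave the
  procedure undefined); the non-significance criterion is omnibus
  p >= 0.05.

## Desk-scale problem sizes

Full-scale runs (13 ROIs, 10 Hz, 27 dyads, 300 permutations) are
reproducible with this package but take hours. The bundled validation
(`scripts/acceptance.R` and the heavier tests) uses documented desk-scale
sizes chosen so each suite finishes in minutes on one CPU:

* The cohort-level analysis keeps the study's 27 dyads and 13 ROIs — the
  cohort size matters because the band-selection threshold (p < 5e-6)
  needs the t distribution's tail at 26 df — but samples at 5 Hz and
  analyzes periods 2–30 s (the synchrony band and its surroundings).
* State-recovery cohorts use 10 dyads with equal state occupancy, 80-s
  mean dwells, `state_share = 0.8` and a master script in which every
  state is substantially expressed ([balanced_master_sequence()]) — the
  "well-separated planted states" regime that recovery tests are entitled
  to.
* Band-recovery cohorts plant constant task-only coupling (a single state)
  so the injected band is the only task-sensitive structure.
* The permutation null runs 100 permutations over an uncoupled 4-ROI
  cohort (the full default is 300).

## What passing validation does and does not show

The generator reproduces the *structure* of dyadic fNIRS hyperscanning —
band-limited shared coupling with state dynamics, systemic physiology,
motion, anti-correlated HbR, turn-taking behavior coupled to brain state —
but not optical physics (no photon transport, no channel geometry beyond
the lattice count), no between-dyad demographic variability, and no
task-evoked hemodynamic response shape. Recovery of planted states
therefore validates the pipeline's correctness and its statistical logic,
not the empirical claim that real communication produces these states.
Magnitude-level agreement with published group means is not expected from
synthetic cohorts; directions and orderings (which state is densest, which
task has more transitions, the sign of brain-behavior correlations) are.

## Known limitations

* Band selection needs cohorts of roughly 20+ dyads at the strict
  threshold; small pilot cohorts should loosen `foi_p_threshold`
  explicitly rather than expect the default to fire.
* The elbow on *group-averaged* windows under-estimates k when state
  occupancies are very unbalanced (the rare dense state contributes little
  group-mean variance); planted-k recovery is assessed on cohorts with
  balanced occupancy. When the planted states form amplitude tiers, the
  dominant dense-vs-sparse split can also legitimately swamp the validity
  curve (the knee reads k = 2); equal-separation distinct topologies are
  recovered reliably.
* The pseudo-dyad permutation check calibrates cleanly for the
  brain-behavior correlation, but the repeated-measures F-tests on state
  efficiency and occurrence are anti-conservative *by construction* in
  this analysis: states are relabeled by descending centroid efficiency
  and every dyad's windows are then assigned to those amplitude-sorted
  centroids, so per-dyad state metrics are systematically ordered even on
  fully uncoupled data (on an uncoupled synthetic cohort the globE
  RM-ANOVA rejects in essentially every sham permutation). A fraction of
  non-significant sham permutations near one should therefore not be
  expected from this design; comparing the real cohort's F statistic
  against the permutation distribution of F would be the calibrated
  alternative.
* Window-label transition counts include label noise from windows striding
  dwell boundaries, so absolute transition counts run higher than the
  latent switching rate; between-task comparisons remain valid because the
  noise is common to both tasks.
* Only the HbO chain is analyzed; CBSI-corrected HbR is retained for audit
  but no HbR-based synchrony is computed.
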