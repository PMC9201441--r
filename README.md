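# dibs — dynamic inter-brain synchrony states from dyadic fNIRS hyperscanning

`dibs` is an R package for analysing **dynamic inter-brain synchrony
(IBS)** in dyadic fNIRS hyperscanning experiments: two people communicate
while oxyhemoglobin (HbO) signals are recorded over matched cortical
regions of interest (ROIs). Instead of assuming synchrony is constant over
a session, the pipeline tracks it window by window, finds a small set of
recurring **inter-brain network states**, and relates their temporal
expression to communication behavior.

It is aimed at hyperscanning researchers who want a tested, scriptable
version of this analysis, and at methodologists who want to probe its
statistical behavior on synthetic data with known ground truth.

## The analysis

For each dyad, with HbO series `x`, `y` over ROIs:

1. **Preprocessing.** Global PCA spatial filtering removes systemic
   physiology shared across channels; correlation-based signal improvement
   (CBSI) cancels motion using the expected HbO/HbR anti-correlation
   (`x0 = (x - a*y)/2`, `a = sd(x)/sd(y)`, `y0 = -x0/a`); the unsteady
   first and last 30 s of each task session are trimmed, leaving 480 s of
   task data from two 5-minute sessions.
2. **Wavelet coherence.** Morlet (omega0 = 6) wavelet transform coherence

       R^2(s, t) = |S(W_xy / s)|^2 / ( S(|W_x|^2 / s) * S(|W_y|^2 / s) )

   with Gaussian-in-time / boxcar-across-scale smoothing `S`, computed for
   every cross-participant ROI pairing and Fisher z-transformed. The two
   reciprocal pairings of each unordered ROI pair are averaged: 13 ROIs
   give 91 ROI combinations per dyad.
3. **Frequency band of interest (FOI).** Per scale and ROI combination,
   paired t-tests across dyads compare task-period versus rest-period
   synchrony (threshold p < 5e-6, no correction); the largest contiguous
   run of significant scales — typically 0.10–0.19 Hz — is the band
   analysed further.
4. **Sliding windows.** Band-averaged coherence in 10-s windows advanced
   in 1-s steps over the concatenated task period: 471 windowed 13 x 13
   IBS matrices per dyad.
5. **State clustering.** Two-level Manhattan-distance k-means (median
   centroids, 1,000 restarts): group-level centroids at the
   elbow-selected k on the dyad-averaged windows, then per-dyad labeling
   seeded by the group centroids. States are ordered by descending global
   efficiency, so state 1 is the densest inter-brain network.
6. **Metrics and inference.** Weighted-graph global efficiency
   (`mean(1/d_ij)`) and harmonic-mean characteristic path length of state
   centroids; per-task occurrence rates and transition counts;
   repeated-measures ANOVA with partial eta squared and Bonferroni
   post-hocs; Pearson correlations between state occurrence and behavior
   (fluency, originality, flexibility, index of cooperation
   `IOC = converge / (group fluency - converge)`); and a pseudo-dyad
   permutation null in which participants are re-paired into sham dyads
   and the whole analysis is re-run.

Because raw hyperscanning recordings are rarely shareable, the package
includes a first-class synthetic-data generator that plants latent
coupling states (band-limited dyad-common sources over ROI modules) in
realistic hemodynamic noise — systemic drift, Mayer waves, respiration,
cardiac pulsation, motion spikes, anti-correlated HbR — plus turn-taking
behavioral logs coupled to the latent states. Every stage of the pipeline
is validated by recovering what the generator planted. See the methods
vignette (`vignettes/dibs-methods.Rmd`) for the model and all numerical
choices.

## Worked example

```r
library(dibs)

# a small synthetic cohort: 5 dyads, 4 ROIs, short sessions
cfg <- sim_config(
  sampling_rate = 5, n_rois = 4,
  session_plan = data.frame(label = c("rest", "taskA", "taskB", "rest"),
                            duration = c(60, 120, 120, 30)),
  seed = 30)
cohort <- generate_cohort(5, cfg, seed = 30, state_share = 0.7)

res <- run_pipeline(cohort, pipeline_config(
  wavelet = wavelet_spec(voices_per_octave = 8, period_range = c(2, 30)),
  preprocess = preprocess_config(trim_head = 10, trim_tail = 10),
  foi_p_threshold = 0.05,   # permissive band threshold for this tiny cohort
  k = 3, n_replicates = 50, seed = 4))

cat("FOI:", res$foi$f_lo, "-", res$foi$f_hi, "\n")
head(res$metrics)
res$stats$globE_states$F
```

Printed output from this exact script:

```
FOI: 0.08105247 - 0.1621049
   dyad  task state occurrence transitions     globE       Lp
1 dyad1 taskA     1  0.2291667           4 0.7950912 1.257717
2 dyad1 taskA     2  0.1979167           4 0.6854846 1.458822
3 dyad1 taskA     3  0.5729167           4 0.6083964 1.643665
4 dyad1 taskB     1  0.0000000           4 0.7950912 1.257717
5 dyad1 taskB     2  0.7684211           4 0.6854846 1.458822
6 dyad1 taskB     3  0.2315789           4 0.6083964 1.643665
> res$stats$globE_states$F
[1] 20.39923
```

The selected band sits inside the planted 0.10–0.19 Hz coupling band (a
small cohort at a permissive threshold recovers its lower half); state 1
has the highest global efficiency (0.795) and shortest path length
(1.26), and occurrence rates within each dyad and task sum to one.
`res$metrics` is a tidy per-dyad table of occurrence, transitions and
centroid graph metrics per state; `res$stats` holds the repeated-measures
tests and brain-behavior correlations; `res$behavior` the fluency /
originality / flexibility / IOC scores.

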