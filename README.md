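# stimselect

Quantifies how *selectively* different peripheral-nerve stimulation
paradigms drive limb movement, starting from pose-estimation keypoint
trajectories. The motivating contrast is temporal interference stimulation
(TIS) — two kilohertz sinusoidal carriers whose superposition carries a
low-frequency envelope at |f1 − f2| — versus conventional charge-balanced
biphasic pulses, delivered through many electrode configurations of a
64-contact nerve cuff. The package is aimed at neural-engineering and
computational-ethology groups who need the full quantification chain, plus
a synthetic ground-truth generator to validate every stage of it.

## What it computes

Given per-frame keypoint tracks (10 hindlimb landmarks, x/y/likelihood at
60 fps) and a stimulation-epoch table:

1. **Preprocessing** — likelihood filter (< 0.5), per-keypoint median
   imputation, Euclidean flattening to a T×10 position matrix, z-scoring,
   and a velocity-based movement gate (rest baseline mean + 3 SD) that
   removes configurations that evoked no movement.
2. **Clustering arm** — 3-D kNN-graph spectral embedding, density-based
   clustering (core-distance / mutual-reachability rule with
   `min_cluster_size`, `min_samples`, `cluster_selection_epsilon`), k-means
   baseline, and **adjusted mutual information** between clusters and
   configurations, with row-shuffle and Gaussian-noise null controls:

   AMI = (I(U,V) − E[I]) / (½(H(U)+H(V)) − E[I]),

   E[I] computed under the fixed-marginal hypergeometric model.
3. **Syllable segmentation** — a sticky autoregressive hidden Markov model
   over a 3-D latent projection (AR-only phase: 50 iterations, kappa 1e9;
   full phase: 500 iterations, kappa 1e8), Viterbi-decoded into behavioral
   "syllables", with per-syllable kinematics and cosine-metric dendrograms.
4. **Selectivity score** — for configuration *i* with syllable proportions
   p_ij over its ON frames:

   H_i = −Σ_j p_ij log p_ij,  Score_i = 1 − H_i / log N,

   N the trial's total syllable count (1 = one configuration → one
   syllable; 0 = uniform over all syllables).
5. **Group statistics** — bootstrap of group means (m = 100, B = 1000,
   percentile 95% CIs), beta regression with a logit link on stimulation
   type / configuration / subject, Mann-Whitney U, Cohen's d, Cliff's
   delta.
6. **Configuration space & waveforms** — the 64-channel cuff sweep
   enumerations (TIS pair sweeps labeled 8(A−1)+B, bipolar and tripolar
   layouts), interference-envelope synthesis and estimation, and
   charge/charge-density/Shannon-criterion arithmetic for charge-balanced
   biphasic trains.

Because the recordings behind the motivating study are not deposited, the
package ships a first-class synthetic generator (`motif_library()`,
`generate_trial()`): stable 3-D latent VAR motifs emitted as keypoint
offsets around a hindlimb rest pose, 5 s ON / 5 s OFF epochs, tracking
noise and likelihood dropouts, in a *selective* regime (each configuration
its own motif) and a *nonselective* regime (all configurations share a few
similar motifs with within-epoch switching).

## Worked example

```r
library(stimselect)

labels <- enumerate_sweep(cuff_grid(), "TIS4")$label[1:8]
lib    <- motif_library(labels, regime = "selective", seed = 1)
trial  <- generate_trial(trial_spec(n_configs = 8, mode = "TIS4", seed = 1), lib)

prep <- preprocess_trial(trial$series, trial$epochs)
emb  <- embed(prep$values)                      # 4800 x 3 embedding
cl   <- cluster_density(emb$coords)
agreement_report(cl, prep$labels)$ami
#> [1] 0.6304739

lat <- pca_latents(prep$values)
fit <- fit_full(fit_ar_only(lat, seed = 1), lat)
sc  <- selectivity_score(syllable_config_table(fit$sequence, prep$epochs))
round(sc$score, 2)
#> [1] 0.74 1.00 0.97 1.00 0.98 1.00 0.75 0.78
```

The AMI of ~0.63 says the density clusters align well (but not perfectly)
with the eight configurations; the per-configuration scores near 1 say
each configuration's ON frames concentrate on essentially one syllable —
the selective phenotype. The same pipeline on the nonselective regime
yields AMI near 0 and scores around 0.5–0.7.

## The full analysis

Numbered drivers under `analysis/` reproduce the whole synthetic study and
write tables/figures under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort of selective + nonselective trials
Rscript analysis/02_preprocess.R    # position matrices + movement-gate report
Rscript analysis/03_cluster.R       # embeddings, clusters, AMI + null controls
Rscript analysis/04_syllables.R     # AR-HMM syllables, stats, dendrograms
Rscript analysis/05_selectivity.R   # scores, bootstrap, beta regression, effects
```

`run_pipeline(run_config(...))` performs the same chain programmatically.
On the bundled six-subject demo cohort (three selective interference
subjects, three nonselective biphasic subjects) the drivers print group
AMI 0.596 (TIS) vs 0.045 (biphasic) with both null controls at ~0,
bootstrap mean selectivity 0.912 vs 0.688 with non-overlapping 95% CIs,
and a beta-regression stimulation-type coefficient of 1.45 (p = 0.001),
with Cohen's d = 1.64 and Cliff's delta = 0.74.

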