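# mstnet

Minimum-spanning-tree analysis of EEG functional connectivity for
motor-imagery neurofeedback studies.

## What it does

Studies of motor-imagery (MI) brain–computer interfaces ask how the
brain's functional network reorganizes between a pre-feedback and a
feedback session. `mstnet` implements that comparison end to end for a
16-channel montage (AF3, AF4, FC3, FCz, FC4, C3, Cz, C4, T7, T8, CP3,
CPz, CP4, Pz, O1, O2):

- **Preprocessing**: zero-phase Butterworth band-pass [0.5, 30] Hz
  (order 8) and 50 Hz notch (order 4), decimation 512 → 128 Hz,
  exponential moving standardization, 2 s epochs at MI onset.
- **Spectra**: multitaper PSD at 0.5 Hz resolution; band power over
  half-open bands (α = [8, 12), β = [12, 30) Hz); frontal alpha
  asymmetry `FAA = ln(PSD_α(AF4) / PSD_α(AF3))`; relative power
  `RP = (PSD_x − PSD_baseline) / PSD_baseline` against the pre-onset
  rest baseline.
- **Connectivity**: phase lag index `PLI = |E{sgn Im X}|` and weighted
  phase lag index `WPLI = |E{Im X}| / E{|Im X|}` of the cross-spectrum
  X per electrode pair — estimators insensitive to zero-lag volume
  conduction — giving a 16 × 16 adjacency matrix per band.
- **Networks**: the maximum-weight spanning tree (Kruskal, deterministic
  ties) of each WPLI matrix, with degree k, betweenness centrality C_B,
  diameter D = d/M, leaf fraction Lf = L/M, tree hierarchy
  Th = L/(2·M·C_Bmax), global connectivity FC_glob = Σ w(e), and graph
  edit distance between label-matched trees (edge symmetric
  difference under unit costs).
- **Statistics**: network-based statistics (NBS) — edgewise paired t
  tests, |t| thresholding, connected components, sign-flip permutation
  control of the family-wise error — plus Wilcoxon signed-rank tests
  with Benjamini–Hochberg FDR over all metric-level comparisons.
- **Synthetic cohorts**: a generator of phase-coupled oscillator
  recordings (balanced left/right trials, two sessions, two groups,
  known coupling ground truth, optional volume-conduction mixing), so
  every stage is testable against ground truth.

See `vignettes/eeg-mst-networks.Rmd` for the methods account and the
design decisions.

## Worked example

Plant stronger α-band coupling on AF3–FC4 and O2–CP3 in the feedback
session of a 10-subject synthetic group, then run the full pipeline:

```r
library(mstnet)

base  <- data.frame(a = c("C3", "O1"), b = c("C4", "Pz"), freq = 10,
                    lag = c(pi/4, -pi/3), strength = 0.5, band = "alpha")
extra <- data.frame(a = c("AF3", "O2"), b = c("FC4", "CP3"), freq = 10,
                    lag = c(pi/3, pi/4), strength = 0.8, band = "alpha")

cfg <- study_config(
  protocol = protocol_config(groups = "VES", subjects_per_group = 10),
  coupling = list(pre = coupling_spec(base),
                  feedback = coupling_spec(rbind(base, extra))),
  noise    = noise_model(noise_sd = 1),
  nbs      = list(statistic = "intensity"),
  out_dir  = "readme-study",
  seed     = 42
)
res <- run_study(cfg)

print(res$nbs$VES)
#> <mst_nbs> 2 suprathreshold component(s), 1024 permutations, |t| > 2
#>   component 1: 2 edge(s), p = 0.959
#>   component 2: 10 edge(s), p = 0.001953

head(res$tree_metrics[, c("subject", "session", "diameter",
                          "leaf_fraction", "tree_hierarchy", "global_fc")], 4)
#>   subject  session  diameter leaf_fraction tree_hierarchy global_fc
#> 1   VES01      pre 0.4000000     0.6000000      0.4436620  2.683002
#> 2   VES01 feedback 0.6666667     0.2666667      0.1891892  4.179745
#> 3   VES02      pre 0.6000000     0.4000000      0.3333333  2.980496
#> 4   VES02 feedback 0.5333333     0.4000000      0.3088235  4.186578

gt <- res$group_trees[["VES.feedback"]]
head(gt$edges[order(-gt$edges$weight), ], 4)
#>     a   b    weight
#> 1 AF3 FC4 0.7076439
#> 2 CP3  O2 0.6932120
#> 3  Pz  O1 0.6124068
#> 4  C3  C4 0.5449341
```

Reading the output: the NBS finds one significant component
(p ≈ 0.002) — it contains both planted edges, whose session difference
in WPLI dwarfs the permutation null — and the feedback-session group
tree ranks exactly the planted couplings as its strongest edges
(WPLI ≈ 0.7 for strength-0.8 coupling under unit noise; band averaging
over noise-only bins keeps the value below 1). Per-subject tree
metrics and `res$ged$VES` (between-session graph edit distances,
mean ≈ 21.8 here) quantify the topology shift; all tables are also
written under `out_dir` (`connectivity/`, `trees/`, `spectra/`,
`tables/`, plus a `log.json` with the config hash and seed).

The same study can be driven from a YAML file via the thin CLI wrapper
(`inst/cli/mstnet run-study --config study.yaml`); the YAML fields
mirror the `study_config()` arguments (`seed`, `out_dir`, `protocol`,
`noise`, `band`, `coupling` as per-session entry lists, `preprocess`,
`analyses`, `nbs`), and `run_study()` writes the fully expanded config
alongside the results.

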