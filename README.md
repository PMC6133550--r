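# axokin

Quantification toolkit for studies of MAP7–kinesin-1 cooperation in cells and
axons. MAP7 (ensconsin) is a microtubule-associated protein that both binds
microtubules and recruits the kinesin-1 motor; characterizing that interplay
rests on three kinds of quantitative measurement, all implemented here for
anyone analyzing (or simulating) such experiments:

1. **FRAP binding kinetics** — normalization of three-region
   (bleached/reference/background) intensity traces and least-squares fitting
   of the diffusion-uncoupled binding model
   *R(t) = A·(1 − exp(−k_off·t))*, yielding the dissociation rate constant
   `k_off`, the half-life `t½ = ln2 / k_off`, and the mobile fraction
   (plateau *A*, "total recovery", in percent).
2. **Organelle motility** — change-point segmentation of particle
   trajectories into constant-speed runs and pauses (pause = movement below
   0.1 µm/s), with run speed *s = l/t* per segment, pause / speed-switch /
   sharp-turn frequencies (a sharp turn is a post-pause departure at > 90° to
   the previous run), kymograph construction, and per-cell → per-condition
   aggregation (mean ± SEM, t-tests, ANOVA + Tukey).
3. **Axon morphometry** — main-axon length (longest soma→tip path), branch
   counting above 10 µm with the terminal (distal 10%) vs interstitial
   split, branch-length statistics, and line-scan peak/background ratios,
   over SWC-format traces.

Because raw microscopy is not shipped, the package includes seeded
**synthetic-data generators** for all four input kinds (FRAP traces,
run-and-pause transport tracks with exact event logs, arbors with
ground-truth branch labels, line-scan profiles), so every estimator is
validated by parameter recovery. The methods vignette
(`vignettes/quantifying-map7-kinesin-dynamics.Rmd`) documents the models,
defaults and limits.

## Worked example

Simulate a noisy FRAP trace with fast-exchange ground truth
(`k_off = 0.27 s⁻¹`, 74% mobile fraction), normalize and fit it:

```r
library(axokin)
cfg <- frap_sim_config(k_off_true = 0.27, mobile_fraction_true = 74,
                       frame_interval = 1, n_post_frames = 60,
                       noise_sd = 24, seed = 7)
fit <- fit_recovery(normalize_trace(simulate_frap_trace(cfg)))
fit
#> FRAP fit (single-site binding):
#>   k_off          0.3308 1/s (SE 0.0192)
#>   t_half         2.095 s
#>   total recovery 77 % (SE 0.524)
#>   rss 767.8 on 60 points; converged: TRUE
t_half_from_koff(0.27)
#> [1] 2.567344
```

A single trace at 3%-of-range noise recovers the plateau to a few percent and
the rate to ~20%; averaging 200 fits recovers both to within a few percent
(see `analysis/01_frap_kinetics.R`). The half-life map reproduces published
rate/half-life pairs, e.g. `k_off = 0.27 s⁻¹ → t½ = 2.6 s`.

Motility, on simulated control-like mitochondria:

```r
ts <- simulate_transport_tracks(transport_sim_config(n_tracks = 20, seed = 1))
st <- do.call(rbind, lapply(split(ts$tracks, ts$tracks$track_id), track_stats))
sprintf("run speed %.2f um/s | pauses %.2f /min | sharp turns %.2f /min",
        mean(st$mean_run_speed, na.rm = TRUE), mean(st$pause_freq),
        mean(st$sharp_turn_freq))
#> [1] "run speed 0.64 um/s | pauses 1.32 /min | sharp turns 0.60 /min"
```

`ts$events` carries the exact ground-truth event log the estimates can be
checked against (`resolvable_events()` filters it to what a 2-s/0.1-µm/s
segmentation can resolve).

## Analysis workflow

Numbered drivers under `analysis/` reproduce the package's full analyses on
simulated data and write tables under `results/`:

| script | what it does |
|---|---|
| `01_frap_kinetics.R` | 200-trace FRAP recovery per construct (MAP7 N/FL/ΔC, KIF5C fragments); kinetic-identity table |
| `02_organelle_motility.R` | control vs MAP7-FL vs MAP7-ΔC mitochondria: per-cell motility statistics, condition comparisons, example kymograph |
| `03_axon_morphology.R` | arbor morphometry across three growth phenotypes, ANOVA + Tukey; line-scan comparison |
| `04_report.R` | collects the headline numbers into `results/report.json` |

Run them in order from the repository root:
`Rscript analysis/01_frap_kinetics.R` etc.

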