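# smtf — single-molecule transcription-factor imaging analysis

smtf is an R package for quantifying how nuclear transcription factors
explore and bind the genome in live-embryo fluorescence imaging. It is
aimed at groups doing single-particle tracking and light-sheet imaging of
nuclear factors who need the complete analysis chain — from spot
detection to bias-corrected binding kinetics — as tested, scriptable
functions rather than one-off scripts.

It covers six analyses:

- **Two-state displacement kinetics.** Displacement histograms at
  multiple frameshifts are fit to a bound/free Brownian mixture. Each
  component has apparent per-axis variance 2(D·Δτ + σ²) with σ the
  localization error; the free component is weighted by the probability
  of staying inside the axial detection slice (absorbing-slab
  eigenfunction series), giving the bound fraction F_bound and the two
  diffusion coefficients.
- **Residence times.** Long-exposure trajectory durations give a survival
  curve fit by SP(t) = F·exp(−k_ns·t) + (1−F)·exp(−k_s·t) after a 10⁻³
  probability cut and a convergence-selected minimum-duration threshold.
  The slow rate is bias-corrected with a stably bound histone control:
  k_s,true = k_s − k_bias, τ_res = 1/k_s,true.
- **TAMSD / anomalous diffusion.** Time- and ensemble-averaged MSD with
  log–log fitting of MSD(τ) = Γτ^α (α = 1 for free diffusion).
- **Hub enrichment.** Nucleus segmentation, per-nucleus percentile
  ("relative density") maps, and fold enrichment of trajectories in
  regions above the 85th percentile.
- **MS2 locus profiles.** 3D difference-of-Gaussians locus detection in a
  coat-protein channel, contrast filtering, nearest-neighbour tracking,
  2.18 µm locus / 2.6 µm-offset control windows, and radial intensity
  profiles of a TF channel normalized at the outermost radius.
- **FRAP.** Dark/control/pre-bleach correction and the reaction-dominant
  fit FRAP(t) = 1 − A·e^(−k_a·t) − B·e^(−k_b·t), reporting the slow
  half-recovery time ln 2 / k_slow.

A synthetic-data module generates every input class with known ground
truth (mixed bound/free trajectories observed through a finite detection
slice with bleaching and motion blur, nucleus images with concentration
hubs, two-channel MS2 volumes, FRAP traces), so each stage is testable as
a parameter-recovery problem without any raw microscopy data.

## Worked example

Simulate 10 ms single-molecule data at a 50% bound fraction, then recover
the kinetics:

```r
library(smtf)

p   <- kineticPreset("zld_like", nMolecules = 20000L, seed = 1L)
sim <- simulateTrajectories(p)
sim$tracks
#> TrackSet: 20000 trajectories, 275932 localizations
#>   frame interval 0.01 s, exposure 0.01 s

ds  <- compileDisplacements(sim$tracks, timepoints = 8L, jumpsPerTraj = 4L)
fitTwoState(ds, sliceDepth = 0.8)
#> Two-state fit: F_bound = 49.4%, D_bound = 0.253, D_free = 3.51 um^2/s
#>   sigma_loc = 29 nm, slice depth 0.80 um, loss 0.000151 (5 inits)
```

The generator placed 50% of molecules in the bound state; the fit
recovers 49.4% along with the two diffusion coefficients (truth 0.25 and
3.5 µm²/s) and the 30 nm localization error.

Residence times from 500 ms data, with the histone bias control:

```r
mk <- function(preset, seed)
  simulateTrajectories(kineticPreset(preset, nMolecules = 10000L,
    fBound = 1, kOffNonspecific = 2, kBleach = 0.15, frameInterval = 0.5,
    exposure = 0.5, nFrames = 200L, seed = seed))$tracks

sp  <- survivalProbability(mk("zld_like", 2L))
thr <- selectMinDurationThreshold(sp, 1:8)
fit <- fitDoubleExponential(sp, minDurationFrames = thr)
fit
#> Double-exponential SP fit: F = 0.36, k_ns = 2.273 /s, k_s = 0.329 /s
#>   min duration 1 frames, SP cut 1e-03

csp  <- survivalProbability(mk("his2b_like", 102L))
cfit <- fitDoubleExponential(csp,
          minDurationFrames = selectMinDurationThreshold(csp, 1:8))
biasCorrectResidenceTime(fit, cfit)
#> Residence time: tau_res = 5.56 s (k_s = 0.329, k_bias = 0.149, k_s,true = 0.180 /s)
```

The apparent slow off-rate (0.329/s) contains the 0.15/s bleaching shared
with the histone control; subtracting the control's slow rate recovers
the generator's 5.56 s specific residence time.

## Pipeline and command line

`runPipeline(config, stage)` chains the stages (`simulate`, `track`,
`kinetics`, `residence`, `msd`, `hubs`, `locus`, `frap`) from a YAML
configuration, writing CSV/TIFF outputs plus a JSON report embedding the
configuration hash and seed. A thin wrapper lives at
`inst/scripts/smtf`:

```sh
Rscript inst/scripts/smtf simulate --config cfg.yaml --seed 1 --out out/
```

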