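---
title: "Models and methods behind smtf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtf)
```

smtf analyses live-embryo fluorescence imaging of nuclear transcription
factors at three scales: single-molecule trajectories (binding kinetics and
mobility), bulk nuclear images (local concentration "hubs"), and two-channel
volumes around an active transcription site. Because raw microscopy data of
this kind are rarely shareable, every analysis stage is paired with a
synthetic-data generator that produces the same input class with known
ground truth; the test suite and the acceptance script validate each stage
as a parameter-recovery problem. This vignette explains the models, the
defaults and why they were chosen, the numerical decisions, and what the
synthetic validation does and does not establish about real data.

## Two-state displacement kinetics

Short-exposure (10 ms) trajectories mix chromatin-bound and freely
diffusing molecules. `compileDisplacements()` collects displacement
magnitudes at frameshifts $k = 1 \dots 7$ (lag $\Delta\tau = k\,\delta t$),
capping each trajectory's contribution at 4 jumps per frameshift so long
tracks do not dominate. `fitTwoState()` fits all frameshift histograms
jointly to a two-component model: each component is a 2D Brownian
displacement density with apparent per-axis variance
$2(D\,\Delta\tau + \sigma^2)$, where $\sigma$ is the localization error
(fitted, bounded to 10–80 nm, since typical single-molecule data do not
determine it independently). State transitions within a displacement are
excluded from the model.

Free molecules also diffuse axially and leave the detection slice
(thickness $\Delta z = 0.8\ \mu m$), so long lags lose free jumps.
`defocalizationSurvival()` gives the probability that a molecule starting
uniform in an absorbing slab is still inside after time $t$, via the
eigenfunction series
$\sum_{n\ \mathrm{odd}} \tfrac{8}{n^2\pi^2} e^{-n^2 \pi^2 D t / \Delta z^2}$
truncated at $10^{-8}$. The model's free-component weight averages this
survival over the jump start offsets the 4-jump cap admits: a jump at lag
$k\,\delta t$ may begin 0–3 frames into a track, and the molecule must
still be present at the jump's end. Using the bare survival from the track
start instead under-weights that selection and, on generator data,
biased the recovered bound fraction by about 6 points; the offset-averaged
weight is the exact expectation for the compilation protocol.

Histograms use 10 nm bins to 3 um — fine enough to resolve
localization-error-scale structure in the bound component without leaving
the well-populated range. The loss is the summed squared difference of
per-lag probability masses, all lags weighted equally; fitting the PDF (not
the CDF) matches how displacement distributions are usually presented.
Optimization runs L-BFGS-B from 5 deterministic pseudo-random starts within
the bounds; "best of 5" is the fit-iterations convention for this analysis.

Two numerical guards matter. First, with effectively single-population
data, $(F_{bound}, D_{free})$ becomes unidentified along a flat ridge: a
ghost free component with a very large $D_{free}$ defocalizes to
invisibility and only absorbs histogram noise. Profile fits at the
boundaries ($F = 1$ and $F = 0$) are therefore compared against the mixed
optimum and win when within 0.5% of its loss — a parsimony tie-break,
not a prior. Second, bound/free labels are enforced by ordering
$D_{bound} < D_{free}$ after fitting.

## Residence times from survival probabilities

At 500 ms exposures, mobile molecules blur into the background and only
bound molecules appear as spots, so trajectory *durations* carry binding
kinetics. `survivalProbability()` is the complement CDF of durations on the
integer-frame grid. `fitDoubleExponential()` fits
$SP(t) = F e^{-k_{ns} t} + (1-F) e^{-k_s t}$, with the fast rate capturing
short-lived (non-specific) binding and the slow rate long-lived (specific)
binding. Points below a $10^{-3}$ survival probability are discarded (the
data-poor tail), as are durations below a minimum frame count;
`selectMinDurationThreshold()` picks that threshold objectively as the
smallest value at which the refitted slow rate stabilizes to within 5%
of the next threshold's. After the cuts the curve is renormalized at its
first retained point (a documented flag disables this); renormalization
and the associated time shift rescale amplitudes but cannot move the
rates, which are the quantities carried forward. The fit is unweighted
least squares on the linear scale — the tail cut already limits the range,
and log-weighting would overweight exactly the noisiest points. If the
optimizer pushes all amplitude onto one exponential, that rate is reported
as the slow rate with a `degenerate` flag, which is the correct reading of
the single-component boundary.

The apparent slow rate still contains photobleaching and other shared
track-loss processes. A stably bound histone (His2B-like) control measures
that bias: its specific class never unbinds, so the slow rate of its
survival fit is the bias rate. Treating the processes as independent
Poisson losses, `biasCorrectResidenceTime()` computes
$k_{s,true} = k_s - k_{bias}$ and $\tau_{res} = 1/k_{s,true}$, refusing to
proceed when the bias reaches the signal.

## The trajectory generator

`simulateTrajectories()` is the forward model the kinetics stages invert:
molecules are bound (specific or non-specific, splitting `fSpecific`) or
free at steady state; lateral motion is Brownian with the state's $D$;
localizations carry i.i.d. Gaussian error per axis; tracks end at the
first of unbinding, bleaching, axial exit, or movie end. Free molecules
start uniform in the slab and are absorbed at its faces; the absorption is
checked with a Brownian-bridge crossing test inside each sub-step, because
a purely discrete check behaves like a wider slab (survival was visibly
above the eigenfunction series before this correction — the same bridge
test is used, with independent code, by the Monte-Carlo oracle in the test
suite).

Bound molecules ride a chromatin locus. Its axial excursions over a track
lifetime are small against the 0.8 um slab, and — decisively — the entire
His2B bias correction presumes that bound-population track loss is the
same for target and control. Giving each preset's bound state free axial
diffusion with its own $D_{bound}$ would violate that premise mechanically
(absorbing-slab loss at even $D = 0.01\ \mu m^2/s$ is $\sim 0.15/s$, the
size of the bleaching rate itself, and differs between presets). Bound
axial motion is therefore off by default and exposed as `dAxialBound` for
sensitivity studies.

At exposures of 100 ms and longer the generator renders a molecule only
when it is bound for at least 60% of the exposure
(`blurBoundFractionThreshold`): motion blur as a detectability gate rather
than rendered streaks, since the analyses consume localizations, not raw
movies.

Presets `zld_like` ($F_{bound} = 0.5$, $\tau_{res} = 5.56$ s), `bcd_like`
(0.5, 2.33 s) and `his2b_like` (0.88, never unbinding) encode the study
conditions the recovery suites target. The diffusion coefficients
($D_{bound}$ 0.25 / 0.3 / 0.15, $D_{free}$ 3.5 / 4.5 / 4.5 $\mu m^2/s$)
are implementation defaults in the range typical of nuclear factors,
ordered so the histone's bound mobility is lowest; they are not measured
values. Bleaching defaults to 0.15/s and the non-specific off-rate to 2/s
for the 500 ms analyses. Movies are 30 frames at 10 ms (displacement
statistics saturate well before movie end) and 200 frames at 500 ms
(the survival tail meets the $10^{-3}$ cut long before truncation).

## TAMSD and anomalous diffusion

`computeTamsd()` pools all overlapping pairs per lag (equivalent to
pair-count-weighted ensemble averaging of per-track time averages), up to
25% of the longest track — beyond that the estimator variance dominates.
`fitAnomalous()` regresses $\log(MSD/\tau)$ on $\log \tau$; for
$MSD = \Gamma \tau^{\alpha}$ the slope is $\alpha - 1$, zero for free
diffusion. The default range drops the first lag, which is dominated by
the $4\sigma^2$ localization-error offset. No attempt is made to decide
*which* sub-diffusion mechanism produces $\alpha < 1$; on these data the
exponent summarizes a mixture of effects.

## Hubs: segmentation, percentile maps, enrichment

`segmentNuclei()` fixes the pipeline order: Gaussian blur ($\sigma = 5$
px) → adaptive local-mean threshold (sensitivity 0.6, re-specified
operationally as intensity > local mean × (1.6 − sensitivity) over a
window of ~1/8 the image side) → dilation (disc radius 3) → optional ROI
mask → hole filling → labelling → area (default 1000–20000 px) and
eccentricity (≤ 0.9) cutoffs. Two additions are documented here: the
threshold carries a noise floor of 3 MADs of the high-frequency residual,
because a bare local-mean rule marks half of any structure-free field as
foreground (the original workflow removed such junk with hand-drawn masks
and manual curation, both deliberately out of scope); and the ROI argument
replaces the hand-drawn embryo-edge mask.

`relativeDensityMap()` ranks each nucleus's pixels into integer
percentiles (1–100, ties take the block maximum — the rule decides hub
membership in flat nuclei, where all pixels then sit at 100). Per-nucleus
ranking makes every downstream quantity invariant to per-nucleus affine
intensity rescaling. Trajectories get the mean percentile under their
localizations (out-of-nucleus points excluded); `foldEnrichment()` counts
trajectories (not localizations) above and below the threshold percentile
(default 85), accumulates counts and pixel areas across images, and forms
the density ratio.

The nucleus-image generator draws non-overlapping nuclei with interior
Gaussian hubs and declares as ground truth the pixels above the 85th
noiseless percentile. Its observation model gives each nucleus a dim
envelope-proximal rim (`rimWidth` 0.5 um, edge falloff 0.15 um): the
stated nucleus radius is the chromatin domain where molecules can sit,
while the bright core appears smaller, as PSF blur and envelope-proximal
depletion dim the outer shell of real nuclei. This matters: the
segmentation's fixed dilation exists to capture the full nucleus on such
soft images, and a calibration probe (noiseless discs) confirms the
segmented radius matches the molecule domain to ~0.2 px. On sharp-edged
discs the same pipeline over-reaches by ~4 px and the enrichment estimator
inherits a large artificial inflation — a property of the synthetic edge,
not of the method.

## MS2 locus profiles

`detectLoci()` runs a 3D difference of Gaussians (lateral sigmas 1.3/3.9
voxels, z scaled by voxel anisotropy; defaults chosen at the
diffraction-limited spot scale), a global threshold at median + 8 MADs of
the response, 26-connected labelling (union-find on the sparse
above-threshold set), a component-size filter, and intensity-weighted
centroids. `contrastFilter()` exploits the coat-protein channel's
geometry — dark nucleoplasm around a nuclear locus, bright cytoplasm
elsewhere: 1 um line profiles along x and y must have a mean max/min ratio
of at least 2 (config-exposed; no published value exists) for a detection
to count as nuclear, and the centroid is refined to the profile maximum.
Nearest-neighbour linking with a distance gate and no gap closing connects
timepoints.

`cropWindows()` cuts a 2.18 um window at the locus from the TF channel
(max-projected over ±2.5 um in z — one nuclear diameter, configurable
since no number is published), keeping it only when fully in-nucleus, and
scans angles in 10° steps for a control window at 2.6 um offset, dropping
the timepoint when no angle fits; the fixed-offset rule is the fully
specified one, and a randomly placed control is available as an option.
`averageAndRadialProfile()` averages windows pixelwise and profiles
one-pixel annuli about the centre, normalizing to 1 at the outermost
annulus with standard errors carried across windows.

## FRAP

`bleachCorrect()` follows the standard three-step normalization: subtract
the per-frame dark mean, divide by the (dark-subtracted) control mean to
cancel shared acquisition bleaching, then divide each spot by its own
pre-bleach mean. Whether the dark mean is also subtracted from the
controls before ratioing is ambiguous in common practice; both orders are
supported, the subtracting one being the default (the two differ only at
second order in dark/control contrast). Spots whose residual s.d. around
the mean curve exceeds 3× the median are discarded — an automated
stand-in, not a reconstruction, of the manual culling of drifting spots.
`fitReactionDominant()` fits
$1 - A e^{-k_a t} - B e^{-k_b t}$ from the first post-bleach frame
($t = 0$ there; the bleach interval itself is never fitted) and reports
$t_{1/2} = \ln 2 / k_{slow}$. Rates within 5% are flagged degenerate.
When the two rates are within a factor of ~3, single-experiment estimates
of the slow half time at 1% noise have ~6% spread; the recovery suites
therefore average estimates over three replicate experiments, just as
recovery curves are averaged over embryo replicates in practice.

## Problem sizes, seeds and reproducibility

The recovery suites run at the scales the analyses are designed for:
50,000 trajectories for bound fractions, 10,000 for residence times, 20
nucleus images × 500 trajectories for enrichment, 3 × 50 spots for FRAP
(the acceptance script reports these sizes alongside each value). Every
generator takes an explicit integer seed, restores the caller's RNG state
on exit, and is bit-reproducible given its parameter list; the pipeline
driver derives all stage streams from one configured seed and embeds the
configuration hash and seed in each JSON report.

## What the synthetic validation does not show

The generators emulate the observation processes the analyses correct for
— finite detection slice, bleaching, motion blur, localization error,
percentile-scale intensity structure, window geometry — but idealize much
else: Gaussian hubs and noise (no photon statistics), circular nuclei, no
nuclear-cycle choreography or chromatin mechanics, no fluorophore
photophysics (blinking), no state transitions within a track, and a
simplified detector/linker in place of full multi-target tracing.
Passing recovery tests therefore demonstrates that the estimators are
correctly implemented and unbiased under their own assumptions at
realistic scales — not that those assumptions hold in any particular
real data set.
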