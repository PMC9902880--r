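---
title: "Counting single miRNA molecules: models, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting single miRNA molecules: models, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smicount)
```

## The measurement

A signal-on digital hybridization assay: a dye-labelled capture probe is
immobilized on a coverslip, quenched by a pre-hybridized competitor strand,
and switched back on when the target miRNA displaces the competitor by
toehold-mediated strand displacement. Each captured target becomes one
diffraction-limited fluorescent spot in a wide-field EMCCD movie; abundance
is the number of spots, averaged over ten imaged regions per sample. A spot
only counts if its intensity trace is consistent with a *single* molecule:
organic dyes photobleach stochastically in single downward steps, so a spot
containing two or more dyes shows a multi-level staircase while a genuine
single molecule shows a one-level trace.

`smicount` implements this measurement end to end on synthetic data with
exact ground truth, so every stage (detection, trace classification,
calibration) can be validated quantitatively.

## Competitive binding model

The surface occupancy at equilibrium follows two-ligand competitive binding
with solution species in excess over surface sites (a 50 µl sample vastly
outnumbers the probes in a 5 mm spot, so ligand depletion is ignored):

$$\theta_T = \frac{c_T e / K_T}{1 + c_T e / K_T + c_2 / K_2},$$

where $c_T$, $c_2$ are target and competitor concentrations, $K_T$, $K_2$
their dissociation constants against the capture probe, and $e \in [0, 1]$ a
phenomenological relative capture efficiency (1 for the perfect-match
target; mismatched species are modelled by $e < 1$ rather than by sequence
thermodynamics, because only fold-differences in counts are observable in
this assay). The fluorescent emitter density is

$$\rho = \rho_{p1}\,(\theta_T + f_0\,\theta_{free}) + \rho_{ns},$$

with $f_0$ the fraction of free capture probes that were never paired with a
competitor (incomplete quenching; default 0.02) and $\rho_{ns}$ a
non-specific adsorption floor (default 0.002 µm⁻²).

The published assay characterization does not include affinities or rate
constants, only operating points: capture probe at 100 pM, competitor at
10 nM, competitor affinity designed *weaker* than the target's, and
displacement "almost reaching saturation" after a 60 min incubation. The
defaults encode exactly these constraints and nothing more:
`kd_target = 10 pM`, `kd_probe2 = 10 nM` (three decades of discrimination, a
plausible magnitude for a full-length versus toehold-shortened duplex), and
a pseudo-first-order rate $k_{obs} = k_{obs/c}(c_T + c_0)$ with
`k_obs_per_conc = 5e9 / (M min)` and a 1 pM kinetic baseline $c_0$, which
gives $\theta(60\,\mathrm{min})/\theta_{eq} = 0.96$ at the standard 10 pM
condition. All are configuration fields, not constants.

## What the simulator emulates — and what it does not

`sample_emitters()` draws a Poisson number of emitters (density × field
area) placed uniformly outside a border margin; a configurable fraction
carries two fluorophores (co-located molecules). Each fluorophore gets an
exponential photobleaching time (`bleach_rate` per frame, default 0.01 at
the 100 ms exposure, i.e. a 10 s mean bleach time — "a few or tens of
seconds"); `render_movie()` renders pixel-integrated Gaussian PSFs
(`psf_sigma` 1.3 px at 0.16 µm/px) and applies the EMCCD chain: Poisson
photons, Gamma(shape = photons, scale = gain) electron multiplication
(the standard excess-noise-factor-2 approximation; disabled at gain 1),
Gaussian read noise, offset, rounding, 16-bit clipping.

Deliberately not modelled: blinking (off by default — the single-molecule
argument rests on monotone bleaching; upward steps are grounds for
rejection, not a photophysics model), drift, uneven illumination, vectorial
PSFs, and sCMOS-style pixel-dependent noise. Passing tests on this
synthetic data therefore validate the *algorithms* under ideal optics; they
do not certify performance on real data with drift or structured
background.

The default photon budget (600 photons/frame, 20 background photons/px,
gain 30, read noise 10 counts) puts the peak-pixel SNR at 8.5
(`expected_snr()`), a realistic mid-range single-molecule setting: bright
enough for reliable detection on a 5-frame average, dim enough that the
trace classifier is genuinely exercised.

## Detection and photometry choices

Detection runs on the average of the first 5 frames (better SNR; early
bleaching losses stay small), band-passed with a difference of Gaussians
(σ 1.2/2.4 px around the 1.3 px PSF). The threshold is robust —
median + 5·MAD of the filtered image — because spot pixels would inflate a
plain mean/SD. Local maxima closer than 4 px are merged keeping the
brighter (ties towards smaller row, then column, making the detector fully
deterministic), positions are refined by a 3×3 intensity-weighted centroid,
and an 8 px border is excluded. Photometry sums a radius-3 aperture minus
the per-frame median of a 5–8 px annulus. None of these numbers come from
the original experiment (its analysis program is unpublished); they are
standard single-molecule practice and all sit in `detection_params()`.

The detector benchmark in the test suite (precision and recall ≥ 0.95 at
density 0.05 µm⁻², SNR 8.5, ten seeds) runs on static, non-bleaching
fields: it isolates detector quality. Losses from bleaching belong to the
acceptance-efficiency model below, and trace-classifier quality is
benchmarked separately on validation-length movies.

## Step counting

Traces are fitted piecewise-constant by binary segmentation with an L2
cost: change points are added greedily wherever they reduce the residual
sum of squares by more than $\beta \sigma^2 \log n$ ($\beta = 4$; minimum
segment length one frame). The noise scale $\sigma$ comes from the median
absolute successive difference, which ignores a handful of genuine steps. A
step must therefore exceed ≈ $\sqrt{4 \beta \log n / n}\,\sigma$ to be
found — about 1.3 σ in a 30-frame trace — while a single 3 σ outlier frame
stays below the penalty. Scaling trace and noise estimate together leaves
the segmentation invariant. On short traces the greedy solution coincides
with the exhaustive dynamic-programming optimum (verified in the tests up
to length 12).

Acceptance policy: no upward steps and at most one downward step. In the
30-frame counting protocol (3 s) a large fraction of fluorophores outlives
the movie, so a constant trace is accepted; in `"validation"` mode (longer
movies, stronger bleaching — the `scenario_imaging("validation")` preset
uses 150 frames at bleach rate 0.04/frame) the final level must also reach
baseline, i.e. the molecule must be *seen* to bleach completely. The two
modes mirror how short counting acquisitions coexist with multi-second
bleach-validation acquisitions.

## Configuring experiments by expected accepted counts

The published response characteristics are linear in log concentration
(counts per field versus log10(C/pM), and versus log10(cell number)). The
recovery experiments configure the simulator so that the *expected accepted
count* — not the emitter count — follows such a line, then require the full
pipeline to measure the line back. Two deterministic corrections connect
target counts to emitter numbers:

1. **Crowding** (`expected_spot_count()` / `emitters_for_expected_count()`):
   at finite density some emitters fall closer than the 4 px merge radius
   and are counted once. The expected detected count is estimated by
   Monte-Carlo non-maximum suppression on the Poisson point process (48
   repetitions, fixed internal seed) and inverted; the result is floored at
   the target since detections cannot exceed emitters.
2. **Acceptance efficiency** (`pipeline_efficiency()`,
   `density_acceptance()`): an isolated emitter is occasionally lost — it
   bleaches before the detection average, or its trace is rejected — and at
   working densities a photobleaching *neighbour* can inject a small
   secondary step into a spot's aperture, adding a density-dependent loss.
   Efficiency is measured once in the isolated limit (jittered-grid fields)
   and once at the experiment's highest density with a matched-pairs design
   (accepted count divided by the geometric survivor count of the same
   placement, so placement randomness cancels), then interpolated linearly
   in density.

Both calibrations are computed by the package itself with fixed internal
seeds; nothing is fitted to the published values. A consequence of the
published cell line for MB-231 cells is worth noting: its value at 100
cells is negative (58.046·2 − 120.14 ≈ −4), which the configuration clamps
to zero counts; refitting over the standard 10²–10⁵ range then compresses
the recovered slope by about 2% — an inherent property of that line, not of
the pipeline.

Selectivity experiments run in the linear low-occupancy regime where
expected counts are proportional to capture efficiency, so a configured
efficiency $1/F$ must be measured back as a fold ratio $F$; at the
operating concentrations of the saturating occupancy formula the fold
would instead be compressed, which is why the experiment drivers configure
counts, not concentrations.

## Quantification conventions

Regions are summarized by the arithmetic mean of accepted counts (sample SD
as the error bar); the calibration is an ordinary least-squares fit with
intercept; the concentration axis is log10 of pM. The limit of detection
uses the conventional blank mean + 3 SD crossing of the calibration line —
the published femtomolar detection limit comes without a stated criterion
or blank statistics, so it is out of reach of a desk-scale reproduction;
the LOD operation is instead verified against its algebraic closed form. If
the blank threshold sits below the fitted line over the whole calibrated
range, the estimate refuses to extrapolate and raises an error.

## Problem sizes

The recovery experiments in the tests and the acceptance script use
256×256 px regions (0.16 µm/px, ≈ 1678 µm²), 30-frame movies, 10 regions
per level and 3 replicate master seeds — four concentration decades
(≈ 10–340 expected counts per field), two cell lines, and a two-variant
selectivity panel at 10 pM. These sizes keep the whole validation suite in
the minutes range on a single CPU while leaving Poisson errors on fitted
slopes near 1%, an order of magnitude below the recovery tolerances.

## Known limitations

* The affinity and rate defaults are plausible anchors consistent with the
  assay's qualitative behaviour, not measured constants.
* Capture efficiency is phenomenological; no sequence thermodynamics.
* The EMCCD Gamma approximation slightly misstates the multiplication
  register's output distribution at very low photon numbers.
* Absolute LOD and 100-cell detection limits depend on unpublished blank
  statistics and are not reproduced, only the rule is implemented.
* Real-data effects (drift, structured background, blinking) are outside
  the simulator; results on such data require re-validation.
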