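# smicount

Single-molecule fluorescence spot counting for digital miRNA assays.

## The problem

Surface-based single-molecule assays count target molecules directly, without
enzymatic amplification: a Cy5-labelled DNA capture probe ("probe 1") is
anchored on a passivated coverslip and pre-hybridized with a shorter
quencher-labelled competitor ("probe 2") that switches the dye off. A target
miRNA (the model target here is miR-126, a breast-cancer-relevant tumour
suppressor) binds the capture probe more tightly than the competitor,
displaces it, and switches the dye back on. Wide-field EMCCD movies of the
surface then show one diffraction-limited spot per captured target, and the
target abundance is read out by counting spots over several imaged regions.

`smicount` re-implements this measurement as a reusable, fully synthetic
pipeline for method development and validation:

* **Binding model** — competitive-hybridization occupancy of the capture
  probe. With relative capture efficiency *e* and dissociation constants
  *K<sub>T</sub>*, *K<sub>2</sub>*, the bound fraction is
  θ<sub>T</sub> = (c<sub>T</sub>·e/K<sub>T</sub>) / (1 + c<sub>T</sub>·e/K<sub>T</sub> + c<sub>2</sub>/K<sub>2</sub>),
  with pseudo-first-order displacement kinetics
  θ<sub>T</sub>(t) = θ<sub>T</sub><sup>eq</sup>(1 − e<sup>−k<sub>obs</sub>t</sup>).
* **Movie simulator** — emitter fields with exact ground truth, rendered as
  pixel-integrated Gaussian PSFs with stochastic photobleaching and the
  EMCCD noise chain (Poisson photons → Gamma electron multiplication →
  Gaussian read noise → offset), written/read as 16-bit multi-page TIFF.
* **Spot detection** — difference-of-Gaussians band-pass, robust
  median + k·MAD threshold, minimum-separation merging, sub-pixel centroid.
* **Trace analysis** — aperture photometry traces and penalized
  binary-segmentation step counting; spots are accepted only when their
  photobleaching trace is one-level (single downward step at most, no upward
  steps), the classic single-molecule validity check.
* **Quantification** — region-wise counts (ten regions per sample by
  default), ordinary-least-squares calibration of mean count versus
  log10(concentration/pM) or log10(cell number), a blank + 3 SD limit of
  detection, and selectivity fold ratios against mismatched species.

## Worked example

```r
library(smicount)

## 1. Chemistry: what fraction of capture probes lights up at 10 pM target?
assay <- assay_config(target_conc = 10e-12)      # probe 2 at 10 nM, 60 min
occ <- solve_competitive_occupancy(assay)
print(occ)

## 2. Simulate one imaged sample (5 regions) and count single molecules
img <- imaging_config(width = 128, height = 128) # 30 frames at 100 ms
counts <- run_counting_pipeline(assay, img, n_regions = 5, seed = 7,
                                label = "miR-126 10 pM")
print(counts)

## 3. Calibration line over four concentrations + limit of detection
cal_counts <- c(4, 33, 61, 92)                   # mean accepted spots
fit <- fit_calibration(c(0.1, 1, 10, 100), cal_counts)
print(fit)
blank <- count_regions(c(1, 2, 1, 3, 2), label = "blank")
print(estimate_lod(fit, blank))
```

Output:

```
Occupancy (miR-126): target 0.3333, probe2 0.3333, free 0.3333
  fluorescent density: 0.053 emitters/um^2
Region counts (miR-126 10 pM): n = 5 regions, mean 23.20, sd 5.63
  counts: 33 23 20 20 20
Calibration fit: N = 29.2 * log10(C/pM) + 32.9  (R^2 = 0.9996)
LOD: 0.1049 (criterion: calibration line crossing of blank mean + 3 SD; blank 1.8 +/- 0.837, threshold 4.31)
```

Reading the numbers: at 10 pM target with the default affinities one third of
the capture probes are switched on (0.053 emitters/µm²), which yields ~23
accepted spots per 128×128 px region after detection and the one-level-trace
filter. The calibration fit returns counts-per-decade slope, intercept and
R²; the LOD is the concentration where that line crosses the blank mean plus
three blank SDs (0.105 pM for this small example).

There is also a thin command-line wrapper (`inst/exec/smicount`) with
`scenario`, `simulate`, `analyze`, `quantify`, `calibrate` and `selectivity`
subcommands over a YAML run configuration (see
`inst/extdata/example_config.yaml`); exit codes are 0 (success),
2 (configuration error) and 3 (data error).

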