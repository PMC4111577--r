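# mslcv

Level-set segmentation of elliptical, low-contrast targets in 2-D
ultrasound-like images — the setting of uterine-fibroid delineation in
ultrasound-guided HIFU (high-intensity focused ultrasound) therapy, where
images combine low SNR, multiplicative speckle, intensity inhomogeneity
and locally missing boundaries, and where plain region-based active
contours leak through boundary gaps or collapse into the target.

The package implements, as composable pieces and as two fitting drivers:

* the global two-phase piecewise-constant (Chan–Vese) region energy and
  its **localized** variant, in which the fitting means
  `u_x`, `v_x` are computed per pixel over a ball of radius `r`
  (`cv_constants()`, `cv_force()`, `local_means_field()`, `lcv_force()`);
* a **shape-constraint force** derived from the distance transform of the
  initial contour, `beta * sign(phi0) * (dist0 / L)^2`, disabled inside a
  *zero narrow band* around the prior, which pulls the evolving contour
  back towards the initial ellipse and suppresses boundary leakage
  (`shape_prior()`, `shape_force()`);
* a **two-stage Gaussian-pyramid driver** (`mslcv()`): 350 iterations on a
  16-fold-smaller pyramid layer with a weak constraint and a large
  localizing radius, then 50 full-resolution iterations initialized (and
  re-priored) by the upsampled coarse result — about 0.18 of the
  single-scale force evaluations at the same total budget;
* an **adaptive localizing radius**,
  `clamp(0.25 * (bbox width + height), 10, 40)` px, from the initial
  contour (`adaptive_radius()`);
* evaluation metrics — Dice overlap and mean sum of squared
  contour-to-contour distances (`dsc()`, `mssd()`, `evaluate_masks()`);
* a seeded **phantom generator** for elliptical targets with speckle,
  bias fields and missing-boundary sectors, plus a graded
  good/fair/poor battery (`make_phantom()`, `phantom_battery()`);
* a small CLI (`inst/cli/mslcv`) with `segment`, `phantoms` and
  `evaluate` subcommands.

Everything is deterministic given the seeds; images are plain numeric
matrices (rows × cols, intensities in [0, 1]).

## Worked example

Segment a noisy phantom with a 90° missing boundary, with and without the
shape constraint:

```r
library(mslcv)

spec  <- phantom_spec(shape = c(256, 256), ellipse = c(128, 128, 60, 40, 0),
                      gap_arc = c(-pi/4, pi/4), speckle_strength = 0.3,
                      seed = 42)
ph    <- make_phantom(spec)
init  <- make_initial_ellipse(spec, scale_jitter = 0.1, offset_jitter = 5,
                              seed = 43)
p     <- seg_params(fixed_iterations = TRUE)

unconstrained <- slcv(ph$image, init, p, n_iters = 400, beta = 0)
constrained   <- slcv(ph$image, init, p, n_iters = 400, beta = 0.7)

dsc(unconstrained$mask, ph$truth)            # 0.8484 — leaks through the gap
sum(unconstrained$mask) / sum(ph$truth)      # 1.319  — 32% area overshoot
dsc(constrained$mask, ph$truth)              # 0.9709 — leak suppressed
sum(constrained$mask) / sum(ph$truth)        # 1.025

fit <- mslcv(ph$image, init, p)              # two-stage coarse-to-fine run
print(fit)
#> Multi-scale (MSLCV) localized active-contour segmentation
#>   image: 256 x 256 px
#>   iterations: 400 (budget exhausted)
#>   segmented area: 8294 px (12.7% of image)
#>   settings: radius = 40, beta = 0.7, band = 0, mu = 0.2
plot(fit, image = ph$image)                  # contour over the phantom
```

Without the constraint the contour escapes through the missing boundary
into the bright funnel outside the target (the Dice coefficient against
truth drops to 0.85 and the segmented area overshoots by a third); with
`beta = 0.7` the pull towards the initial ellipse blocks the leak while
leaving the intact boundary data-driven.

From a shell, the same pipeline:

```sh
inst/cli/mslcv phantoms --n 9 --seed 1 --out phantoms/
inst/cli/mslcv segment --image phantoms/phantom_01_good.png \
    --init "ellipse:128,128,60,40,0" --out results/
inst/cli/mslcv evaluate --results "results/*_mask.png" \
    --references phantoms/ --out report.jsonl
```

## Scope

2-D, two-phase, single-target segmentation. No DICOM ingestion, no GPU
path, no statistical (trained) shape models — the prior is the
initialization itself. See the methods vignette
(`vignettes/mslcv-methods.Rmd`) for the model, parameter guidance and
limitations.
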