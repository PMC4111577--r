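---
title: "Shape-constrained localized active contours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained localized active contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslcv)
```

## The segmentation problem

Ultrasound images of approximately elliptical soft-tissue targets (the
motivating case is uterine fibroids imaged during high-intensity focused
ultrasound therapy) combine low signal-to-noise ratio, low contrast,
multiplicative speckle, smooth intensity inhomogeneity and locally missing
boundaries. Edge-based active contours fail on the weak gradients;
global region models fail on the inhomogeneity; localized region models
handle both but leak through missing boundary segments or collapse into
bright interior pockets. This package implements a localized region model
with an elliptical *shape constraint* — the initial contour itself acts as a
prior — run coarse-to-fine on a Gaussian pyramid for efficiency.

## Region energies

Let $I : \Omega \to [0,1]$ be the image and $\phi$ a level-set field,
negative inside the contour $C = \{\phi = 0\}$. The global two-phase
piecewise-constant (Chan–Vese) energy fits one mean per region:

$$c_1 = \frac{\int I\,(1 - H_\epsilon(\phi))}{\int (1 - H_\epsilon(\phi))},
\qquad
c_2 = \frac{\int I\,H_\epsilon(\phi)}{\int H_\epsilon(\phi)},$$

with the regularized Heaviside
$H_\epsilon(z) = \tfrac12\bigl(1 + \tfrac2\pi \arctan\tfrac z\epsilon\bigr)$
and its derivative
$\delta_\epsilon(z) = \tfrac1\pi\,\epsilon/(\epsilon^2 + z^2)$
(`smooth_heaviside()`, `smooth_dirac()`; $\epsilon = 1.5$ px so the
effective transition band spans about three pixels). The pointwise descent
force is $\lambda_1 (I - c_1)^2 - \lambda_2 (I - c_2)^2$: under the
package's conventions (inside negative; positive force raises $\phi$, i.e.
expels a pixel from the interior) a pixel fitting the interior mean better
is absorbed into the interior.

The localized variant replaces the global means with ball-restricted ones.
With the ball indicator $B(x, y) = \mathbf 1\{\lVert x - y\rVert \le r\}$
(`ball_indicator()`; the boundary is inclusive so ties are deterministic),
the local interior and exterior means $u_x, v_x$ at every pixel $x$ are
$H_\epsilon$-weighted means of $I$ over $B(x,\cdot)$ intersected with each
side of the contour (`local_means_field()`), and the localized force is the
pointwise

$$F(x) = (I(x) - u_x)^2 - (I(x) - v_x)^2,$$

computed on the Dirac band and then normalized by its maximum absolute
value to lie in $[-1, 1]$ (`lcv_force()`). The normalization puts the data
term on a fixed scale against the arc-length and shape terms below. A ball
that lies entirely on one side of the contour leaves its undefined mean
flagged and contributes zero force — the conservative choice for a model
that should only act where the contour is locally visible. Localized means
are computed exactly (they match a per-pixel brute-force ball loop to
rounding error) by an $O(N r)$ prefix-sum disc convolution in compiled
code, which is what makes 400-iteration runs at $512^2$ practical.

## The shape constraint and the zero narrow band

The prior is the level-set representation $\phi_0$ of the initial contour
and the unsigned distance $d_0 = |\phi_0|$ to it (`shape_prior()`; the
distance is obtained from the Euclidean distance transform of the rasterized
initial mask, identical within a pixel to an explicit nearest-point search
but $O(N)$). The constraint force at $x$ is

$$F_{shape}(x) \;=\; \beta\,\operatorname{sign}(\phi_0(x))
  \left(\frac{d_0(x)}{L}\right)^2
  \quad\text{for } d_0(x) > \epsilon_b, \qquad 0 \text{ otherwise,}$$

a pull of the current contour towards the prior from either side, disabled
inside the *zero narrow band* of half-width $\epsilon_b$ around the prior.

Three design choices deserve comment, because the constraint's published
description fixes only "a monotone function of the nearest distance with a
direction towards the initial contour":

* **Quadratic growth with a reference length $L$** (default $L = 10$ px;
  a linear pull is available via `shape_prior(pull = "linear")`). With the
  region force normalized to $[-1, 1]$, $\beta$ becomes interpretable: it
  is the weight of the constraint at an $L$-pixel excursion from the prior.
  The quadratic form separates scales — within a few pixels of the prior the
  data term dominates and refines the contour freely; over leak-sized
  excursions (tens of pixels) the constraint dominates regardless of what
  the data term found there. A linear pull cannot do both at once: any
  slope steep enough to stop leaks also pins the contour to the prior at
  the 2–4 px scale, which matters most at the fine multiscale stage where
  the prior is the upsampled coarse result and carries exactly that much
  interpolation error.
* **The zero narrow band** decouples the result from small errors in a
  manually placed initialization: within $\epsilon_b$ (default 3 px) of the
  prior the evolution is purely data-driven. The band is used at the coarse
  multiscale stage (manual initialization) and dropped at the fine stage,
  whose prior — the coarse result — is already trusted.
* **$\beta$ trades data against prior.** Values around 0.5–0.9 suit noisy,
  low-contrast images; small values degrade towards the unconstrained
  localized model, and very large values (tens) freeze the contour at its
  initialization — both limits are exercised in the test suite.

## Evolution scheme

Each iteration composes the total speed $F + \mu\kappa$ ($\kappa$ the
curvature of $\phi$ by central differences, $|\nabla\phi|$ floored at
$10^{-8}$; $\mu = 0.2$ by default — larger values suppress speckle-induced
islands) and applies the update with per-iteration normalization
(`evolve_step()`):

$$\phi \leftarrow \phi + dt\,\frac{U}{\max|U|},
\qquad U = \delta_\epsilon(\phi)\,(F + \mu\kappa).$$

The normalization is the standard scheme of localized active-contour
solvers: the largest level-set change per iteration is exactly $dt$ pixels
(default 0.45, a CFL-style bound guaranteeing stability of the explicit
step), and — crucially — weak fronts keep advancing as the strongly driven
parts of the contour settle. Under a fixed global step the force scale at a
blurred or missing boundary is two orders of magnitude below the sharp-edge
forces elsewhere, and the contour there would effectively never move.

Every 25 iterations $\phi$ is rebuilt as the exact signed distance function
of its current sign pattern (`reinitialize()`, via distance transforms) —
simple, deterministic level-set hygiene that keeps $|\nabla\phi| \approx 1$.
The drivers stop early when the mean $|\Delta\phi|$ over the
near-interface band stays below $10^{-4}$ for 10 consecutive iterations;
`fixed_iterations = TRUE` disables the stop for iteration-count
comparisons.

## Multiscale protocol

`mslcv()` runs two stages (`slcv()` is the single-scale driver):

1. **Coarse**: the image is decomposed by a Gaussian pyramid
   (`gaussian_pyramid()`: $\sigma = 1$ smoothing, then $2\times$ decimation
   per layer, sides rounding up) and the default coarse stage runs 350
   iterations on layer 2 (1/16 of the pixels). The initialization is the
   decimated user ellipse/mask; the constraint is deliberately weak
   ($\beta/2$, band on) and the localizing radius proportionally large
   ($\alpha_1 = 0.35$), prioritizing robustness to the manual
   initialization.
2. **Fine**: the coarse mask is bilinearly upsampled and thresholded at 0.5
   (`upsample_mask()`), becoming both the initialization and the rebuilt
   prior of a 50-iteration full-resolution run with the full $\beta$, the
   band off and a smaller radius ($\alpha_2 = 0.2$).

All length-like stage-1 settings — the adaptive-radius clamp bounds, the
zero-band half-width and the pull reference length $L$ — are divided by
$2^{\text{layer}}$ so that their physical size in full-resolution pixels is
scale-invariant; without this the coarse band alone would license a
12-full-resolution-pixel excursion through any boundary gap. With
`coarse_layer = 0` the driver degenerates to a single full-resolution run
over the combined iteration budget.

The efficiency mechanism is arithmetic, not wall-clock: at the reference
350 + 50 vs 400 split the two-stage driver performs
$350/4^2 + 50$ full-image force evaluations against 400, a ratio of about
0.18 at layer 2 — the test suite asserts the pixels-times-iterations count
directly.

### Adaptive localizing radius

`adaptive_radius()` sets $r$ from the initial contour:
$c = \alpha\,[(\text{col}_{max} - \text{col}_{min}) +
(\text{row}_{max} - \text{row}_{min})]$ — for an ellipse, a proportion of
the sum of the axes — clamped to $[10, 40]$ px at full resolution and
rounded. $\alpha = 0.25$ by default. Too small a radius starves the
evolution (the ball sees only one side); too large a radius reintroduces
the global model's leakage and wastes computation, hence the saturation.

## The phantom generator

`make_phantom()` emulates the degradations the method targets, on known
elliptical ground truth: rasterized ellipse at `fg_level` over `bg_level`;
optionally a *missing-boundary sector* — the arc sector between elliptical
radius 0.85 and `gap_extent` (default 1.6) filled with the foreground
level, so the boundary gradient vanishes along the gap and the interior
opens into a bright funnel through which an unconstrained contour leaks;
Gaussian blur; a smooth multiplicative bias field ($1 + a P$, $P$ a seeded
quadratic polynomial normalized to $[-1,1]$) emulating intensity
inhomogeneity; and i.i.d. mean-one Gamma speckle (variance $s^2$), the
standard first-order surrogate for fully developed multiplicative
ultrasound speckle. All randomness flows from one seed per call; the
global RNG stream is left untouched.

`phantom_battery()` grades difficulty the way clinical image quality is
graded: *good* (contrast 0.6, intact boundary, light speckle), *fair*
(contrast 0.4, 40° gap, speckle 0.3), *poor* (contrast 0.15, 90° gap,
strong bias field). What the phantoms do **not** model: spatially
correlated speckle texture, attenuation shadows, reverberation and mirror
artifacts, non-elliptical anatomy, and operator-dependent probe geometry.
Passing tests on these phantoms therefore demonstrates the model's
mechanics — localization, leak suppression, initialization robustness,
multiscale bookkeeping — not clinical-grade performance on real scans.

## Evaluation metrics

`dsc()` is the Dice overlap $2|A \cap B|/(|A| + |B|)$ on masks. `mssd()`
is the mean, over result-contour points, of the squared nearest Euclidean
distance to the reference contour, measured to the reference *polyline's
segments* (projections included), not only its vertices — sub-pixel
contours make vertex-only distances overestimate. It is asymmetric by
definition (the denominator is the result-contour size). Reference
contours for mask-level evaluation are extracted from the signed distance
function of the mask by marching squares (`extract_zero_contour()`).

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col) with pixel centers at integer
  coordinates, matching R matrix indexing; all modules share the
  convention.
* Intensity rescaling maps the observed min/max to $[0,1]$; a constant
  image maps to all zeros rather than erroring, so degenerate fixtures
  flow through with a defined result.
* The level-set sign convention (negative inside) is fixed globally.
* `sdf_from_mask()` requires a two-sided mask; the difference of the two
  distance transforms equals the distance to the interface within one
  pixel, which bounds all band and prior geometry errors below.
* The localized-force normalization floors its divisor at $10^{-10}$ so a
  flat image yields an exactly zero force rather than amplified rounding
  dust.
* Gradient and curvature stencils use edge replication at the borders.
* Contour extraction returns the longest closed component of the zero set;
  ties are broken by list order of `grDevices::contourLines`.
* Area monotonicity under a uniform force holds weakly per iteration —
  pixel counts change only when the (at most $dt$-pixel) update flips a
  pixel — and strictly over any run of several iterations.

## Problem sizes

The test suite and the acceptance script run the drivers at the sizes a
single CPU handles comfortably while preserving every mechanism under
test: unit fixtures at $32^2$–$128^2$, the gap and large-$\beta$
experiments at $256^2$ with 400 and 100 iterations, the graded battery as
nine $256^2$ phantoms segmented by both drivers (350 + 50 vs 400
iterations), and the force-evaluation comparison at the full $512^2$ with
the same split.

## Known limitations

* The shape prior is the initialization itself; a badly misplaced initial
  ellipse yields a well-constrained segmentation of the wrong region.
  The band and the coarse stage's weak constraint mitigate, not remove,
  initialization sensitivity.
* Full-grid evolution: no narrow-band or sparse-field optimization, and no
  semi-implicit scheme; efficiency comes from the pyramid instead.
* Two pyramid stages only; the coarse layer is a parameter, not selected
  automatically.
* The model is two-phase: a single closed target against one background
  population. Multiple targets or shells require re-initialization per
  target.
* 2-D only.
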