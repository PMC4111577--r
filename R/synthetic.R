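# Seeded phantom generator. Emulates the degradations of ultrasound imaging
# of elliptical soft-tissue targets: low contrast, multiplicative speckle,
# smooth intensity-inhomogeneity (bias) fields and missing boundary segments
# through which an unconstrained contour leaks.

# Run code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom specification
#'
#' Validated parameter bundle for [make_phantom()].
#'
#' @param shape \code{c(H, W)} in pixels.
#' @param ellipse \code{c(center_row, center_col, a, b, theta)} of the target;
#'   must lie fully inside the image with a 5 px margin.
#' @param fg_level,bg_level foreground/background intensities,
#'   \code{0 <= bg < fg <= 1}.
#' @param gap_arc \code{c(start, end)} angles in radians of a missing-boundary
#'   sector (in the ellipse frame), or \code{NULL} for an intact boundary.
#' @param gap_extent outer elliptical radius of the gap's bright bleed
#'   (relative to the target boundary at 1); the sector between radius 0.85
#'   and this value is filled with \code{fg_level} before blurring, erasing
#'   the edge and opening a leakage path.
#' @param blur_sigma Gaussian blur of the clean scene in pixels (boundary
#'   softness).
#' @param speckle_strength standard deviation of the multiplicative
#'   mean-one Gamma speckle (0 disables it).
#' @param bias_field_amplitude relative amplitude of the smooth multiplicative
#'   intensity-inhomogeneity field (0 disables it).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(256, 256),
                         ellipse = c(128, 128, 60, 40, 0),
                         fg_level = 0.75, bg_level = 0.25,
                         gap_arc = NULL, gap_extent = 1.6,
                         blur_sigma = 1.5, speckle_strength = 0.2,
                         bias_field_amplitude = 0.2, seed = 1L) {
  if (length(shape) != 2L || any(shape < 16L)) stop("shape must be >= 16x16")
  if (length(ellipse) != 5L) stop("ellipse must be c(row, col, a, b, theta)")
  a <- ellipse[3L]; b <- ellipse[4L]
  if (a <= 0 || b <= 0) stop("ellipse semi-axes must be positive")
  reach <- max(a, b)
  if (ellipse[1L] - reach < 5 || ellipse[1L] + reach > shape[1L] - 4 ||
      ellipse[2L] - reach < 5 || ellipse[2L] + reach > shape[2L] - 4)
    stop("ellipse must lie inside the image with a 5 px margin")
  if (!(bg_level >= 0 && bg_level < fg_level && fg_level <= 1))
    stop("need 0 <= bg_level < fg_level <= 1")
  if (!is.null(gap_arc) && length(gap_arc) != 2L)
    stop("gap_arc must be c(start, end) in radians or NULL")
  if (gap_extent <= 1) stop("gap_extent must exceed 1")
  if (blur_sigma < 0 || speckle_strength < 0 || bias_field_amplitude < 0)
    stop("blur, speckle and bias amplitudes must be >= 0")
  structure(
    list(shape = as.integer(shape), ellipse = as.numeric(ellipse),
         fg_level = fg_level, bg_level = bg_level, gap_arc = gap_arc,
         gap_extent = gap_extent, blur_sigma = blur_sigma,
         speckle_strength = speckle_strength,
         bias_field_amplitude = bias_field_amplitude,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Elliptical radius (1 on the boundary) and angle fields in the ellipse frame.
ellipse_frame <- function(shape, ellipse) {
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L]) - ellipse[1L]
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE) -
    ellipse[2L]
  th <- ellipse[5L]
  u <- cos(th) * rr + sin(th) * cc
  v <- -sin(th) * rr + cos(th) * cc
  list(rho = sqrt((u / ellipse[3L])^2 + (v / ellipse[4L])^2),
       ang = atan2(v, u))
}

#' Generate a phantom image and its ground-truth mask
#'
#' Pipeline: rasterize the ellipse at \code{fg_level} over \code{bg_level};
#' if a gap arc is given, fill the arc sector between elliptical radius 0.85
#' and \code{gap_extent} with \code{fg_level} (the boundary gradient along the
#' gap vanishes and the interior opens outward); Gaussian-blur; multiply by a
#' smooth bias field \code{1 + amplitude * P} with \code{P} a seeded low-order
#' polynomial normalized to \code{[-1, 1]}; multiply by i.i.d. mean-one Gamma
#' speckle with standard deviation \code{speckle_strength}; clip to
#' \code{[0, 1]}. The truth mask is the clean rasterized ellipse.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{image} (matrix in \code{[0, 1]}), \code{truth}
#'   (logical mask) and \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  truth <- rasterize_ellipse(shape, spec$ellipse[1:2], spec$ellipse[3L],
                             spec$ellipse[4L], spec$ellipse[5L])
  img <- spec$bg_level + (spec$fg_level - spec$bg_level) * truth

  if (!is.null(spec$gap_arc)) {
    ef <- ellipse_frame(shape, spec$ellipse)
    a0 <- spec$gap_arc[1L]; a1 <- spec$gap_arc[2L]
    off <- (ef$ang - a0) %% (2 * pi)
    span <- (a1 - a0) %% (2 * pi)
    in_sector <- off <= span
    gap <- in_sector & ef$rho >= 0.85 & ef$rho <= spec$gap_extent
    img[gap] <- spec$fg_level
  }

  with_seed(spec$seed, {
    if (spec$blur_sigma > 0)
      img <- unclass(EBImage::gblur(img, sigma = spec$blur_sigma,
                                    boundary = "replicate"))
    if (spec$bias_field_amplitude > 0) {
      rr <- (matrix(seq_len(shape[1L]), shape[1L], shape[2L]) - 1) /
        (shape[1L] - 1) * 2 - 1
      cc <- (matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE) -
               1) / (shape[2L] - 1) * 2 - 1
      co <- runif(5L, -1, 1)
      p <- co[1L] * rr + co[2L] * cc + co[3L] * rr * cc +
        co[4L] * rr^2 + co[5L] * cc^2
      if (max(abs(p)) > 0) p <- p / max(abs(p))
      img <- img * (1 + spec$bias_field_amplitude * p)
    }
    if (spec$speckle_strength > 0) {
      k <- 1 / spec$speckle_strength^2  # Gamma(k, rate = k): mean 1, var s^2
      img <- img * matrix(rgamma(length(img), shape = k, rate = k),
                          shape[1L], shape[2L])
    }
  })
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, truth = truth, spec = spec)
}

#' Jittered initial ellipse
#'
#' Scales the truth ellipse by \code{1 + U(-scale_jitter, scale_jitter)} and
#' translates it by a uniform draw from the disc of radius
#' \code{offset_jitter}, then rasterizes it. Errors if the jittered ellipse
#' leaves the image margin.
#'
#' @param spec a [phantom_spec()] (its ellipse is the truth).
#' @param scale_jitter relative scale jitter (>= 0).
#' @param offset_jitter translation jitter radius in px (>= 0).
#' @param seed integer seed.
#' @return logical init mask.
#' @export
make_initial_ellipse <- function(spec, scale_jitter = 0.15,
                                 offset_jitter = 8, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  e <- with_seed(seed, {
    s <- 1 + runif(1L, -scale_jitter, scale_jitter)
    ang <- runif(1L, 0, 2 * pi)
    rad <- offset_jitter * sqrt(runif(1L))
    c(spec$ellipse[1L] + rad * cos(ang), spec$ellipse[2L] + rad * sin(ang),
      spec$ellipse[3L] * s, spec$ellipse[4L] * s, spec$ellipse[5L])
  })
  if (e[3L] <= 0 || e[4L] <= 0)
    stop("scale jitter produced a degenerate ellipse; reduce the jitter")
  reach <- max(e[3L], e[4L])
  if (e[1L] - reach < 1 || e[1L] + reach > spec$shape[1L] ||
      e[2L] - reach < 1 || e[2L] + reach > spec$shape[2L])
    stop("jittered initial ellipse leaves the image; reduce the jitter")
  rasterize_ellipse(spec$shape, e[1:2], e[3L], e[4L], e[5L])
}

#' Battery of graded phantoms
#'
#' \code{n/3} phantoms in each difficulty group, emulating the grading of
#' clinical image quality: \emph{good} (high contrast, intact boundary),
#' \emph{fair} (moderate speckle, 40 degree gap), \emph{poor} (contrast
#' <= 0.15, 90 degree gap, strong bias field). Geometry is drawn per item
#' from the seeded generator; everything is reproducible given \code{seed}.
#'
#' @param n number of phantoms (>= 3; allocated round-robin when not a
#'   multiple of 3).
#' @param seed integer seed.
#' @param shape image shape, default 256 x 256.
#' @return list of \code{n} elements, each with \code{image}, \code{truth},
#'   \code{init}, \code{spec} and \code{group}.
#' @export
phantom_battery <- function(n = 9, seed = 1L, shape = c(256, 256)) {
  if (n < 3) stop("n must be >= 3")
  groups <- rep(c("good", "fair", "poor"), times = diff(floor(n * 0:3 / 3)))
  lapply(seq_len(n), function(i) {
    item_seed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
    geom <- with_seed(item_seed, {
      a <- runif(1L, 0.18, 0.25) * min(shape)
      b <- runif(1L, 0.12, 0.17) * min(shape)
      th <- runif(1L, 0, pi)
      ctr <- shape / 2 + runif(2L, -8, 8)
      c(ctr[1L], ctr[2L], a, b, th)
    })
    g <- groups[i]
    sp <- switch(g,
      good = phantom_spec(shape, geom, fg_level = 0.8, bg_level = 0.2,
                          gap_arc = NULL, blur_sigma = 1,
                          speckle_strength = 0.1,
                          bias_field_amplitude = 0.1, seed = item_seed),
      fair = phantom_spec(shape, geom, fg_level = 0.7, bg_level = 0.3,
                          gap_arc = c(0, 40 * pi / 180), blur_sigma = 1.5,
                          speckle_strength = 0.3,
                          bias_field_amplitude = 0.2, seed = item_seed),
      poor = phantom_spec(shape, geom, fg_level = 0.45, bg_level = 0.3,
                          gap_arc = c(0, pi / 2), blur_sigma = 2,
                          speckle_strength = 0.3,
                          bias_field_amplitude = 0.3, seed = item_seed))
    ph <- make_phantom(sp)
    init <- make_initial_ellipse(sp, scale_jitter = 0.1, offset_jitter = 5,
                                 seed = item_seed + 1)
    list(image = ph$image, truth = ph$truth, init = init, spec = sp,
         group = g)
  })
}
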