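# Gaussian-pyramid decomposition, adaptive localizing-radius selection and
# the single-scale (SLCV) / two-stage coarse-to-fine (MSLCV) drivers.

#' Segmentation parameters
#'
#' All tunables of the single- and multi-scale drivers, with the defaults
#' used throughout the package. Fields:
#' \describe{
#'   \item{mu}{arc-length (smoothness) weight; 0.2 suits noisy images.}
#'   \item{beta}{shape-constraint weight; useful range 0.5-0.9.}
#'   \item{radius}{localizing radius in px, or \code{"auto"} for adaptive
#'     selection from the initial contour's bounding box.}
#'   \item{alpha}{proportion coefficient of the adaptive radius (0.25).}
#'   \item{radius_bounds}{clamp range for the adaptive radius at full
#'     resolution, \code{c(10, 40)}; scaled by \code{2^-layer} on coarser
#'     pyramid layers.}
#'   \item{iters_coarse, iters_fine}{iteration budgets of the two stages
#'     (350 and 50).}
#'   \item{coarse_layer}{pyramid layer of the coarse stage (2; 0 degenerates
#'     to single-scale).}
#'   \item{epsilon}{Heaviside/Dirac smoothing width (1.5 px).}
#'   \item{dt}{explicit step size (0.45, stable with forces in [-1, 1]).}
#'   \item{band_halfwidth}{zero-narrow-band half-width for the shape force
#'     (3 px; the fine stage always runs with 0).}
#'   \item{shape_pull, pull_scale}{functional form of the shape pull
#'     (\code{"quadratic"} or \code{"linear"}) and the distance in px at
#'     which it reaches weight \code{beta} (10 at full resolution; divided
#'     by \code{2^layer} on coarser pyramid layers).}
#'   \item{lambda1, lambda2}{data-term weights (1, 1).}
#'   \item{alpha_coarse, alpha_fine}{stage-wise adaptive-radius proportions
#'     (0.35 and 0.2): large radius + weak shape constraint first, the
#'     reverse on the fine stage.}
#'   \item{reinit_every}{full SDF reinitialization period (25 iterations).}
#'   \item{convergence_tol, convergence_patience}{early stop when the mean
#'     |delta phi| over the near-interface band stays below the tolerance
#'     for this many consecutive iterations.}
#'   \item{fixed_iterations}{disable the early stop (for iteration-count
#'     comparisons).}
#'   \item{seed}{integer seed recorded with the run (the evolution itself is
#'     deterministic; the seed fixes fixture noise in tests).}
#' }
#'
#' @param mu,beta,radius,alpha,radius_bounds,iters_coarse,iters_fine,coarse_layer,epsilon,dt,band_halfwidth,shape_pull,pull_scale,lambda1,lambda2,alpha_coarse,alpha_fine,reinit_every,convergence_tol,convergence_patience,fixed_iterations,seed see Description.
#' @return object of class \code{seg_params}.
#' @export
seg_params <- function(mu = 0.2, beta = 0.7, radius = "auto", alpha = 0.25,
                       radius_bounds = c(10, 40), iters_coarse = 350,
                       iters_fine = 50, coarse_layer = 2, epsilon = 1.5,
                       dt = 0.45, band_halfwidth = 3,
                       shape_pull = "quadratic", pull_scale = 10,
                       lambda1 = 1, lambda2 = 1, alpha_coarse = 0.35,
                       alpha_fine = 0.2, reinit_every = 25,
                       convergence_tol = 1e-4, convergence_patience = 10,
                       fixed_iterations = FALSE, seed = 1L) {
  if (mu < 0) stop("mu must be >= 0")
  if (beta < 0) stop("beta must be >= 0")
  if (!(identical(radius, "auto") || (is.numeric(radius) && radius >= 1)))
    stop("radius must be \"auto\" or a number >= 1")
  for (a in c(alpha, alpha_coarse, alpha_fine))
    if (a <= 0 || a >= 1) stop("alpha coefficients must lie in (0, 1)")
  if (length(radius_bounds) != 2L || radius_bounds[1L] >= radius_bounds[2L])
    stop("radius_bounds must be c(min, max) with min < max")
  if (iters_coarse < 1 || iters_fine < 0) stop("iteration counts invalid")
  if (!coarse_layer %in% 0:3) stop("coarse_layer must be in 0..3")
  check_epsilon(epsilon)
  if (dt <= 0) stop("dt must be positive")
  if (band_halfwidth < 0) stop("band_halfwidth must be >= 0")
  if (!shape_pull %in% c("quadratic", "linear"))
    stop("shape_pull must be \"quadratic\" or \"linear\"")
  if (pull_scale <= 0) stop("pull_scale must be positive")
  structure(
    list(mu = mu, beta = beta, radius = radius, alpha = alpha,
         radius_bounds = radius_bounds, iters_coarse = iters_coarse,
         iters_fine = iters_fine, coarse_layer = coarse_layer,
         epsilon = epsilon, dt = dt, band_halfwidth = band_halfwidth,
         shape_pull = shape_pull, pull_scale = pull_scale,
         lambda1 = lambda1, lambda2 = lambda2, alpha_coarse = alpha_coarse,
         alpha_fine = alpha_fine, reinit_every = reinit_every,
         convergence_tol = convergence_tol,
         convergence_patience = convergence_patience,
         fixed_iterations = fixed_iterations, seed = as.integer(seed)),
    class = "seg_params")
}

#' Gaussian pyramid decomposition
#'
#' Layer k halves each side of layer k-1 (rounding up on odd sides), after
#' Gaussian smoothing (sigma = 1, replicated borders). Element \code{k + 1}
#' of the returned list is layer k; element 1 is the original image.
#'
#' @param image intensity matrix.
#' @param n_layers number of reduced layers (>= 1); every side of the image
#'   must be at least \code{2^n_layers} px.
#' @return list of \code{n_layers + 1} matrices.
#' @export
gaussian_pyramid <- function(image, n_layers) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (min(dim(image)) < 2^n_layers)
    stop("image too small for ", n_layers, " pyramid layers")
  out <- vector("list", n_layers + 1L)
  out[[1L]] <- image
  cur <- image
  for (k in seq_len(n_layers)) {
    sm <- unclass(EBImage::gblur(cur, sigma = 1, boundary = "replicate"))
    cur <- sm[seq(1L, nrow(sm), by = 2L), seq(1L, ncol(sm), by = 2L),
              drop = FALSE]
    out[[k + 1L]] <- cur
  }
  out
}

#' Adaptive localizing-radius selection
#'
#' \code{c = alpha * ((col_max - col_min) + (row_max - row_min))} over the
#' initial contour (for an ellipse, a proportion of the sum of the axes),
#' clamped to \code{bounds} and rounded to the nearest integer. Saturation
#' avoids radii too small to evolve the contour or so large that they cause
#' boundary leakage and wasted computation.
#'
#' @param init_contour \code{n x 2} (row, col) contour matrix.
#' @param alpha proportion coefficient, usually 0.25.
#' @param bounds \code{c(rmin, rmax)} clamp range in pixels.
#' @return integer radius in pixels.
#' @export
adaptive_radius <- function(init_contour, alpha = 0.25, bounds = c(10, 40)) {
  ctr <- as_contour(init_contour)
  extent <- diff(range(ctr[, "col"])) + diff(range(ctr[, "row"]))
  if (extent <= 0) stop("degenerate contour: zero extent")
  cc <- alpha * extent
  as.integer(round(min(max(cc, bounds[1L]), bounds[2L])))
}

#' Upsample a coarse mask to a finer grid
#'
#' Bilinear upscale of the 0/1 mask followed by thresholding at 0.5. Used to
#' carry the coarse-stage segmentation up the pyramid as the fine-stage
#' initialization.
#'
#' @param coarse_mask binary mask.
#' @param target_shape \code{c(H, W)} of the finer grid (each side >= the
#'   coarse side).
#' @return logical mask of shape \code{target_shape}.
#' @export
upsample_mask <- function(coarse_mask, target_shape) {
  coarse_mask <- as_mask(coarse_mask)
  if (any(target_shape < dim(coarse_mask)))
    stop("target shape must be at least the coarse shape")
  if (all(target_shape == dim(coarse_mask))) return(coarse_mask)
  up <- EBImage::resize(coarse_mask * 1.0, w = target_shape[1L],
                        h = target_shape[2L])
  m <- unclass(up) >= 0.5
  nf <- sum(m)
  if (nf == 0L || nf == length(m))
    stop("upsampling produced a one-sided mask")
  m
}

#' Rasterize an ellipse to a binary mask
#'
#' @param shape \code{c(H, W)} of the target grid.
#' @param center \code{c(row, col)} of the ellipse center.
#' @param a,b semi-axes in pixels (\code{a} along the rotated row axis).
#' @param theta rotation in radians.
#' @return logical mask.
#' @export
rasterize_ellipse <- function(shape, center, a, b, theta = 0) {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L]) - center[1L]
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE) -
    center[2L]
  u <- cos(theta) * rr + sin(theta) * cc
  v <- -sin(theta) * rr + cos(theta) * cc
  (u / a)^2 + (v / b)^2 <= 1
}

# Accept an init specification: logical/0-1 mask matrix, or an ellipse as
# c(center_row, center_col, a, b, theta) / list(center=, a=, b=, theta=).
resolve_init_mask <- function(init, shape) {
  if (is.matrix(init)) {
    m <- as_mask(init)
    if (!all(dim(m) == shape)) stop("init mask shape does not match image")
    return(m)
  }
  if (is.numeric(init) && length(init) %in% c(4L, 5L)) {
    theta <- if (length(init) == 5L) init[5L] else 0
    return(rasterize_ellipse(shape, init[1:2], init[3L], init[4L], theta))
  }
  if (is.list(init))
    return(rasterize_ellipse(shape, init$center, init$a, init$b,
                             init$theta %||% 0))
  stop("init must be a mask matrix or ellipse c(row, col, a, b, theta)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-scale shape-constrained localized segmentation
#'
#' Evolves the zero level set of a signed distance function under the
#' normalized localized Chan-Vese force plus the shape-constraint force,
#' with curvature regularization, periodic SDF reinitialization and an
#' optional convergence early stop.
#'
#' @param image intensity matrix in \code{[0, 1]}.
#' @param init initial contour: a binary mask, or an ellipse
#'   \code{c(center_row, center_col, a, b, theta)}.
#' @param params a [seg_params()] object.
#' @param use_band logical; apply the zero narrow band of half-width
#'   \code{params$band_halfwidth} to the shape force (on for manual
#'   initializations, off when refining a trusted contour).
#' @param radius localizing radius override in px; \code{NULL} resolves
#'   \code{params$radius} (\code{"auto"} selects [adaptive_radius()] with
#'   \code{params$alpha}).
#' @param n_iters iteration budget override; \code{NULL} uses
#'   \code{params$iters_coarse}.
#' @param beta shape-weight override; \code{NULL} uses \code{params$beta}.
#' @param alpha adaptive-radius proportion override.
#' @param radius_bounds adaptive-radius clamp override.
#' @param pull_scale shape-pull reference distance override (px).
#' @param band_halfwidth zero-narrow-band half-width override (px); only
#'   used when \code{use_band} is TRUE.
#' @return object of class \code{slcv_fit}: final \code{mask}, \code{contour},
#'   \code{phi}, per-iteration \code{diagnostics} (mean |delta phi| over the
#'   near-interface band), \code{force_evals} (pixels x iterations),
#'   \code{converged}, \code{iterations} and the resolved \code{settings}.
#' @export
slcv <- function(image, init, params = seg_params(), use_band = TRUE,
                 radius = NULL, n_iters = NULL, beta = NULL, alpha = NULL,
                 radius_bounds = NULL, pull_scale = NULL,
                 band_halfwidth = NULL) {
  stopifnot(inherits(params, "seg_params"))
  shape <- dim(image)
  init_mask <- resolve_init_mask(init, shape)
  beta <- beta %||% params$beta
  n_iters <- n_iters %||% params$iters_coarse
  bounds <- radius_bounds %||% params$radius_bounds
  if (is.null(radius)) {
    radius <- if (identical(params$radius, "auto")) {
      phi_init <- sdf_from_mask(init_mask)
      adaptive_radius(extract_zero_contour(phi_init),
                      alpha %||% params$alpha, bounds)
    } else params$radius
  }
  radius <- max(1L, as.integer(round(radius)))
  band <- if (use_band) band_halfwidth %||% params$band_halfwidth else 0
  prior <- shape_prior(init_mask, beta = beta, band_halfwidth = band,
                       pull = params$shape_pull,
                       pull_scale = pull_scale %||% params$pull_scale)
  eps <- params$epsilon

  phi <- sdf_from_mask(init_mask)
  mean_dphi <- numeric(0L)
  still <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < n_iters) {
    iter <- iter + 1L
    force <- tryCatch(
      slcv_total_force(image, phi, prior, radius, eps),
      error = function(e) stop("iteration ", iter, ": ", conditionMessage(e)))
    phi_new <- tryCatch(
      evolve_step(phi, force, mu = params$mu, dt = params$dt, epsilon = eps),
      error = function(e) stop("iteration ", iter, ": ", conditionMessage(e)))
    if (any(!is.finite(phi_new)))
      stop("numeric blowup at iteration ", iter)
    near <- abs(phi) <= 3 * eps
    mean_dphi[iter] <- if (any(near)) mean(abs(phi_new - phi)[near]) else 0
    phi <- phi_new
    if (iter %% params$reinit_every == 0L && min(phi) < 0 && max(phi) >= 0)
      phi <- reinitialize(phi)
    if (!params$fixed_iterations) {
      still <- if (mean_dphi[iter] < params$convergence_tol) still + 1L else 0L
      if (still >= params$convergence_patience) { converged <- TRUE; break }
    }
  }
  if (iter > 0L && min(phi) < 0 && max(phi) >= 0) phi <- reinitialize(phi)

  mask <- phi < 0
  contour <- if (min(phi) < 0 && max(phi) > 0) extract_zero_contour(phi)
             else NULL
  structure(
    list(mask = mask, contour = contour, phi = phi,
         diagnostics = data.frame(iter = seq_len(iter),
                                  mean_dphi = mean_dphi,
                                  stage = rep(1L, iter)),
         force_evals = as.numeric(iter) * prod(shape),
         converged = converged, iterations = iter,
         init_mask = init_mask, image_dim = shape,
         settings = list(radius = radius, beta = beta,
                         band_halfwidth = band, mu = params$mu,
                         dt = params$dt, epsilon = eps,
                         n_iters = n_iters),
         params = params, call = match.call()),
    class = "slcv_fit")
}

#' Multi-scale shape-constrained localized segmentation
#'
#' Two-stage coarse-to-fine driver. Stage 1 runs [slcv()] on pyramid layer
#' \code{params$coarse_layer} with a large localizing radius
#' (\code{alpha_coarse}), half the shape weight and the zero narrow band on
#' (weak constraint, robust to a rough manual initialization). The coarse
#' mask is upsampled to full resolution and becomes both the initialization
#' and the rebuilt shape prior of stage 2, which runs few iterations with a
#' small radius (\code{alpha_fine}), the full shape weight and the band off.
#' With \code{coarse_layer = 0} the driver degenerates to a single
#' full-resolution [slcv()] run over the combined iteration budget.
#'
#' @inheritParams slcv
#' @return object of class \code{c("mslcv_fit", "slcv_fit")}; stage-2 result
#'   with the stage-1 fit attached as \code{$stage1}, combined
#'   \code{diagnostics} and total \code{force_evals}.
#' @export
mslcv <- function(image, init, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  shape <- dim(image)
  init_mask <- resolve_init_mask(init, shape)
  k <- params$coarse_layer

  if (k == 0L) {
    fit <- slcv(image, init_mask, params, use_band = TRUE,
                n_iters = params$iters_coarse + params$iters_fine)
    fit$stage1 <- NULL
    class(fit) <- c("mslcv_fit", "slcv_fit")
    return(fit)
  }

  pyr <- gaussian_pyramid(image, k)
  coarse_img <- pyr[[k + 1L]]
  dec <- function(n) seq(1L, n, by = 2L^k)
  coarse_init <- init_mask[dec(shape[1L]), dec(shape[2L]), drop = FALSE]
  if (sum(coarse_init) == 0L || sum(coarse_init) == length(coarse_init))
    stop("initial contour collapsed at the coarse scale; re-initialize")

  stage1 <- slcv(coarse_img, coarse_init, params, use_band = TRUE,
                 n_iters = params$iters_coarse, beta = params$beta / 2,
                 alpha = params$alpha_coarse,
                 radius_bounds = pmax(1, params$radius_bounds / 2^k),
                 pull_scale = params$pull_scale / 2^k,
                 band_halfwidth = params$band_halfwidth / 2^k)
  if (sum(stage1$mask) == 0L)
    stop("stage-1 segmentation is empty; re-initialize the contour")

  fine_init <- upsample_mask(stage1$mask, shape)
  stage2 <- slcv(image, fine_init, params, use_band = FALSE,
                 n_iters = params$iters_fine, beta = params$beta,
                 alpha = params$alpha_fine)

  stage1$diagnostics$stage <- 1L
  stage2$diagnostics$stage <- 2L
  stage2$diagnostics$iter <- stage2$diagnostics$iter + stage1$iterations
  fit <- stage2
  fit$stage1 <- stage1
  fit$diagnostics <- rbind(stage1$diagnostics, stage2$diagnostics)
  fit$force_evals <- stage1$force_evals + stage2$force_evals
  fit$iterations <- stage1$iterations + stage2$iterations
  fit$init_mask <- init_mask
  fit$call <- match.call()
  class(fit) <- c("mslcv_fit", "slcv_fit")
  fit
}
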