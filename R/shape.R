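# Shape-constraint force: a pull towards the initial contour, proportional to
# the nearest distance to it, disabled inside a "zero narrow band" around it.

#' Build a shape prior from an initial mask
#'
#' The prior stores the level-set representation \code{phi0} of the initial
#' contour (negative inside), the unsigned nearest-distance field
#' \code{dist0 = |phi0|}, the constraint weight \code{beta} and the half-width
#' of the zero narrow band inside which the constraint is ignored.
#'
#' @param init_mask binary mask of the initial contour's interior (two-sided).
#' @param beta shape-constraint weight (>= 0). The pull reaches magnitude
#'   \code{beta} at \code{pull_scale} pixels from the prior, so with the
#'   region force normalized to \code{[-1, 1]} a weight in the typical
#'   0.5-0.9 range lets the data term refine the contour within a few pixels
#'   of the prior but overrides it over leak-sized excursions.
#' @param band_halfwidth half-width of the zero narrow band in pixels (>= 0).
#' @param pull functional form of the pull: \code{"quadratic"} (magnitude
#'   \code{beta * (dist0 / pull_scale)^2}, the default — negligible within a
#'   few pixels of the prior, dominant over leak-sized excursions) or
#'   \code{"linear"} (\code{beta * dist0 / pull_scale}).
#' @param pull_scale reference distance in pixels at which the pull equals
#'   \code{beta}.
#' @return object of class \code{shape_prior}.
#' @export
shape_prior <- function(init_mask, beta = 0.7, band_halfwidth = 3,
                        pull = c("quadratic", "linear"), pull_scale = 10) {
  pull <- match.arg(pull)
  if (beta < 0) stop("beta must be >= 0")
  if (band_halfwidth < 0) stop("band_halfwidth must be >= 0")
  if (pull_scale <= 0) stop("pull_scale must be positive")
  phi0 <- sdf_from_mask(init_mask)
  structure(
    list(phi0 = phi0, dist0 = abs(phi0), beta = beta,
         band_halfwidth = band_halfwidth, pull = pull,
         pull_scale = pull_scale),
    class = "shape_prior")
}

#' Shape-constraint force field
#'
#' Zero wherever \code{dist0 <= band_halfwidth} (the zero narrow band);
#' outside the band, magnitude \code{beta * (dist0 / pull_scale)^2} (or
#' \code{beta * dist0 / pull_scale} for the linear pull), monotone in
#' the distance to the prior, with direction \code{sign(phi0)}, which moves
#' the zero set of \code{phi} towards the zero set of \code{phi0} from either
#' side under the package's positive-force-contracts convention. The caller
#' (the evolution step) applies it through \code{smooth_dirac(phi)} so it
#' acts on the current contour only.
#'
#' @param prior a [shape_prior()].
#' @param phi current level-set field (used for shape validation only; the
#'   force is a fixed field of the prior).
#' @return force field, same shape as \code{phi0}.
#' @export
shape_force <- function(prior, phi = NULL) {
  stopifnot(inherits(prior, "shape_prior"))
  if (!is.null(phi) && !all(dim(phi) == dim(prior$phi0)))
    stop("phi and prior shapes disagree")
  d <- prior$dist0 / prior$pull_scale
  mag <- if (prior$pull == "linear") d else d^2
  force <- prior$beta * sign(prior$phi0) * mag
  force[prior$dist0 <= prior$band_halfwidth] <- 0
  force
}

#' Total shape-constrained localized force
#'
#' Sum of the normalized localized region force and the shape-constraint
#' force. The arc-length (curvature) term is added separately by
#' [evolve_step()] with weight \code{mu}.
#'
#' @inheritParams lcv_force
#' @param prior a [shape_prior()].
#' @return force field.
#' @export
slcv_total_force <- function(image, phi, prior, r, epsilon = 1.5) {
  region <- lcv_force(image, phi, r, epsilon)
  if (prior$beta > 0) region + shape_force(prior, phi) else region
}
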