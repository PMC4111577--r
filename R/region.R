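# Region-based driving forces: global Chan-Vese fitting constants/force and
# the Lankton-style localized means and force used by the localized model.
#
# Sign convention (shared with evolve_step): phi < 0 inside; a POSITIVE force
# increases phi, i.e. moves a pixel towards the exterior. Hence the data term
# is (I - c_in)^2 - (I - c_out)^2: pixels fitting the interior mean better get
# a negative speed and are absorbed into the interior.

#' Global Chan-Vese fitting constants
#'
#' Smoothed-Heaviside-weighted mean intensities of the interior
#' (weight \code{1 - H_eps(phi)}) and exterior (weight \code{H_eps(phi)}).
#'
#' @param image intensity matrix in \code{[0, 1]}.
#' @param phi level-set field (negative inside).
#' @param epsilon Heaviside smoothing width.
#' @return list with \code{c1} (interior mean) and \code{c2} (exterior mean).
#' @export
cv_constants <- function(image, phi, epsilon = 1.5) {
  stopifnot(all(dim(image) == dim(phi)))
  h <- smooth_heaviside(phi, epsilon)
  w_in <- 1 - h
  m_in <- sum(w_in); m_out <- sum(h)
  if (m_in <= 1e-6 || m_out <= 1e-6)
    stop("degenerate region: one side has (near-)zero smoothed mass")
  list(c1 = sum(image * w_in) / m_in, c2 = sum(image * h) / m_out)
}

#' Global Chan-Vese force field
#'
#' Pointwise \eqn{\lambda_1 (I - c_1)^2 - \lambda_2 (I - c_2)^2}; under the
#' package's conventions the interface moves towards the region whose
#' constant better fits the local intensity.
#'
#' @param image intensity matrix.
#' @param c1,c2 interior / exterior fitting constants.
#' @param lambda1,lambda2 nonnegative data-term weights.
#' @return force field, same shape as \code{image}.
#' @export
cv_force <- function(image, c1, c2, lambda1 = 1, lambda2 = 1) {
  lambda1 * (image - c1)^2 - lambda2 * (image - c2)^2
}

#' Ball indicator
#'
#' 1 iff the Euclidean distance between points \code{x} and \code{y} is at
#' most \code{r} (boundary inclusive), else 0. This is the localizing window
#' that turns the global region energy into a local one.
#'
#' @param x,y points as \code{c(row, col)}.
#' @param r radius in pixels (> 0).
#' @return 0 or 1.
#' @export
ball_indicator <- function(x, y, r) {
  if (r <= 0) stop("radius must be positive")
  as.numeric(sum((x - y)^2) <= r^2)
}

#' Local interior/exterior means over the whole grid
#'
#' For every pixel x, the smoothed-Heaviside-weighted mean of the image over
#' the disc of radius \code{r} at x intersected with the interior
#' (\code{phi < 0} side, weight \code{1 - H_eps}) and the exterior (weight
#' \code{H_eps}), plus the unweighted pixel counts of each side within the
#' disc. Computed with an O(N r) prefix-sum disc convolution; means are
#' \code{NA} where the corresponding count is zero.
#'
#' @inheritParams cv_constants
#' @param r localizing radius in pixels (>= 1).
#' @return list of matrices \code{mu_in}, \code{mu_out}, \code{n_in},
#'   \code{n_out}.
#' @export
local_means_field <- function(image, phi, r, epsilon = 1.5) {
  stopifnot(all(dim(image) == dim(phi)))
  if (r < 1) stop("localizing radius must be >= 1")
  h <- smooth_heaviside(phi, epsilon)
  s <- local_sums(image, 1 - h, h, phi < 0, r)
  mu_in <- s$num_in / s$den_in
  mu_out <- s$num_out / s$den_out
  mu_in[s$n_in == 0L] <- NA_real_
  mu_out[s$n_out == 0L] <- NA_real_
  list(mu_in = mu_in, mu_out = mu_out, n_in = s$n_in, n_out = s$n_out)
}

#' Local interior/exterior means at one point
#'
#' Convenience accessor for [local_means_field()] at a single pixel.
#'
#' @inheritParams local_means_field
#' @param x point as \code{c(row, col)}, 1-based integer pixel coordinates.
#' @return list with \code{mu_in}, \code{mu_out} (NA when the side is empty
#'   within the ball) and counts \code{n_in}, \code{n_out}.
#' @export
local_means <- function(image, phi, x, r, epsilon = 1.5) {
  f <- local_means_field(image, phi, r, epsilon)
  i <- x[1L]; j <- x[2L]
  list(mu_in = f$mu_in[i, j], mu_out = f$mu_out[i, j],
       n_in = f$n_in[i, j], n_out = f$n_out[i, j])
}

#' Localized Chan-Vese force field
#'
#' At every pixel x in the Dirac band (\code{smooth_dirac(phi) > band_threshold}),
#' the point-wise localized flow \eqn{(I(x) - u_x)^2 - (I(x) - v_x)^2} built
#' from the local means \eqn{u_x, v_x}; zero elsewhere and wherever a ball
#' lies entirely on one side of the contour. The result is normalized by its
#' maximum absolute value to lie in \code{[-1, 1]} before being combined with
#' the arc-length and shape terms.
#'
#' @inheritParams local_means_field
#' @param band_threshold Dirac value below which the force is clamped to zero.
#' @return normalized force field in \code{[-1, 1]}.
#' @export
lcv_force <- function(image, phi, r, epsilon = 1.5, band_threshold = 1e-8) {
  f <- local_means_field(image, phi, r, epsilon)
  force <- (image - f$mu_in)^2 - (image - f$mu_out)^2
  force[is.na(force)] <- 0  # ball entirely on one side: conservative fallback
  force[smooth_dirac(phi, epsilon) <= band_threshold] <- 0
  if (any(!is.finite(force))) {
    bad <- which(!is.finite(force), arr.ind = TRUE)[1L, ]
    stop("non-finite localized force at pixel (", bad[1L], ", ", bad[2L], ")")
  }
  m <- max(abs(force))
  # floor guards against amplifying rounding dust on flat images
  if (m > 1e-10) force / m else array(0, dim(force))
}
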