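# Level-set representation and numerics. phi is a numeric [row, col] matrix,
# strictly negative inside the contour, positive outside; the contour is the
# zero level set.

#' Regularized Heaviside function
#'
#' Smooth step \eqn{H_\epsilon(z) = \frac{1}{2}\left(1 +
#' \frac{2}{\pi}\arctan\frac{z}{\epsilon}\right)}, the standard regularization
#' used with two-phase region energies. Monotone nondecreasing, \eqn{H(0) =
#' 1/2}, \eqn{H(z) + H(-z) = 1}.
#'
#' @param z signed value(s), typically a level-set field.
#' @param epsilon smoothing width in pixels (> 0).
#' @return values in \code{(0, 1)}, same shape as \code{z}.
#' @export
smooth_heaviside <- function(z, epsilon = 1.5) {
  check_epsilon(epsilon)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Regularized Dirac delta
#'
#' Exact derivative of [smooth_heaviside()]:
#' \eqn{\delta_\epsilon(z) = \frac{1}{\pi}\frac{\epsilon}{\epsilon^2 + z^2}}.
#' Even in \code{z}, maximal at 0, integrates to 1 over the real line. Marks
#' the band of pixels near the current contour on which forces act.
#'
#' @inheritParams smooth_heaviside
#' @return nonnegative values, same shape as \code{z}.
#' @export
smooth_dirac <- function(z, epsilon = 1.5) {
  check_epsilon(epsilon)
  (epsilon / pi) / (epsilon^2 + z^2)
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("epsilon must be a single positive number")
}

#' Signed distance function from a binary mask
#'
#' \code{phi = dist(to foreground) - dist(to background)} (Euclidean distance
#' transforms), so \code{phi < 0} exactly on foreground pixels and \code{|phi|}
#' is the distance to the interface within one pixel.
#'
#' @param mask logical or 0/1 matrix with at least one foreground and one
#'   background pixel.
#' @return numeric matrix \code{phi}.
#' @export
sdf_from_mask <- function(mask) {
  mask <- as_mask(mask)
  nf <- sum(mask)
  if (nf == 0L || nf == length(mask))
    stop("mask must have both foreground and background pixels")
  d_bg <- EBImage::distmap(mask * 1.0)        # distance to nearest background
  d_fg <- EBImage::distmap((!mask) * 1.0)     # distance to nearest foreground
  unclass(d_fg - d_bg)
}

# Central differences with edge replication.
grad_row <- function(m) {
  n <- nrow(m)
  (m[c(2:n, n), , drop = FALSE] - m[c(1L, 1:(n - 1L)), , drop = FALSE]) / 2
}
grad_col <- function(m) {
  n <- ncol(m)
  (m[, c(2:n, n), drop = FALSE] - m[, c(1L, 1:(n - 1L)), drop = FALSE]) / 2
}

#' Curvature of the level-set field
#'
#' \eqn{\kappa = \nabla\cdot(\nabla\phi/|\nabla\phi|)} by central differences
#' with edge replication; \eqn{|\nabla\phi|} is floored at 1e-8 before the
#' division. On a signed distance function of a circle of radius r (negative
#' inside) the value near the interface is \eqn{1/r}.
#'
#' @param phi level-set field.
#' @return curvature field, same shape as \code{phi}.
#' @export
curvature <- function(phi) {
  if (any(!is.finite(phi))) stop("phi must be finite")
  gr <- grad_row(phi); gc <- grad_col(phi)
  mag <- pmax(sqrt(gr^2 + gc^2), 1e-8)
  grad_row(gr / mag) + grad_col(gc / mag)
}

#' Extract the zero-level contour
#'
#' Marching-squares contour of \code{phi} at level 0 (via
#' \code{grDevices::contourLines}); when several closed components exist the
#' one with the longest perimeter is returned. Coordinates are sub-pixel
#' (row, col), 1-based; the duplicate closing point is dropped.
#'
#' @param phi level-set field that changes sign somewhere.
#' @return \code{n x 2} matrix with columns \code{row, col}.
#' @export
extract_zero_contour <- function(phi) {
  if (min(phi) >= 0 || max(phi) <= 0)
    stop("empty contour: phi does not change sign")
  cl <- contourLines(x = seq_len(nrow(phi)), y = seq_len(ncol(phi)),
                     z = phi, levels = 0)
  if (length(cl) == 0L) stop("empty contour: no zero crossing found")
  perim <- function(comp) {
    p <- cbind(comp$x, comp$y)
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }
  comp <- cl[[which.max(vapply(cl, perim, numeric(1L)))]]
  pts <- cbind(row = comp$x, col = comp$y)
  n <- nrow(pts)
  if (n > 1L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  as_contour(pts)
}

#' One explicit level-set evolution step
#'
#' Computes the update field \eqn{U = \delta_\epsilon(\phi)\,(F +
#' \mu\kappa(\phi))} — \code{F} the caller-composed signed speed per pixel
#' (region + shape terms), \eqn{\mu\kappa} the arc-length regularization —
#' and applies it with the standard per-iteration update normalization of
#' localized active-contour solvers:
#' \deqn{\phi' = \phi + dt\,U / \max|U|}
#' so the largest level-set change per step is exactly \code{dt} pixels
#' (a CFL-style bound) and weak fronts keep moving as the rest of the
#' contour settles. If \code{U} vanishes everywhere, \code{phi} is returned
#' unchanged. Positive total speed increases \code{phi} (contour contraction
#' under the inside-negative convention); the step is linear in \code{dt}.
#'
#' @param phi level-set field.
#' @param force signed speed field, same shape as \code{phi}.
#' @param mu arc-length (curvature) weight, >= 0.
#' @param dt maximum level-set change per step, in pixels (> 0).
#' @param epsilon Dirac smoothing width.
#' @return updated field \code{phi'}.
#' @export
evolve_step <- function(phi, force, mu = 0.2, dt = 0.45, epsilon = 1.5) {
  if (!all(dim(phi) == dim(force))) stop("phi and force shapes disagree")
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(force))) stop("non-finite force values")
  total <- if (mu != 0) force + mu * curvature(phi) else force
  u <- smooth_dirac(phi, epsilon) * total
  m <- max(abs(u))
  if (m > 0) phi + (dt / m) * u else phi
}

#' Reinitialize a level-set field to a signed distance function
#'
#' Recomputes the exact SDF of the current sign pattern (\code{phi < 0} is
#' interior), preserving that pattern exactly. Standard level-set hygiene:
#' evolution distorts \code{|grad phi|} away from 1; periodic reinitialization
#' restores it.
#'
#' @param phi level-set field whose sign pattern is two-sided.
#' @return fresh signed distance function with the same sign pattern.
#' @export
reinitialize <- function(phi) {
  sdf_from_mask(phi < 0)
}
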