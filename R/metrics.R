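# Evaluation metrics: Dice similarity coefficient on masks and mean sum of
# square distance between contours.

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)} between two binary masks of the same
#' shape; 1 for identical nonempty masks, 0 for disjoint ones.
#'
#' @param mask_a,mask_b logical or 0/1 matrices of equal shape, at least one
#'   of them nonempty.
#' @return value in \code{[0, 1]}.
#' @export
dsc <- function(mask_a, mask_b) {
  a <- as_mask(mask_a); b <- as_mask(mask_b)
  if (!all(dim(a) == dim(b))) stop("mask shapes disagree")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("both masks are empty")
  2 * sum(a & b) / (na + nb)
}

#' Mean sum of square distance between contours
#'
#' Mean, over the points of the result contour, of the squared nearest
#' Euclidean distance to the reference contour, with distances taken to the
#' reference polyline's segments (point-to-segment, projections included),
#' not only its vertices. Asymmetric by definition: the denominator is the
#' size of the result contour.
#'
#' @param result_contour,reference_contour \code{n x 2} (row, col) contour
#'   matrices, implicitly closed.
#' @return mean squared distance in px^2.
#' @export
mssd <- function(result_contour, reference_contour) {
  p <- as_contour(result_contour)
  q <- as_contour(reference_contour)
  qa <- q
  qb <- q[c(2:nrow(q), 1L), , drop = FALSE]  # closing segment included
  er <- qb[, 1L] - qa[, 1L]
  ec <- qb[, 2L] - qa[, 2L]
  len2 <- pmax(er^2 + ec^2, .Machine$double.eps)
  d2 <- vapply(seq_len(nrow(p)), function(i) {
    wr <- p[i, 1L] - qa[, 1L]
    wc <- p[i, 2L] - qa[, 2L]
    t <- pmin(pmax((wr * er + wc * ec) / len2, 0), 1)
    min((wr - t * er)^2 + (wc - t * ec)^2)
  }, numeric(1L))
  mean(d2)
}

#' Evaluate a segmentation against a reference mask
#'
#' Computes the Dice coefficient of the masks and the mean sum of square
#' distance between their boundary contours (extracted from the signed
#' distance functions of the masks).
#'
#' @param result_mask,reference_mask binary masks of equal shape.
#' @return list with \code{dsc}, \code{mssd} and \code{n_result_points}.
#' @export
evaluate_masks <- function(result_mask, reference_mask) {
  rc <- extract_zero_contour(sdf_from_mask(result_mask))
  qc <- extract_zero_contour(sdf_from_mask(reference_mask))
  list(dsc = dsc(result_mask, reference_mask),
       mssd = mssd(rc, qc),
       n_result_points = nrow(rc))
}
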