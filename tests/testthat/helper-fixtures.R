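# Shared fixtures and independent oracles.

disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  if (length(center) == 1L) center <- c(center, center)
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - center[1L])^2 + (j - center[2L])^2 <= radius^2)
}

square_mask <- function(n, half_side, center = (n + 1) / 2) {
  outer(seq_len(n), seq_len(n),
        function(i, j) abs(i - center) <= half_side & abs(j - center) <= half_side)
}

# Exact (analytic) signed distance of a circle, negative inside.
circle_sdf <- function(n, center, radius) {
  outer(seq_len(n), seq_len(n),
        function(i, j) sqrt((i - center[1L])^2 + (j - center[2L])^2) - radius)
}

# Brute-force O(N^2 r^2) localized means, the oracle for local_means_field.
brute_local_means <- function(image, phi, x, r, epsilon) {
  h <- smooth_heaviside(phi, epsilon)
  w_in <- 1 - h
  H <- nrow(image); W <- ncol(image)
  ni <- 0L; no <- 0L; num_in <- 0; den_in <- 0; num_out <- 0; den_out <- 0
  for (a in seq_len(H)) for (b in seq_len(W)) {
    if ((a - x[1L])^2 + (b - x[2L])^2 <= r^2) {
      if (phi[a, b] < 0) ni <- ni + 1L else no <- no + 1L
      num_in <- num_in + image[a, b] * w_in[a, b]
      den_in <- den_in + w_in[a, b]
      num_out <- num_out + image[a, b] * h[a, b]
      den_out <- den_out + h[a, b]
    }
  }
  list(mu_in = if (ni > 0L) num_in / den_in else NA_real_,
       mu_out = if (no > 0L) num_out / den_out else NA_real_,
       n_in = ni, n_out = no)
}

# Brute-force point-to-closed-polyline squared distance (per-segment scan),
# the oracle for mssd.
brute_mssd <- function(p, q) {
  seg_d2 <- function(pt, a, b) {
    ab <- b - a
    t <- sum((pt - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    sum((pt - a - t * ab)^2)
  }
  qs <- rbind(q, q[1L, ])
  mean(vapply(seq_len(nrow(p)), function(i) {
    min(vapply(seq_len(nrow(q)), function(j)
      seg_d2(p[i, ], qs[j, ], qs[j + 1L, ]), numeric(1L)))
  }, numeric(1L)))
}

# Perimeter of a closed polyline.
polyline_perimeter <- function(pts) {
  pp <- rbind(pts, pts[1L, ])
  sum(sqrt(rowSums((pp[-1L, , drop = FALSE] - pp[-nrow(pp), , drop = FALSE])^2)))
}

# Symmetric Hausdorff distance between two point sets (vertex-based).
hausdorff_points <- function(a, b) {
  d2 <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    (a[i, 1L] - b[j, 1L])^2 + (a[i, 2L] - b[j, 2L])^2)
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}
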