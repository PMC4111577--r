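# S3 methods for slcv_fit / mslcv_fit objects.

#' @export
print.slcv_fit <- function(x, ...) {
  kind <- if (inherits(x, "mslcv_fit")) "Multi-scale (MSLCV)" else "Single-scale (SLCV)"
  cat(kind, "localized active-contour segmentation\n")
  cat(sprintf("  image: %d x %d px\n", x$image_dim[1L], x$image_dim[2L]))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "budget exhausted"))
  cat(sprintf("  segmented area: %d px (%.1f%% of image)\n", sum(x$mask),
              100 * mean(x$mask)))
  cat(sprintf("  settings: radius = %d, beta = %.3g, band = %g, mu = %.3g\n",
              x$settings$radius, x$settings$beta, x$settings$band_halfwidth,
              x$settings$mu))
  invisible(x)
}

#' @export
summary.slcv_fit <- function(object, ...) {
  print(object)
  d <- object$diagnostics
  if (nrow(d)) {
    cat("  per-stage iterations:",
        paste(sprintf("stage %d: %d", unique(d$stage),
                      tabulate(d$stage)[unique(d$stage)]), collapse = ", "),
        "\n")
    cat(sprintf("  final mean |delta phi| on band: %.2e\n",
                d$mean_dphi[nrow(d)]))
  }
  cat(sprintf("  force evaluations (pixels x iterations): %.3g\n",
              object$force_evals))
  invisible(object)
}

#' @export
fitted.slcv_fit <- function(object, ...) object$mask

#' Plot a segmentation result
#'
#' Grayscale image with the final contour (solid) and the initial contour
#' (dashed) overlaid.
#'
#' @param x an \code{slcv_fit}.
#' @param image optional intensity matrix to display under the contours
#'   (defaults to the fitted mask).
#' @param ... passed to \code{graphics::image}.
#' @export
plot.slcv_fit <- function(x, image = NULL, ...) {
  bg <- if (is.null(image)) x$mask * 1.0 else image
  H <- nrow(bg); W <- ncol(bg)
  # transpose + flip rows so that row 1 is drawn at the top
  graphics::image(x = seq_len(W), y = seq_len(H), z = t(bg[H:1, , drop = FALSE]),
                  col = gray(seq(0, 1, length.out = 256)), asp = 1,
                  xlab = "col", ylab = "row", useRaster = TRUE, ...)
  draw <- function(ctr, ...) {
    if (is.null(ctr)) return(invisible())
    p <- rbind(ctr, ctr[1L, ])
    graphics::lines(p[, "col"], H + 1 - p[, "row"], ...)
  }
  draw(x$contour, col = "red", lwd = 2)
  if (!is.null(x$init_mask) && sum(x$init_mask) > 0 &&
      sum(x$init_mask) < length(x$init_mask))
    draw(extract_zero_contour(sdf_from_mask(x$init_mask)),
         col = "yellow", lty = 2)
  invisible(x)
}
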