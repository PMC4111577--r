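# Image, mask and contour plumbing. Images are numeric [row, col] matrices in
# [0,1]; EBImage stores [x, y] so every read/write transposes.

#' Load a grayscale image
#'
#' Reads a PNG or TIFF image (8- or 16-bit, grayscale or RGB) and returns a
#' numeric matrix indexed \code{[row, col]} with intensities linearly rescaled
#' so the observed minimum maps to 0 and the maximum to 1. RGB input is
#' converted by the unweighted channel mean before rescaling. A constant image
#' maps to all zeros.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix, values in \code{[0, 1]}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)  # luminance = channel mean
  m <- t(a)  # EBImage [x, y] -> [row, col]
  if (length(m) == 0L) stop("zero-area image: ", path)
  if (nrow(m) < 16L || ncol(m) < 16L)
    stop("image smaller than 16x16: pyramid and radius logic degenerate")
  if (any(!is.finite(m))) stop("non-finite pixel values in ", path)
  rescale01(m)
}

#' Rescale intensities to [0, 1]
#'
#' Linear min-max rescale; a constant matrix maps to all zeros. Monotone:
#' pixel ordering by intensity is preserved.
#'
#' @param m numeric matrix.
#' @return numeric matrix in \code{[0, 1]}.
#' @export
rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(array(0, dim(m)))
  (m - lo) / (hi - lo)
}

#' Save a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0; the file round-trips
#' bit-exactly through [load_mask()].
#'
#' @param mask logical or 0/1 matrix \code{[row, col]}.
#' @param path output PNG path.
#' @param image_shape optional \code{c(H, W)} the mask must match.
#' @export
save_mask <- function(mask, path, image_shape = NULL) {
  mask <- as_mask(mask)
  if (!is.null(image_shape) && !all(dim(mask) == image_shape))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match declared image shape ",
         paste(image_shape, collapse = "x"))
  EBImage::writeImage(t(mask * 1.0), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Load a binary mask from an image file
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path image path.
#' @return logical matrix \code{[row, col]}.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  t(a) > 0
}

#' Save a contour polyline as CSV
#'
#' Writes a two-column CSV with header \code{row,col}; the polyline is closed
#' implicitly (the first point is not repeated).
#'
#' @param contour \code{n x 2} matrix (\code{row, col}), \code{n >= 3}.
#' @param path output CSV path.
#' @export
save_contour <- function(contour, path) {
  contour <- as_contour(contour)
  df <- data.frame(row = contour[, 1L], col = contour[, 2L])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a contour polyline from CSV
#'
#' @param path CSV written by [save_contour()].
#' @return \code{n x 2} matrix with columns \code{row, col}.
#' @export
load_contour <- function(path) {
  df <- read.csv(path)
  as_contour(cbind(row = df$row, col = df$col))
}

# Validate/coerce a contour: >= 3 points, no two consecutive points identical.
as_contour <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("a contour is an n x 2 (row, col) matrix")
  if (nrow(points) < 3L) stop("a contour needs at least 3 points")
  storage.mode(points) <- "double"
  d <- rowSums((points - points[c(2:nrow(points), 1L), , drop = FALSE])^2)
  if (any(d[-length(d)] == 0))
    stop("contour has two identical consecutive points")
  colnames(points) <- c("row", "col")
  points
}

# Validate/coerce a binary mask to logical [row, col].
as_mask <- function(mask) {
  if (is.logical(mask)) m <- mask
  else m <- mask > 0
  if (!is.matrix(m)) stop("mask must be a matrix")
  m
}

#' Read segmentation parameters from a YAML file
#'
#' Every field is optional; missing fields take the [seg_params()] defaults.
#'
#' @param path YAML file.
#' @return a \code{seg_params} object.
#' @export
read_params_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(seg_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  do.call(seg_params, vals)
}

#' Write segmentation parameters to a YAML file
#'
#' @param params a \code{seg_params} object.
#' @param path output path.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "seg_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
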