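#' Remap image intensities to a new range
#'
#' Linear (affine) remap of the input range \[`in_low`, `in_high`\] onto the
#' output range \[`out_low`, `out_high`\]; intensities outside the input range
#' are clipped to the corresponding output endpoint. This is the standard
#' intensity-adjustment enhancement used before clustering: stretching the
#' observed range to the full 8-bit scale increases contrast between tissue
#' and tumor without altering intensity order.
#'
#' @param img numeric matrix of intensities.
#' @param in_low,in_high input range; `in_low < in_high` required.
#' @param out_low,out_high output range; `out_low <= out_high`.
#' @return Remapped matrix, same shape.
#' @export
#' @examples
#' adjust_intensity(matrix(c(0, 50, 100)), 50, 100, 0, 255)
adjust_intensity <- function(img, in_low, in_high, out_low = 0, out_high = 255) {
  if (in_low >= in_high) stop("in_low must be < in_high", call. = FALSE)
  if (out_low > out_high) stop("out_low must be <= out_high", call. = FALSE)
  out <- out_low + (img - in_low) / (in_high - in_low) * (out_high - out_low)
  pmin(pmax(out, out_low), out_high)
}

#' Stretch an image to the full 8-bit range
#'
#' Applies [adjust_intensity()] with the observed min/max as input range and
#' \[0, 255\] as output. A constant image has no range to stretch; by
#' convention every pixel then maps to 0.
#'
#' @param img numeric matrix.
#' @return Enhanced matrix in \[0, 255\].
#' @export
auto_enhance <- function(img) {
  r <- range(img)
  if (r[1] == r[2]) return(matrix(0, nrow(img), ncol(img)))
  adjust_intensity(img, r[1], r[2], 0, 255)
}

#' Image contrast
#'
#' The difference between the largest and smallest intensity in the image.
#'
#' @param img nonempty numeric matrix.
#' @return Scalar contrast.
#' @export
image_contrast <- function(img) {
  if (length(img) == 0) stop("empty image", call. = FALSE)
  max(img) - min(img)
}

#' Intensity-to-colour lookup table
#'
#' A fixed 256-entry RGB table used by [color_label()]. The table is a
#' piecewise-linear ramp from dark navy through teal to copper, with anchor
#' colours at intensities 0, 160, 200 and 255. Its defining property is its
#' arc-length profile: slow (~0.5 per intensity unit) over the dark range
#' where background and normal tissue live, fast (~4) across the 160--200
#' gap, and slow again (~0.7) over the bright tumor range. Dark tissue and
#' bright tumor intensities are each compressed into compact colour
#' clusters while the gap between them is stretched, so a K=2 clustering
#' isolates the bright region and stays robust when noise blurs the
#' intensity histogram.
#'
#' @return A 256 x 3 numeric matrix (rows = intensities 0..255, columns =
#'   R, G, B channels in \[0, 255\]).
#' @export
tumor_colormap <- function() {
  xi <- c(0, 160, 200, 255)
  cbind(R = stats::approx(xi, c(0, 0, 136, 170), 0:255)$y,
        G = stats::approx(xi, c(0, 60, 92, 100), 0:255)$y,
        B = stats::approx(xi, c(90, 150, 70, 50), 0:255)$y)
}

#' Colour-label a grayscale image
#'
#' Maps each intensity to an RGB triple through the fixed 256-entry lookup
#' table. Non-integer intensities are rounded to the nearest table row.
#' Equal intensities always map to equal colours.
#'
#' @param img numeric matrix with values in \[0, 255\].
#' @param colormap a 256 x 3 lookup table, default [tumor_colormap()].
#' @return An `height x width x 3` numeric array (RGB image).
#' @export
color_label <- function(img, colormap = tumor_colormap()) {
  if (any(img < 0 | img > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  stopifnot(nrow(colormap) == 256, ncol(colormap) == 3)
  idx <- round(img) + 1
  array(c(colormap[idx, 1], colormap[idx, 2], colormap[idx, 3]),
        dim = c(nrow(img), ncol(img), 3))
}

#' Flatten an image into a per-pixel feature set
#'
#' Pixels are flattened row-major: the pixel at image position (r, c) becomes
#' feature row `(r - 1) * width + c`. For a grayscale matrix the feature
#' dimension is 1; for an RGB array it is 3. The set records `z_max`, the
#' maximum value over all entries, used by the clustering objective's
#' separation term, and the original shape for reshaping label vectors back
#' into maps.
#'
#' @param img numeric matrix (grayscale) or `h x w x 3` array (RGB).
#' @return An object of class `pixel_features`: list with `features`
#'   (N x d matrix), `z_max`, `origin_shape` (height, width) and `d`.
#' @export
extract_features <- function(img) {
  if (is.matrix(img)) {
    feats <- matrix(as.vector(t(img)), ncol = 1)
  } else if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    feats <- cbind(as.vector(t(img[, , 1])),
                   as.vector(t(img[, , 2])),
                   as.vector(t(img[, , 3])))
  } else {
    stop("img must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  structure(list(features = feats, z_max = max(feats),
                 origin_shape = c(dim(img)[1], dim(img)[2]),
                 d = ncol(feats)),
            class = "pixel_features")
}

#' @export
print.pixel_features <- function(x, ...) {
  cat(sprintf("pixel feature set: N = %d, d = %d, z_max = %g (image %dx%d)\n",
              nrow(x$features), x$d, x$z_max,
              x$origin_shape[1], x$origin_shape[2]))
  invisible(x)
}

# Reshape a per-pixel vector (row-major pixel order) back to an image matrix.
reshape_to_image <- function(v, shape) {
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

as_feature_matrix <- function(features) {
  if (inherits(features, "pixel_features")) features$features
  else as.matrix(features)
}
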