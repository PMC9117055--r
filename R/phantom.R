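#' Specify a synthetic brain phantom
#'
#' A phantom is a 2-D grayscale image made of three nested regions: a dark
#' background, a brighter brain-like ellipse, and an even brighter tumor
#' ellipse wholly inside the brain. Additive Gaussian noise (clipped to
#' \[0, 255\]) completes the image. Phantoms carry an exact ground-truth tumor
#' mask, so every stage of the segmentation pipeline can be validated without
#' external imaging data.
#'
#' Ellipses are rasterized by a centre-of-pixel point-in-ellipse test: pixel
#' (r, c) belongs to an ellipse with centre (r0, c0) and semi-axes (ar, ac)
#' iff ((r - r0)/ar)^2 + ((c - c0)/ac)^2 <= 1.
#'
#' @param height,width image size in pixels.
#' @param brain_center,brain_axes centre (row, col) and semi-axes (rows, cols)
#'   of the brain ellipse, in pixels.
#' @param tumor_center,tumor_axes centre and semi-axes of the tumor ellipse,
#'   which must lie wholly inside the brain ellipse and the frame.
#' @param background_level,brain_level,tumor_level region intensities on the
#'   8-bit scale; must be strictly increasing.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units (>= 0).
#' @param seed optional integer seed fixing the noise realisation.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_batch()]
#' @export
#' @examples
#' spec <- phantom_spec(noise_sd = 10, seed = 1)
#' ph <- generate_phantom(spec)
#' range(ph$image)
phantom_spec <- function(height = 128, width = 128,
                         brain_center = c(64.5, 64.5), brain_axes = c(30, 36),
                         tumor_center = c(72, 78), tumor_axes = c(13, 16),
                         background_level = 10, brain_level = 120,
                         tumor_level = 220, noise_sd = 0, seed = NULL) {
  spec <- structure(list(
    height = height, width = width,
    brain_center = as.numeric(brain_center), brain_axes = as.numeric(brain_axes),
    tumor_center = as.numeric(tumor_center), tumor_axes = as.numeric(tumor_axes),
    background_level = background_level, brain_level = brain_level,
    tumor_level = tumor_level, noise_sd = noise_sd, seed = seed
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$height >= 1, spec$width >= 1)
  if (spec$noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!(spec$background_level < spec$brain_level &&
        spec$brain_level < spec$tumor_level))
    stop("intensity levels must satisfy background < brain < tumor",
         call. = FALSE)
  if (any(spec$brain_axes <= 0) || any(spec$tumor_axes <= 0))
    stop("ellipse semi-axes must be positive", call. = FALSE)
  # containment: every rasterized tumor pixel must be a brain pixel, and the
  # tumor bounding box must stay in frame
  lo <- spec$tumor_center - spec$tumor_axes
  hi <- spec$tumor_center + spec$tumor_axes
  if (lo[1] < 1 || lo[2] < 1 || hi[1] > spec$height || hi[2] > spec$width)
    stop("tumor ellipse extends outside the image frame", call. = FALSE)
  tum <- ellipse_mask(spec$height, spec$width, spec$tumor_center, spec$tumor_axes)
  brn <- ellipse_mask(spec$height, spec$width, spec$brain_center, spec$brain_axes)
  if (any(tum & !brn))
    stop("tumor ellipse is not wholly inside the brain ellipse", call. = FALSE)
  if (!any(tum))
    stop("tumor ellipse rasterizes to zero pixels", call. = FALSE)
  invisible(spec)
}

#' Rasterize an ellipse as a logical mask
#'
#' Centre-of-pixel point-in-ellipse test on an `height` x `width` grid.
#'
#' @param height,width grid size.
#' @param center centre (row, col).
#' @param axes semi-axes (rows, cols).
#' @return Logical matrix, `TRUE` inside the ellipse.
#' @export
ellipse_mask <- function(height, width, center, axes) {
  r <- ((seq_len(height) - center[1]) / axes[1])^2
  c <- ((seq_len(width) - center[2]) / axes[2])^2
  outer(r, c, `+`) <= 1
}

#' Generate one synthetic brain phantom
#'
#' Renders the three-level image described by a [phantom_spec()], adds
#' Gaussian noise of sd `noise_sd`, clips to \[0, 255\], and returns the image
#' together with the exact tumor mask. Identical spec + seed gives bit
#' identical output.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `brain_phantom`: a list with `image` (numeric
#'   matrix in \[0, 255\]), `mask` (logical matrix, `TRUE` on tumor pixels) and
#'   the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  brn <- ellipse_mask(spec$height, spec$width, spec$brain_center, spec$brain_axes)
  tum <- ellipse_mask(spec$height, spec$width, spec$tumor_center, spec$tumor_axes)
  img <- matrix(spec$background_level, spec$height, spec$width)
  img[brn] <- spec$brain_level
  img[tum] <- spec$tumor_level
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                        spec$height, spec$width)
    img <- pmin(pmax(img, 0), 255)
  }
  structure(list(image = img, mask = tum, spec = spec),
            class = "brain_phantom")
}

#' Generate a batch of phantoms with jittered tumors
#'
#' Draws `n` phantoms from a seeded stream, jittering the tumor centre
#' (uniform +/- 6 px per axis) and semi-axes (uniform scale 0.8--1.2) around
#' the base spec. Jittered geometry violating the containment invariants is
#' resampled. Reproducible for a fixed `seed`.
#'
#' @param spec base [phantom_spec()]; its `seed` field is ignored here.
#' @param n number of phantoms (>= 1).
#' @param seed integer seed for the whole batch stream.
#' @return List of `n` [generate_phantom()] results.
#' @export
generate_batch <- function(spec, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    for (attempt in 1:100) {
      s <- spec
      s$seed <- NULL
      s$tumor_center <- spec$tumor_center + stats::runif(2, -6, 6)
      s$tumor_axes <- spec$tumor_axes * stats::runif(2, 0.8, 1.2)
      ok <- tryCatch({ validate_phantom_spec(s); TRUE },
                     error = function(e) FALSE)
      if (ok) return(generate_phantom(s))
    }
    stop("could not draw a valid jittered tumor ellipse in 100 attempts",
         call. = FALSE)
  })
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat(sprintf("brain phantom %dx%d, tumor pixels: %d, noise sd: %g\n",
              nrow(x$image), ncol(x$image), sum(x$mask), x$spec$noise_sd))
  invisible(x)
}

#' Write a phantom to PNG files
#'
#' The image is written as 8-bit grayscale PNG, the mask (if a path is given)
#' as a 0/255 binary PNG.
#'
#' @param phantom a `brain_phantom`.
#' @param image_path path for the grayscale image PNG.
#' @param mask_path optional path for the mask PNG.
#' @return Invisibly, `image_path`.
#' @export
write_phantom <- function(phantom, image_path, mask_path = NULL) {
  write_gray_png(phantom$image, image_path)
  if (!is.null(mask_path)) write_mask_png(phantom$mask, mask_path)
  invisible(image_path)
}
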