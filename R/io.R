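#' Read a grayscale image from PNG or TIFF
#'
#' The decoded image is rescaled to the 8-bit \[0, 255\] intensity scale the
#' pipeline assumes. A colour file is collapsed to grayscale with the
#' Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix in \[0, 255\].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Write a binary mask as 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask * 1), path)
  invisible(path)
}

#' Write a cluster label map as an indexed-colour PNG
#'
#' Each cluster index gets a distinct colour from an evenly spaced hue
#' palette.
#'
#' @param label_map integer matrix of labels in 1..k.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_label_png <- function(label_map, path) {
  k <- max(label_map)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(max(k, 2), "viridis")) / 255
  h <- nrow(label_map); w <- ncol(label_map)
  arr <- array(0, c(h, w, 3))
  for (ch in 1:3)
    arr[, , ch] <- matrix(pal[ch, label_map], h, w)
  png::writePNG(arr, path)
  invisible(path)
}
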