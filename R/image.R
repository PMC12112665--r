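# Image preprocessing: resize, unsharp masking, contrast/brightness,
# pixel-intensity scaling. Images are plain numeric arrays, H x W or
# H x W x C, with integer-valued intensities in [0, 255] ("raw" images)
# or real intensities in [0, 1] ("normalized" images).

as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (!is.array(img) || !(length(dim(img)) == 3L)) {
    stop_invalid("image must be an H x W or H x W x C array")
  }
  if (!dim(img)[3] %in% c(1L, 3L)) stop_invalid("image must have 1 or 3 channels")
  if (any(!is.finite(img))) stop_invalid("image contains non-finite values")
  img
}

check_raw_range <- function(img) {
  if (min(img) < 0 || max(img) > 255) {
    stop_invalid("raw image intensities must lie in [0, 255]")
  }
  img
}

#' Resize an image to a target width, preserving aspect ratio
#'
#' The output width equals `target_width`; the height is
#' `round(H * target_width / W)`. Bilinear interpolation is used (via
#' EBImage); when the width is already the target the input is returned
#' unchanged.
#'
#' @param img Numeric array, H x W (grayscale) or H x W x C, values in
#'   \[0, 255\].
#' @param target_width Positive integer output width in pixels.
#' @return Resized image array with integer-valued intensities in \[0, 255\].
#' @export
#' @examples
#' img <- matrix(0, 4, 8)
#' dim(resize_preserve_aspect(img, 4))  # 2 x 4
resize_preserve_aspect <- function(img, target_width) {
  was_matrix <- is.matrix(img)
  img <- check_raw_range(as_image_array(img))
  if (length(target_width) != 1 || !is.finite(target_width) || target_width < 1) {
    stop_invalid("target_width must be a positive integer")
  }
  target_width <- as.integer(target_width)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (target_width == w) {
    return(if (was_matrix && dim(img)[3] == 1L) img[, , 1] else img)
  }
  new_h <- max(1L, as.integer(round(h * target_width / w)))
  # EBImage stores images x-first (width, height, channel)
  xw <- aperm(img, c(2, 1, 3)) / 255
  out <- EBImage::resize(EBImage::Image(xw, colormode = "Grayscale"),
                         w = target_width, h = new_h)
  out <- aperm(array(as.numeric(out), dim = c(target_width, new_h, dim(img)[3])),
               c(2, 1, 3))
  out <- round(pmin(pmax(out * 255, 0), 255))
  if (was_matrix && dim(out)[3] == 1L) out[, , 1] else out
}

gaussian_blur <- function(img, radius) {
  if (radius == 0) return(img)
  xw <- aperm(img, c(2, 1, 3)) / 255
  # kernel must not exceed the image; keep it odd
  ksize <- 2L * as.integer(ceiling(3 * radius)) + 1L
  kmax <- min(dim(img)[1:2])
  if (kmax %% 2L == 0L) kmax <- kmax - 1L
  bl <- EBImage::gblur(EBImage::Image(xw, colormode = "Grayscale"),
                       sigma = radius, radius = min(ksize, kmax))
  aperm(array(as.numeric(bl), dim = dim(xw)), c(2, 1, 3)) * 255
}

#' Unsharp-mask sharpening
#'
#' Adds back the difference between the image and its Gaussian blur:
#' `out = in + amount * (in - blur(in, radius))`, applied only where the
#' absolute difference exceeds `threshold`, then clipped to \[0, 255\] and
#' rounded. Sharpens edges and fine facial detail (wrinkles, muscle tension)
#' ahead of landmark detection.
#'
#' @inheritParams resize_preserve_aspect
#' @param radius Gaussian blur sigma in pixels (>= 0; 0 leaves the image
#'   unchanged).
#' @param amount Sharpening gain (>= 0; 0 leaves the image unchanged).
#' @param threshold Minimum absolute input-blur difference (intensity units)
#'   for a pixel to be sharpened.
#' @return Sharpened image array, same shape as the input.
#' @export
unsharp_mask <- function(img, radius = 2, amount = 1.5, threshold = 3) {
  was_matrix <- is.matrix(img)
  img <- check_raw_range(as_image_array(img))
  if (radius < 0 || amount < 0 || threshold < 0) {
    stop_invalid("radius, amount and threshold must be non-negative")
  }
  if (radius == 0 || amount == 0) {
    return(if (was_matrix && dim(img)[3] == 1L) img[, , 1] else img)
  }
  diff <- img - gaussian_blur(img, radius)
  out <- img + amount * diff * (abs(diff) > threshold)
  out <- round(pmin(pmax(out, 0), 255))
  if (was_matrix && dim(out)[3] == 1L) out[, , 1] else out
}

#' Contrast and brightness adjustment
#'
#' Contrast scales each pixel's deviation from the global image mean by
#' `contrast`; brightness then scales the result by `brightness`. The output
#' is clipped to \[0, 255\] and rounded. `contrast = 1, brightness = 1` is
#' the identity; `contrast = 0` collapses the image to its (brightness
#' scaled) mean.
#'
#' @inheritParams resize_preserve_aspect
#' @param contrast Non-negative contrast factor.
#' @param brightness Non-negative brightness factor.
#' @return Adjusted image array, same shape as the input.
#' @export
#' @examples
#' adjust_contrast_brightness(matrix(c(100, 200), 1), contrast = 2)
adjust_contrast_brightness <- function(img, contrast = 1, brightness = 1) {
  was_matrix <- is.matrix(img)
  img <- check_raw_range(as_image_array(img))
  if (contrast < 0 || brightness < 0) {
    stop_invalid("contrast and brightness must be non-negative")
  }
  m <- mean(img)
  out <- brightness * (m + contrast * (img - m))
  out <- round(pmin(pmax(out, 0), 255))
  if (was_matrix && dim(out)[3] == 1L) out[, , 1] else out
}

#' Scale pixel intensities to \[0, 1\]
#'
#' Maps every intensity v to v/255, putting all images on a common scale to
#' reduce the influence of lighting variation.
#'
#' @inheritParams resize_preserve_aspect
#' @return Image array with real values in \[0, 1\].
#' @export
#' @examples
#' normalize_pixels(matrix(c(0, 51, 255), 1))
normalize_pixels <- function(img) {
  was_matrix <- is.matrix(img)
  img <- check_raw_range(as_image_array(img))
  out <- img / 255
  if (was_matrix && dim(out)[3] == 1L) out[, , 1] else out
}

#' Read an image file
#'
#' Reads PNG or TIFF into the raw \[0, 255\] array convention used by the
#' preprocessing functions. An alpha channel, if present, is dropped.
#'
#' @param path Path to a .png or .tif/.tiff file.
#' @return Numeric array H x W (grayscale) or H x W x 3 with values in
#'   \[0, 255\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("image not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop_config("package 'png' required")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop_config("package 'tiff' required")
      tiff::readTIFF(path)
    },
    stop_parse(paste0("unsupported image format: .", ext))
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1]
  round(px * 255)
}

#' Standard preprocessing pipeline for a face image
#'
#' Resize to a consistent width, unsharp-mask sharpening, contrast and
#' brightness adjustment, then pixel scaling to \[0, 1\]. Default parameters:
#' width 480 px, unsharp radius 2 / amount 1.5 / threshold 3, neutral
#' contrast and brightness.
#'
#' @inheritParams resize_preserve_aspect
#' @inheritParams unsharp_mask
#' @inheritParams adjust_contrast_brightness
#' @return Normalized image array with values in \[0, 1\].
#' @export
preprocess_image <- function(img, target_width = 480, radius = 2, amount = 1.5,
                             threshold = 3, contrast = 1, brightness = 1) {
  img |>
    resize_preserve_aspect(target_width) |>
    unsharp_mask(radius = radius, amount = amount, threshold = threshold) |>
    adjust_contrast_brightness(contrast = contrast, brightness = brightness) |>
    normalize_pixels()
}
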