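#' Calibrated intensity image
#'
#' A plain numeric matrix carrying its physical pixel calibration. All
#' downstream measurements (areas, distances, axis lengths) are reported in
#' micrometres using `pixel_size`. The coordinate convention is row-major
#' with the origin at the top-left corner: `x` runs along columns, `y` along
#' rows, both 0-based, so a pixel at matrix position `[r, c]` sits at
#' physical position `((c - 1) * pixel_size, (r - 1) * pixel_size)` µm.
#'
#' Only isotropic pixels are supported; the measurements these pipelines
#' implement assume isotropy.
#'
#' @param pixels Numeric matrix of intensities (at least 2 x 2).
#' @param pixel_size Side length of a pixel in µm (single positive number).
#'   A length-2 vector is accepted only if both entries are equal;
#'   anisotropic calibration is an error.
#' @param channel_name Free-text channel label.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size, channel_name = "") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must have at least 2 rows and 2 columns")
  pixel_size <- check_pixel_size(pixel_size)
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel_name = as.character(channel_name)[1]),
    class = "calibrated_image"
  )
}

#' Binary mask with physical calibration
#'
#' Same shape and calibration rules as [calibrated_image()], but the pixel
#' array is logical. Used for vessel masks, sprouting-front masks,
#' artery-exclusion masks and junction masks.
#'
#' @param pixels Logical matrix (numeric input is coerced with `!= 0`).
#' @param pixel_size Pixel side length in µm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels)) stop("'pixels' must be logical or numeric")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("mask must have at least 2 rows and 2 columns")
  pixel_size <- check_pixel_size(pixel_size)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

check_pixel_size <- function(pixel_size) {
  if (length(pixel_size) == 2L) {
    if (!isTRUE(all.equal(pixel_size[1], pixel_size[2])))
      stop("anisotropic pixels are not supported")
    pixel_size <- pixel_size[1]
  }
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um per pixel)")
  as.numeric(pixel_size)
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              if (nzchar(x$channel_name)) paste0(", channel '", x$channel_name, "'") else ""))
  cat(sprintf("  field: %.4g x %.4g um, intensity range [%.4g, %.4g]\n",
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %.1f%% foreground\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              100 * mean(x$pixels)))
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, c("calibrated_image", "binary_mask"))) x$pixels else as.matrix(x)
}

# shared shape/calibration check for multi-input operations
check_same_geometry <- function(...) {
  objs <- list(...)
  objs <- objs[!vapply(objs, is.null, TRUE)]
  dims <- vapply(objs, function(o) dim(o$pixels), integer(2))
  ps <- vapply(objs, function(o) o$pixel_size, numeric(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inputs must share the same image shape")
  if (any(abs(ps - ps[1]) > 1e-9 * ps[1]))
    stop("inputs must share the same pixel size")
  invisible(TRUE)
}
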