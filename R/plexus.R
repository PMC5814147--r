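#' Segment vessels by global thresholding
#'
#' Thresholds a vessel-marker (IB4-like) image, closes small gaps with a
#' morphological closing, and removes speckle components below 10 µm².
#'
#' @param image A [calibrated_image()].
#' @param method `"otsu"` (default), `"fixed"` or `"percentile"`.
#' @param value Threshold value for `"fixed"` (intensity units) or
#'   `"percentile"` (in \[0, 1\]).
#' @param closing_radius Disc radius of the closing, px.
#' @param min_object_area Minimum vessel-component area kept, µm².
#' @return A [binary_mask()].
#' @export
segment_vessels <- function(image, method = c("otsu", "fixed", "percentile"),
                            value = NULL, closing_radius = 1,
                            min_object_area = 10) {
  method <- match.arg(method)
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) == 0 && method != "fixed") {
    warning("constant image: returning an empty vessel mask")
    return(binary_mask(matrix(FALSE, nrow(px), ncol(px)), image$pixel_size))
  }
  thr <- switch(method,
    otsu = {
      norm <- (px - rng[1]) / diff(rng)
      rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(norm))
    },
    fixed = { if (is.null(value)) stop("method 'fixed' needs 'value'"); value },
    percentile = {
      if (is.null(value)) stop("method 'percentile' needs 'value'")
      stats::quantile(px, value, names = FALSE)
    })
  bin <- px > thr
  if (closing_radius > 0 && any(bin)) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    bin <- EBImage::imageData(EBImage::closing(EBImage::Image(bin * 1), brush)) > 0
  }
  if (any(bin)) {
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
    sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
    small <- which(sizes * image$pixel_size^2 < min_object_area)
    bin[labels %in% small] <- FALSE
  }
  binary_mask(bin, image$pixel_size)
}

#' Extract the closed loops of a vessel network
#'
#' Loops are the bounded lacunae of the plexus: connected components of the
#' complement of the vessel mask that do not touch the image border.
#' Background components use 4-connectivity and the vessel foreground
#' 8-connectivity (the standard complementary pairing that avoids
#' topological paradoxes). Loops smaller than `min_loop_area` are removed;
#' the 86 µm² default is the artifact-exclusion cutoff used for plexus
#' regularity scoring.
#'
#' @param mask A [binary_mask()] (TRUE = vessel).
#' @param min_loop_area Smallest loop kept, µm².
#' @return A data frame of loop records: `id`, `area` (µm²), `perimeter`
#'   (µm, corrected chain-code contour length), `circularity`
#'   (4*pi*A/P², clamped to \[0, 1\]), centroid `x`, `y` (µm),
#'   `touches_border` (always FALSE for returned loops). A mask with no
#'   bounded complement yields 0 rows.
#' @export
extract_loops <- function(mask, min_loop_area = 86) {
  ps <- mask$pixel_size
  labels <- label_4conn(!mask$pixels)
  if (max(labels) == 0L) return(empty_loop_records())
  border <- setdiff(unique(c(labels[1, ], labels[nrow(labels), ],
                             labels[, 1], labels[, ncol(labels)])), 0L)
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- setdiff(which(sizes * ps^2 >= min_loop_area), border)
  if (!length(keep)) return(empty_loop_records())
  map <- integer(max(labels)); map[keep] <- seq_along(keep)
  relab <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  relab[nz] <- map[labels[nz]]
  perim <- perimeter_chain(relab) * ps
  rows <- lapply(seq_along(keep), function(k) {
    coords <- which(relab == k, arr.ind = TRUE)
    area <- nrow(coords) * ps^2
    data.frame(id = k, area = area, perimeter = perim[[k]],
               circularity = loop_circularity(area, perim[[k]]),
               x = mean(coords[, 2] - 1) * ps, y = mean(coords[, 1] - 1) * ps,
               touches_border = FALSE)
  })
  do.call(rbind, rows)
}

empty_loop_records <- function() {
  data.frame(id = integer(0), area = numeric(0), perimeter = numeric(0),
             circularity = numeric(0), x = numeric(0), y = numeric(0),
             touches_border = logical(0))
}

#' Circularity of a loop
#'
#' `4 * pi * area / perimeter^2`, the ImageJ circularity convention: 1 for a
#' disc, smaller for elongated or irregular shapes. Clamped to \[0, 1\]
#' because discrete perimeter estimates can push a rasterized disc slightly
#' above the isoperimetric bound.
#'
#' @param area Loop area, µm² (> 0). Vectorized.
#' @param perimeter Loop perimeter, µm (> 0).
#' @return Circularity in \[0, 1\].
#' @export
loop_circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  clamp(4 * pi * area / perimeter^2, 0, 1)
}

#' Plexus regularity statistics
#'
#' Cohort dispersion of the loop geometry — the regularity readout of a
#' vascular plexus — plus capillary density. Regularity is summarized as the
#' sample standard deviation (n-1 denominator) of loop area and of loop
#' circularity; capillary density is the vessel area divided by the field of
#' view area.
#'
#' @param loops Loop records from [extract_loops()].
#' @param mask Optional [binary_mask()] for vessel density.
#' @param min_loop_area The loop-size cutoff that produced `loops` (logged in
#'   the report).
#' @return A `regularity_report` list: `n_loops`, `mean_area`, `sd_area`,
#'   `mean_circularity`, `sd_circularity`, `vessel_density`,
#'   `min_loop_area`. With fewer than 2 loops the SDs are `NA` (undefined,
#'   never 0).
#' @export
regularity_stats <- function(loops, mask = NULL, min_loop_area = 86) {
  n <- nrow(loops)
  sds <- if (n >= 2L) c(stats::sd(loops$area), stats::sd(loops$circularity))
         else { if (n < 2L) warning("fewer than 2 loops: SDs undefined"); c(NA_real_, NA_real_) }
  density <- if (is.null(mask)) NA_real_ else mean(mask$pixels)
  structure(list(n_loops = n,
                 mean_area = if (n) mean(loops$area) else NA_real_,
                 sd_area = sds[1],
                 mean_circularity = if (n) mean(loops$circularity) else NA_real_,
                 sd_circularity = sds[2],
                 vessel_density = density,
                 min_loop_area = min_loop_area,
                 border_loops_excluded = TRUE),
            class = "regularity_report")
}

#' @export
print.regularity_report <- function(x, ...) {
  cat("<regularity_report>\n")
  cat(sprintf("  loops: %d (min area %.4g um^2, border loops excluded)\n",
              x$n_loops, x$min_loop_area))
  cat(sprintf("  area: mean %.4g um^2, SD %.4g um^2\n", x$mean_area, x$sd_area))
  cat(sprintf("  circularity: mean %.3f, SD %.3f\n",
              x$mean_circularity, x$sd_circularity))
  cat(sprintf("  vessel density: %s\n",
              if (is.na(x$vessel_density)) "NA" else sprintf("%.3f", x$vessel_density)))
  invisible(x)
}

#' Full plexus pipeline on one image or mask
#'
#' @param image A [calibrated_image()]; ignored if `mask` is given.
#' @param mask Optional precomputed [binary_mask()].
#' @param min_loop_area Loop-size cutoff, µm².
#' @param ... Passed to [segment_vessels()].
#' @return List with `mask`, `loops`, `report`.
#' @export
plexus_pipeline <- function(image = NULL, mask = NULL, min_loop_area = 86, ...) {
  if (is.null(mask)) {
    if (is.null(image)) stop("need an image or a mask")
    mask <- segment_vessels(image, ...)
  }
  loops <- extract_loops(mask, min_loop_area)
  list(mask = mask, loops = loops,
       report = regularity_stats(loops, mask, min_loop_area))
}
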