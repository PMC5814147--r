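#' Pairwise nematic alignment score
#'
#' The alignment score between two nuclear orientations. Nuclear long axes
#' are nematic (headless) directions, so the score must be invariant under
#' adding pi to either angle. The score is `cos(2 * (theta1 - theta2))`: the
#' unique smooth nematic-invariant interpolation through the three anchor
#' values 1, 0 and -1 at angle differences of 0, 45 and 90 degrees. Its
#' population mean under independent uniform orientations is exactly 0, so a
#' randomly oriented monolayer scores 0 on average and a perfectly parallel
#' one scores 1.
#'
#' @param theta1,theta2 Orientations in radians (any real values; the score
#'   is pi-periodic in each argument). Vectorized.
#' @return Numeric score(s) in \[-1, 1\].
#' @examples
#' pair_alignment(0, 0)        # parallel: 1
#' pair_alignment(0, pi / 4)   # 45 degrees: 0
#' pair_alignment(0, pi / 2)   # perpendicular: -1
#' @export
pair_alignment <- function(theta1, theta2) {
  # cospi keeps the 45/90 degree anchors exact (cos(pi/2) is only ~6e-17)
  cospi(2 * (theta1 - theta2) / pi)
}

#' Segment nuclei in a nuclear-stain image
#'
#' Standard nuclear segmentation for DAPI-like images: Gaussian smoothing
#' (sigma 1 px), global Otsu threshold, hole filling, watershed split of
#' touching nuclei on the Euclidean distance transform, area filter, and
#' exclusion of regions touching the image border.
#'
#' @param image A [calibrated_image()] (single channel).
#' @param min_area,max_area Area filter in µm².
#' @param watershed_tolerance Minimum depth (in distance-transform units, px)
#'   separating two watershed seeds; defaults to half the expected nucleus
#'   minor radius (2 px) — the standard touching-nuclei split.
#' @return An integer label matrix (0 = background); labels are contiguous.
#'   A blank or constant image yields an all-zero matrix.
#' @export
segment_nuclei <- function(image, min_area = 20, max_area = 500,
                           watershed_tolerance = 2) {
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) == 0) {
    warning("constant image: no nuclei segmented")
    return(matrix(0L, nrow(px), ncol(px)))
  }
  ps <- image$pixel_size
  norm <- (px - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = 1)
  bin <- sm > EBImage::otsu(sm)
  bin <- EBImage::fillHull(bin)
  dm <- EBImage::distmap(bin)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  labels <- filter_labels(labels, min_area / ps^2, max_area / ps^2,
                          exclude_border = TRUE)
  labels
}

# area filter (in px^2) + optional border exclusion + relabel contiguously
filter_labels <- function(labels, min_px, max_px, exclude_border = TRUE) {
  if (max(labels) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  drop <- which(sizes < min_px | sizes > max_px | sizes == 0L)
  if (exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border[border > 0L])
  }
  keep <- setdiff(seq_len(max(labels)), drop)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  out[nz] <- map[labels[nz]]
  out
}

#' Fit a moment-equivalent ellipse to one pixel region
#'
#' The ellipse with the same second central moments as the pixel set. The
#' orientation is the angle of the major axis with the image x-axis (the
#' column direction), folded into \[0, pi) because nuclear axes are nematic.
#'
#' @param region Two-column matrix of (row, col) pixel indices (>= 5 pixels),
#'   as from `which(labels == k, arr.ind = TRUE)`.
#' @param pixel_size Pixel side length in µm.
#' @param id,image_id Identifiers carried into the record.
#' @return A one-row data frame (a nucleus record): `id`, centroid `x`, `y`
#'   (µm), orientation `theta` (radians in \[0, pi)), `major_axis`,
#'   `minor_axis` (µm), `area` (µm²), `image_id`.
#' @export
fit_ellipse <- function(region, pixel_size = 1, id = 1L, image_id = "") {
  region <- as.matrix(region)
  if (nrow(region) < 5L) stop("region must have at least 5 pixels")
  pixel_size <- check_pixel_size(pixel_size)
  em <- ellipse_moments(region)
  minor <- em$minor * pixel_size
  if (minor <= 0) {
    warning("degenerate (collinear) region: minor axis clamped to one pixel")
    minor <- pixel_size
  }
  data.frame(id = as.integer(id),
             x = em$cx * pixel_size, y = em$cy * pixel_size,
             theta = em$theta,
             major_axis = em$major * pixel_size, minor_axis = minor,
             area = nrow(region) * pixel_size^2,
             image_id = image_id, stringsAsFactors = FALSE)
}

#' Nucleus records for every labeled region
#'
#' Applies [fit_ellipse()] to each label of a segmentation.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param pixel_size Pixel side length in µm.
#' @param image_id Identifier stored with each record.
#' @return A data frame of nucleus records (possibly 0 rows).
#' @export
nucleus_records <- function(labels, pixel_size = 1, image_id = "") {
  labs <- seq_len(max(labels, 0L))
  rows <- lapply(labs, function(k) {
    coords <- which(labels == k, arr.ind = TRUE)
    if (nrow(coords) < 5L) return(NULL)
    fit_ellipse(coords, pixel_size, id = k, image_id = image_id)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_nucleus_records())
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}

empty_nucleus_records <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0),
             theta = numeric(0), major_axis = numeric(0),
             minor_axis = numeric(0), area = numeric(0),
             image_id = character(0), stringsAsFactors = FALSE)
}

#' Distance-binned mean alignment curve of a monolayer
#'
#' For every unordered pair of nuclei in one image, computes the Euclidean
#' centroid distance and the pairwise alignment score, bins pairs by distance
#' into half-open bins `[lo, hi)` of `bin_width`, and averages the score per
#' bin. A curve of 1 in every bin means all cells are parallel; a randomly
#' oriented monolayer gives 0 in every bin (in expectation). Pairs at or
#' beyond `max_distance` are dropped.
#'
#' Bins with no pairs carry `NA` (flagged, never zero-filled).
#'
#' @param records Data frame of nucleus records from one image (>= 2 rows,
#'   single `image_id`).
#' @param bin_width Bin width in µm.
#' @param max_distance Maximum pair distance in µm (exclusive).
#' @return An `alignment_curve`: data frame with `bin_lo`, `bin_hi`,
#'   `mean_alignment`, `pair_count`, plus attribute `n_nuclei`.
#' @export
coordination_curve <- function(records, bin_width = 25, max_distance = 1000) {
  if (nrow(records) < 2L) stop("need at least 2 nucleus records")
  if (length(unique(records$image_id)) > 1L)
    stop("records span several images; pairs never cross images - ",
         "compute one curve per image and combine with aggregate_curves()")
  n <- nrow(records)
  x <- records$x; y <- records$y; th <- records$theta
  nb <- as.integer(ceiling(max_distance / bin_width))
  sums <- numeric(nb); cnts <- numeric(nb)
  chunk <- max(1L, min(500L, n))
  for (a in seq(1L, n - 1L, by = chunk)) {
    b <- min(a + chunk - 1L, n - 1L)
    i <- a:b
    dx <- outer(x[i], x, "-"); dy <- outer(y[i], y, "-")
    dd <- sqrt(dx * dx + dy * dy)
    keep <- outer(i, seq_len(n), "<") & dd < max_distance
    if (!any(keep)) next
    sc <- pair_alignment(outer(th[i], th, "-"), 0)
    bi <- bin_index(dd[keep], bin_width, max_distance)
    s <- sc[keep]
    agg <- rowsum(s, bi)   # only occupied bins are returned
    idx <- as.integer(rownames(agg))
    sums[idx] <- sums[idx] + agg[, 1]
    cnts <- cnts + tabulate(bi, nb)
  }
  edges <- bin_edges(bin_width, nb * bin_width)
  curve <- data.frame(bin_lo = edges[, "lo"], bin_hi = edges[, "hi"],
                      mean_alignment = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                      pair_count = as.integer(cnts))
  structure(curve, n_nuclei = n, class = c("alignment_curve", "data.frame"))
}

#' Combine alignment curves across images or experiments
#'
#' Pair-count-weighted mean per bin with summed pair counts, so the combined
#' curve equals the curve that would result from pooling all pairs (pairs
#' still never cross images).
#'
#' @param curves List of `alignment_curve` objects with identical bins.
#' @return An `alignment_curve`.
#' @export
aggregate_curves <- function(curves) {
  if (!length(curves)) stop("no curves to aggregate")
  ref <- curves[[1]]
  for (cv in curves[-1]) {
    if (nrow(cv) != nrow(ref) ||
        any(cv$bin_lo != ref$bin_lo) || any(cv$bin_hi != ref$bin_hi))
      stop("curves have mismatched bin definitions")
  }
  w <- sapply(curves, function(cv) cv$pair_count)
  v <- sapply(curves, function(cv) ifelse(cv$pair_count > 0, cv$mean_alignment, 0))
  if (is.null(dim(w))) { w <- matrix(w, nrow = 1); v <- matrix(v, nrow = 1) }
  tot <- rowSums(w)
  out <- data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi,
                    mean_alignment = ifelse(tot > 0, rowSums(v * w) / pmax(tot, 1), NA_real_),
                    pair_count = as.integer(tot))
  structure(out, n_nuclei = sum(vapply(curves, function(cv) attr(cv, "n_nuclei") %||% 0L,
                                       numeric(1))),
            class = c("alignment_curve", "data.frame"))
}

#' Full coordination pipeline on one image
#'
#' Segments nuclei, fits ellipses, and computes the alignment curve.
#'
#' @inheritParams segment_nuclei
#' @inheritParams coordination_curve
#' @param image_id Identifier for the records.
#' @return List with `records` and `curve`.
#' @export
coordination_pipeline <- function(image, min_area = 20, max_area = 500,
                                  bin_width = 25, max_distance = 1000,
                                  image_id = "") {
  labels <- segment_nuclei(image, min_area, max_area)
  records <- nucleus_records(labels, image$pixel_size, image_id)
  list(records = records,
       curve = coordination_curve(records, bin_width, max_distance))
}
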