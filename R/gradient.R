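#' Euclidean distance to the sprouting front
#'
#' Exact Euclidean distance of every pixel to the nearest front pixel,
#' in µm. Front pixels are at distance 0.
#'
#' @param front A [binary_mask()] marking the front (non-empty).
#' @return Numeric matrix of distances (µm), same shape as the mask.
#' @export
distance_to_front <- function(front) {
  if (!any(front$pixels)) stop("front mask is empty")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(!front$pixels)))
  d * front$pixel_size
}

#' Normalize a marker image to its extravascular mean
#'
#' Divides every pixel by the mean raw intensity over pixels outside the
#' vessel mask, so the extravascular mean of the result is 1 and
#' intravascular values read as fold-over-background. An empty vessel mask
#' degenerates to dividing the image by its own mean (warned).
#'
#' @param marker A [calibrated_image()].
#' @param vessel_mask A [binary_mask()] (TRUE = vessel).
#' @return A [calibrated_image()] of normalized intensities.
#' @export
normalize_marker <- function(marker, vessel_mask) {
  check_same_geometry(marker, vessel_mask)
  outside <- !vessel_mask$pixels
  if (!any(outside)) {
    warning("vessel mask covers the whole field: normalizing to the image mean")
    denom <- mean(marker$pixels)
  } else denom <- mean(marker$pixels[outside])
  if (!is.finite(denom) || denom <= 0)
    stop("extravascular mean intensity is not positive; cannot normalize")
  calibrated_image(marker$pixels / denom, marker$pixel_size,
                   paste0(marker$channel_name, " (normalized)"))
}

#' Distance-binned marker intensity profile from the front
#'
#' Normalizes the marker to its extravascular mean, computes the distance of
#' every pixel to the sprouting front, restricts to intravascular pixels
#' (excluding arteries if an artery mask is given), and averages the
#' normalized intensity in half-open distance bins `[lo, hi)` — by default
#' 15 µm bins from 0 to 500 µm. Pixels at or beyond `max_distance` are
#' dropped; empty bins carry `NA`.
#'
#' @param marker A [calibrated_image()] (raw marker channel).
#' @param vessel_mask A [binary_mask()] (TRUE = vessel).
#' @param front A [binary_mask()] marking the sprouting front (drawn
#'   upstream; there is no automatic front detection).
#' @param artery_mask Optional [binary_mask()] of pixels to exclude.
#' @param bin_width Bin width, µm.
#' @param max_distance Profile extent, µm.
#' @param background Optional constant background subtracted from the raw
#'   marker before normalization (default 0: operate on the raw channel).
#' @param replicate_id Identifier carried on the profile.
#' @return A `gradient_profile`: data frame with `bin_lo`, `bin_hi`,
#'   `mean_normalized_intensity`, `pixel_count`, plus attribute
#'   `replicate_id`.
#' @export
gradient_profile <- function(marker, vessel_mask, front, artery_mask = NULL,
                             bin_width = 15, max_distance = 500,
                             background = 0, replicate_id = "") {
  check_same_geometry(marker, vessel_mask, front, artery_mask)
  if (background != 0)
    marker <- calibrated_image(marker$pixels - background, marker$pixel_size,
                               marker$channel_name)
  norm <- normalize_marker(marker, vessel_mask)
  d <- distance_to_front(front)
  eligible <- vessel_mask$pixels
  if (!is.null(artery_mask)) eligible <- eligible & !artery_mask$pixels
  if (!any(eligible)) stop("no eligible intravascular pixels")
  nb <- as.integer(ceiling(max_distance / bin_width))
  bi <- bin_index(d[eligible], bin_width, max_distance)
  v <- norm$pixels[eligible]
  ok <- !is.na(bi)
  sums <- numeric(nb)
  agg <- rowsum(v[ok], bi[ok])   # only occupied bins are returned
  sums[as.integer(rownames(agg))] <- agg[, 1]
  cnts <- tabulate(bi[ok], nb)
  edges <- bin_edges(bin_width, nb * bin_width)
  out <- data.frame(bin_lo = edges[, "lo"], bin_hi = edges[, "hi"],
                    mean_normalized_intensity = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                    pixel_count = as.integer(cnts))
  structure(out, replicate_id = replicate_id,
            class = c("gradient_profile", "data.frame"))
}

#' Aggregate gradient profiles across replicates
#'
#' Unweighted mean and SEM across replicate curves per bin: each replicate
#' curve counts once regardless of how many pixels fed it. A bin where any
#' replicate lacks data is reported `NA` (flagged). With a single replicate
#' the mean is the curve itself and the SEM is undefined.
#'
#' @param profiles List of `gradient_profile` objects with identical bins.
#' @return An `aggregate_profile`: data frame with `bin_center`, `mean`,
#'   `sem`, `n_replicates`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to aggregate")
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (nrow(p) != nrow(ref) ||
        any(p$bin_lo != ref$bin_lo) || any(p$bin_hi != ref$bin_hi))
      stop("profiles have mismatched bin definitions")
  }
  vals <- sapply(profiles, function(p) p$mean_normalized_intensity)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  n <- length(profiles)
  complete <- rowSums(is.na(vals)) == 0
  mu <- ifelse(complete, rowMeans(vals), NA_real_)
  sem <- if (n >= 2) ifelse(complete, apply(vals, 1, stats::sd) / sqrt(n), NA_real_)
         else rep(NA_real_, nrow(vals))
  if (n < 2) warning("single replicate: SEM undefined")
  structure(data.frame(bin_center = (ref$bin_lo + ref$bin_hi) / 2,
                       mean = mu, sem = sem, n_replicates = n),
            class = c("aggregate_profile", "data.frame"))
}
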