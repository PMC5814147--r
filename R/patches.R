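#' Divide images into blinded patches
#'
#' Tiles each field into non-overlapping square patches — by default
#' (16 µm)² patches of a (160 µm)² field — and assigns every patch a
#' shuffled anonymous name so manual scoring can be done blind to the
#' source image and position. The mapping back to `(image, row, col)` is the
#' manifest, kept separately: it is the blinding key and the only way to
#' de-blind. Patch names carry no positional information.
#'
#' Trailing rows/columns that do not fill a whole patch are dropped with a
#' warning (acquisition fields are normally exact multiples of the patch
#' size).
#'
#' @param images A single image or a named list of them. Each element is a
#'   [calibrated_image()] or, for multi-channel fields, a named list of
#'   channel images sharing geometry.
#' @param patch_size Patch side length, µm.
#' @param seed Integer shuffle seed (shuffle is reproducible from it).
#' @param write_dir Optional directory: patches are written as TIFFs under
#'   their anonymous names and the manifest as `manifest.csv`.
#' @return A `patch_set`: list with `patches` (named by anonymous patch
#'   name, each mirroring the channel structure of its source),
#'   `manifest` (data frame: `patch_name`, `image_id`, `row`, `col`),
#'   `patch_size`, `seed`.
#' @export
make_patches <- function(images, patch_size = 16, seed = 1L,
                         write_dir = NULL) {
  images <- normalize_image_set(images)
  all_patches <- list(); src <- list()
  for (img_id in names(images)) {
    channels <- images[[img_id]]
    ps <- channels[[1]]$pixel_size
    size_px <- as.integer(round(patch_size / ps))
    if (size_px < 1L) stop("patch_size smaller than one pixel")
    nr <- nrow(channels[[1]]$pixels); nc <- ncol(channels[[1]]$pixels)
    if (size_px > nr || size_px > nc)
      stop("patch_size larger than the field")
    nrow_p <- nr %/% size_px; ncol_p <- nc %/% size_px
    if (nrow_p * size_px != nr || ncol_p * size_px != nc)
      warning(sprintf(
        "field '%s' (%d x %d px) is not a multiple of the patch size; dropping the remainder",
        img_id, nr, nc))
    for (r in seq_len(nrow_p)) for (c in seq_len(ncol_p)) {
      rows <- (r - 1L) * size_px + seq_len(size_px)
      cols <- (c - 1L) * size_px + seq_len(size_px)
      patch <- lapply(channels, function(ch)
        calibrated_image(ch$pixels[rows, cols], ps, ch$channel_name))
      if (length(patch) == 1L && identical(names(patch), "ch1"))
        patch <- patch[[1]]
      all_patches <- c(all_patches, list(patch))
      src <- c(src, list(data.frame(image_id = img_id, row = r, col = c,
                                    stringsAsFactors = FALSE)))
    }
  }
  n <- length(all_patches)
  if (!n) stop("no patches produced")
  manifest <- do.call(rbind, src)
  perm <- with_seed(seed, function() sample.int(n))
  names_anon <- sprintf("patch_%0*d", max(4L, nchar(n)), seq_len(n))
  # patch i (tiling order) receives the anonymous name at its shuffled rank
  manifest$patch_name <- names_anon[order(perm)]
  patches <- stats::setNames(all_patches, manifest$patch_name)
  # present patches and manifest in anonymous-name order (blind order)
  ord <- order(manifest$patch_name)
  manifest <- manifest[ord, c("patch_name", "image_id", "row", "col")]
  rownames(manifest) <- NULL
  patches <- patches[manifest$patch_name]
  out <- structure(list(patches = patches, manifest = manifest,
                        patch_size = patch_size, seed = as.integer(seed)),
                   class = "patch_set")
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(patches)) {
      p <- patches[[nm]]
      if (inherits(p, "calibrated_image"))
        write_image(p, file.path(write_dir, paste0(nm, ".tif")))
      else for (ch in names(p))
        write_image(p[[ch]], file.path(write_dir, paste0(nm, "_", ch, ".tif")))
    }
    write_table(manifest, file.path(write_dir, "manifest.csv"))
  }
  out
}

# Accepts: one calibrated_image; a list of calibrated_images (one image
# each); or a list whose elements are lists of channel images
# (multi-channel fields). Returns a named list of named channel lists.
normalize_image_set <- function(images) {
  wrap <- function(x) {
    if (inherits(x, "calibrated_image")) return(list(ch1 = x))
    if (is.list(x) && length(x) &&
        all(vapply(x, inherits, TRUE, "calibrated_image"))) {
      if (is.null(names(x))) names(x) <- paste0("ch", seq_along(x))
      do.call(check_same_geometry, unname(x))
      return(x)
    }
    stop("each image must be a calibrated_image or a list of channel images")
  }
  if (inherits(images, "calibrated_image")) images <- list(images)
  if (!is.list(images)) stop("'images' must be an image or a list of images")
  if (is.null(names(images)) || any(!nzchar(names(images))))
    names(images) <- paste0("img", seq_along(images))
  lapply(images, wrap)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %g um from %d image(s), shuffle seed %d\n",
              nrow(x$manifest), x$patch_size,
              length(unique(x$manifest$image_id)), x$seed))
  invisible(x)
}

#' De-blind manual patch labels via the manifest
#'
#' Joins labels keyed by anonymous patch name back to their source image and
#' grid position. Unknown patch names and duplicate labels are errors.
#'
#' @param patchset A `patch_set` from [make_patches()].
#' @param labels A data frame (or CSV path) with columns `patch_name`,
#'   `morphology`, `turnover`. Morphology is one of straight, thick,
#'   thick_to_reticular, reticular, fingers, or unscorable; turnover one of
#'   high, intermediate, low, or unscored.
#' @return A data frame of de-blinded patch labels: `patch_name`,
#'   `image_id`, `row`, `col`, `morphology`, `turnover`.
#' @export
ingest_labels <- function(patchset, labels) {
  if (is.character(labels)) labels <- read_table(labels)
  if (!nrow(labels))
    return(data.frame(patch_name = character(0), image_id = character(0),
                      row = integer(0), col = integer(0),
                      morphology = character(0), turnover = character(0),
                      stringsAsFactors = FALSE))
  need <- c("patch_name", "morphology", "turnover")
  if (!all(need %in% names(labels)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(labels$patch_name, patchset$manifest$patch_name)
  if (length(unknown))
    stop("labels refer to unknown patch name(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  dup <- labels$patch_name[duplicated(labels$patch_name)]
  if (length(dup))
    stop("duplicate label for patch(es): ", paste(unique(dup), collapse = ", "))
  check_levels(labels$morphology, morphology_levels(), "morphology")
  check_levels(labels$turnover, turnover_levels(), "turnover")
  merged <- merge(patchset$manifest, labels, by = "patch_name")
  merged[order(merged$patch_name),
         c("patch_name", "image_id", "row", "col", "morphology", "turnover")]
}

morphology_levels <- function()
  c("straight", "thick", "thick_to_reticular", "reticular", "fingers",
    "unscorable")
turnover_levels <- function() c("high", "intermediate", "low", "unscored")

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop("invalid ", what, " label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")")
}

#' Cross-tabulate de-blinded patch labels
#'
#' Marginal counts and percentages per morphology and per turnover class,
#' the morphology x turnover table, and the percentage of high-turnover
#' patches within each morphology. Unscorable / unscored patches are
#' excluded from the respective denominators (and their number reported).
#' Morphologies with fewer than 5 scored patches are flagged as unreliable
#' for percentage readouts.
#'
#' @param labels De-blinded labels from [ingest_labels()] (or any data frame
#'   with `morphology` and `turnover` columns).
#' @return A `crosstab_report` list.
#' @export
crosstab_labels <- function(labels) {
  if (!nrow(labels)) stop("no scored patches")
  morph <- factor(labels$morphology, morphology_levels())
  turn <- factor(labels$turnover, turnover_levels())
  m_ok <- morph != "unscorable"
  t_ok <- turn != "unscored"
  m_counts <- table(droplevels2(morph[m_ok], "unscorable"))
  t_counts <- table(droplevels2(turn[t_ok], "unscored"))
  tab <- table(morphology = droplevels2(morph[m_ok & t_ok], "unscorable"),
               turnover = droplevels2(turn[m_ok & t_ok], "unscored"))
  pct_high <- if (nrow(tab) && sum(tab) > 0)
    100 * tab[, "high"] / pmax(rowSums(tab), 1) else numeric(0)
  pct_high[rowSums(tab) == 0] <- NA_real_
  structure(list(
    n_scored_morphology = sum(m_ok), n_scored_turnover = sum(t_ok),
    n_excluded_morphology = sum(!m_ok), n_excluded_turnover = sum(!t_ok),
    morphology_counts = m_counts,
    morphology_percent = 100 * prop.table(m_counts),
    turnover_counts = t_counts,
    turnover_percent = 100 * prop.table(t_counts),
    table = tab,
    percent_high_by_morphology = pct_high,
    unreliable_morphologies = names(m_counts)[m_counts < 5 & m_counts > 0]),
    class = "crosstab_report")
}

droplevels2 <- function(f, drop) factor(f, setdiff(levels(f), drop))

#' @export
print.crosstab_report <- function(x, ...) {
  cat("<crosstab_report>\n")
  cat(sprintf("  scored: %d (morphology), %d (turnover); excluded: %d / %d\n",
              x$n_scored_morphology, x$n_scored_turnover,
              x$n_excluded_morphology, x$n_excluded_turnover))
  if (sum(x$turnover_counts) > 0) {
    p <- x$turnover_percent
    cat("  turnover: ",
        paste(sprintf("%s %.0f%%", names(p), p), collapse = ", "), "\n")
  }
  if (length(x$unreliable_morphologies))
    cat("  note: <5 patches in: ",
        paste(x$unreliable_morphologies, collapse = ", "),
        " - percentages unreliable\n")
  invisible(x)
}

#' Quantitative turnover score of one patch (extension)
#'
#' An optional quantitative stand-in for the manual high/intermediate/low
#' turnover call on pulse-chase images: the mean retained (pulse) intensity
#' over junction pixels divided by the mean total surface intensity over the
#' same pixels. A high retained ratio means low turnover. This score and the
#' class thresholds in [classify_turnover()] are calibrated on synthetic
#' data only; they are an extension, not a replacement for manual scoring.
#'
#' @param pulse,surface [calibrated_image()] patches (same geometry).
#' @param junction_mask Optional [binary_mask()]; by default the junction is
#'   segmented by Otsu thresholding of the surface channel.
#' @return The retained ratio (numeric), or `NA` (unscorable) when the
#'   junction mask is empty.
#' @export
turnover_score <- function(pulse, surface, junction_mask = NULL) {
  check_same_geometry(pulse, surface, junction_mask)
  if (is.null(junction_mask)) {
    px <- surface$pixels
    rng <- range(px)
    if (diff(rng) == 0) return(NA_real_)
    norm <- (px - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm))
    junction_mask <- binary_mask(norm > thr, surface$pixel_size)
  }
  sel <- junction_mask$pixels
  if (!any(sel)) return(NA_real_)
  denom <- mean(surface$pixels[sel])
  if (denom <= 0) return(NA_real_)
  mean(pulse$pixels[sel]) / denom
}

#' Classify turnover scores into high / intermediate / low
#'
#' Thresholds the retained ratio from [turnover_score()]: scores below the
#' first threshold are high turnover, above the second low turnover. When no
#' thresholds are given they are fitted from the score distribution itself
#' by 1-D 3-means clustering (deterministic: centres initialized at the
#' 10/50/90% quantiles) and placed midway between adjacent cluster centres.
#'
#' @param scores Numeric retained ratios (`NA` = unscorable).
#' @param thresholds Optional increasing length-2 numeric vector.
#' @return Character vector over high/intermediate/low (`NA` preserved),
#'   with the thresholds used as attribute `thresholds`.
#' @export
classify_turnover <- function(scores, thresholds = NULL) {
  if (is.null(thresholds)) {
    ok <- stats::na.omit(scores)
    if (length(unique(ok)) < 3) stop("need at least 3 distinct scores to fit thresholds")
    centers <- sort(stats::kmeans(ok, centers = sort(stats::quantile(
      ok, c(0.1, 0.5, 0.9), names = FALSE)))$centers[, 1])
    thresholds <- c(mean(centers[1:2]), mean(centers[2:3]))
  }
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two increasing numbers")
  out <- ifelse(is.na(scores), NA_character_,
                ifelse(scores < thresholds[1], "high",
                       ifelse(scores < thresholds[2], "intermediate", "low")))
  attr(out, "thresholds") <- thresholds
  out
}
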