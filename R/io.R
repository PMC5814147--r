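#' Read a calibrated image from TIFF or PNG
#'
#' Reads a single-plane or multi-channel image and attaches the physical
#' pixel calibration. The calibration always comes from the caller (or a run
#' config), never from file metadata: TIFF resolution tags are written in too
#' many dialects to be trusted. If the file carries an interpretable
#' resolution tag that disagrees with `pixel_size` by more than 1%, a warning
#' is issued and `pixel_size` wins.
#'
#' Integer-valued TIFFs are returned with their stored integer counts
#' (no rescaling to \[0, 1\]); PNGs are returned on the 0..255 / 0..65535
#' integer scale of their bit depth.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size Pixel side length in µm.
#' @param channel_names Optional character vector of channel labels.
#' @return A list of [calibrated_image()] objects, one per channel, in file
#'   order (a single-channel file yields a list of length 1).
#' @export
read_image <- function(path, pixel_size, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  pixel_size <- check_pixel_size(pixel_size)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    check_tiff_resolution(planes[[1]], pixel_size, path)
    channels <- list()
    for (p in planes) {
      p <- unclass(p)
      attributes(p) <- attributes(p)["dim"]
      if (length(dim(p)) == 2L) channels <- c(channels, list(p))
      else if (length(dim(p)) == 3L)
        channels <- c(channels, lapply(seq_len(dim(p)[3]), function(k) p[, , k]))
      else stop("plane in ", path, " is not 2-D after channel split")
    }
  } else if (ext == "png") {
    p <- png::readPNG(path)
    depth <- attr(p, "bit.depth")
    scale <- if (is.null(depth)) 255 else 2^depth - 1
    p <- round(unclass(p) * scale)
    attributes(p) <- attributes(p)["dim"]
    if (length(dim(p)) == 2L) channels <- list(p)
    else channels <- lapply(seq_len(dim(p)[3]), function(k) p[, , k])
  } else stop("unsupported image format: .", ext)
  if (is.null(channel_names)) channel_names <- rep("", length(channels))
  channel_names <- rep_len(channel_names, length(channels))
  mapply(function(ch, nm) calibrated_image(ch, pixel_size, nm),
         channels, channel_names, SIMPLIFY = FALSE)
}

check_tiff_resolution <- function(plane, pixel_size, path) {
  xres <- attr(plane, "x.resolution")
  unit <- attr(plane, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(invisible())
  per_px <- switch(as.character(unit %||% ""),
                   "cm" = 1e4 / xres, "inch" = 25400 / xres, NULL)
  if (is.null(per_px)) return(invisible())
  if (abs(per_px - pixel_size) > 0.01 * pixel_size)
    warning(sprintf(
      "TIFF metadata of %s implies %.4g um/px but config says %.4g; using config",
      path, per_px, pixel_size))
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calibrated image as TIFF
#'
#' Integer data are stored losslessly at 8 or 16 bits so that
#' `read_image(write_image(x))` round-trips exactly; other data are stored
#' as 32-bit float.
#'
#' @param image A [calibrated_image()] or [binary_mask()].
#' @param path Output path (`.tif`).
#' @export
write_image <- function(image, path) {
  px <- as_pixel_matrix(image)
  if (is.logical(px)) px <- px * 1L
  if (all(px == round(px)) && min(px) >= 0 && max(px) < 2^16) {
    bits <- if (max(px) < 256) 8L else 16L
    tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(px, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Write a table of typed result records as CSV
#'
#' One record per row, header row, UTF-8, '.' decimal separator, full double
#' precision. An empty record set yields a header-only file when the column
#' schema is supplied via `template`.
#'
#' @param records A data frame of homogeneous result rows (nucleus records,
#'   loop records, curve bins, ...).
#' @param path Output path.
#' @param config Optional [run_config()]; when given, the parameters used are
#'   written next to the table (see [write_run_log()]) so runs are
#'   reproducible from their outputs.
#' @export
write_table <- function(records, path, config = NULL) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame of typed rows")
  utils::write.csv(format_full_precision(records), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8", na = "NA")
  if (!is.null(config)) write_run_log(config, paste0(path, ".run.yaml"))
  invisible(path)
}

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  df
}

#' Read back a table written by [write_table()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Run configuration
#'
#' A validated bag of run parameters: the physical calibration, the global
#' random seed, and per-module parameter blocks. Every tunable a pipeline
#' exposes can be carried here and is logged with the run outputs.
#'
#' @param pixel_size Pixel side length in µm.
#' @param random_seed Integer global seed.
#' @param out_dir Output directory.
#' @param ... Named per-module parameter blocks (lists), e.g.
#'   `coordination = list(bin_width = 25, max_distance = 1000)`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size = 1, random_seed = 1L, out_dir = ".", ...) {
  pixel_size <- check_pixel_size(pixel_size)
  random_seed <- as.integer(random_seed)
  blocks <- list(...)
  if (length(blocks) && (is.null(names(blocks)) || any(!nzchar(names(blocks)))))
    stop("module parameter blocks must be named")
  structure(c(list(pixel_size = pixel_size, random_seed = random_seed,
                   out_dir = out_dir), blocks),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml`/`.json` config file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write the run log: timestamp, seed and full parameter dump
#' @param config A [run_config()] (or any named list of parameters).
#' @param path Output path (`.yaml`).
#' @export
write_run_log <- function(config, path) {
  entry <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package_version = as.character(utils::packageVersion("vasquant")),
                parameters = unclass(config))
  yaml::write_yaml(entry, path)
  invisible(path)
}
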