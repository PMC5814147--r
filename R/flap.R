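#' Photoconversion (FLAP) time course
#'
#' The mean converted-channel intensity of a junctional ROI over time,
#' together with a per-frame background estimate from a non-photoconverted
#' region and the index of the first post-conversion frame. The default
#' acquisition is 15 min at 10 s resolution.
#'
#' @param times Acquisition times in seconds, strictly increasing, uniform
#'   spacing.
#' @param roi_intensity Mean ROI intensity per frame.
#' @param background_intensity Background estimate per frame (same length).
#' @param conversion_index Index (1-based) of the first post-conversion
#'   frame; at least one pre-conversion frame must precede it.
#' @param qc_pass Manual quality flag: junction did not substantially move
#'   or remodel during observation (upstream manual call, carried along).
#' @return An object of class `flap_trace` (a data frame with attributes
#'   `conversion_index` and `qc_pass`).
#' @export
flap_trace <- function(times, roi_intensity, background_intensity = NULL,
                       conversion_index, qc_pass = TRUE) {
  n <- length(times)
  if (is.null(background_intensity)) background_intensity <- numeric(n)
  if (length(roi_intensity) != n || length(background_intensity) != n)
    stop("times, ROI and background series must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  conversion_index <- as.integer(conversion_index)
  if (conversion_index < 2L || conversion_index > n)
    stop("conversion_index must leave at least one pre-conversion frame")
  structure(data.frame(time = times, roi = roi_intensity,
                       background = background_intensity),
            conversion_index = conversion_index, qc_pass = isTRUE(qc_pass),
            class = c("flap_trace", "data.frame"))
}

trace_attrs <- function(trace) {
  list(ci = attr(trace, "conversion_index"), qc = attr(trace, "qc_pass"))
}

rebuild_trace <- function(trace, roi) {
  flap_trace(trace$time, roi, trace$background,
             attr(trace, "conversion_index"), attr(trace, "qc_pass"))
}

#' Subtract the per-frame background from a FLAP trace
#'
#' Negative corrected values are allowed (noise); a warning is raised if the
#' post-conversion plateau region goes negative on average.
#'
#' @param trace A [flap_trace()].
#' @return A `flap_trace` with the background removed (background column 0).
#' @export
subtract_background <- function(trace) {
  corrected <- trace$roi - trace$background
  ci <- attr(trace, "conversion_index")
  tail_idx <- seq(max(ci, length(corrected) - 9L), length(corrected))
  if (mean(corrected[tail_idx]) < 0)
    warning("post-conversion plateau is negative after background subtraction")
  flap_trace(trace$time, corrected, numeric(length(corrected)),
             ci, attr(trace, "qc_pass"))
}

#' Fit a photobleaching model on a fixed-cell control trace
#'
#' Least-squares fit of `A * exp(-k_b * t)` to a background-subtracted
#' fixed-cell trace (all molecules immobile, so any decay of the converted
#' signal is bleaching). The fit uses the post-conversion frames — before
#' conversion the converted channel holds no signal — with `t` measured from
#' acquisition start, so the fitted model extrapolates over the whole
#' acquisition.
#'
#' @param control A background-subtracted [flap_trace()] from fixed cells.
#' @return A `bleach_model` list: `rate` (`k_b`, 1/s, >= 0), `amplitude`,
#'   `residual` (RMS of fit residuals).
#' @export
fit_bleach <- function(control) {
  ci <- attr(control, "conversion_index") %||% 1L
  idx <- ci:nrow(control)
  t <- control$time[idx] - control$time[1]
  y <- control$roi[idx]
  if (mean(y > 0) < 0.5)
    stop("control trace is dominated by non-positive intensities")
  pos <- y > 0
  start_fit <- stats::lm(log(y[pos]) ~ t[pos])
  k0 <- max(0, -unname(stats::coef(start_fit)[2]))
  a0 <- exp(unname(stats::coef(start_fit)[1]))
  rss0 <- sum((y - a0 * exp(-k0 * t))^2)
  if (rss0 <= 1e-20 * sum(y^2)) {
    A <- a0; k <- k0   # log-linear start is already exact (noiseless data)
  } else {
    fit <- try(suppressWarnings(
      stats::nls(y ~ A * exp(-k * t), start = list(A = a0, k = k0),
                 control = stats::nls.control(warnOnly = TRUE))), silent = TRUE)
    if (inherits(fit, "try-error")) {
      A <- a0; k <- k0
    } else {
      cf <- stats::coef(fit); A <- unname(cf["A"]); k <- unname(cf["k"])
    }
  }
  k <- max(k, 0)
  res <- sqrt(mean((y - A * exp(-k * t))^2))
  structure(list(rate = k, amplitude = A, residual = res),
            class = "bleach_model")
}

#' Correct a trace for photobleaching
#'
#' Divides each frame by `exp(-k_b * t)` with `t` measured from acquisition
#' start (the microscope bleaches from the first frame, including
#' pre-conversion frames).
#'
#' @param trace A [flap_trace()].
#' @param model A `bleach_model` from [fit_bleach()].
#' @return A corrected `flap_trace`.
#' @export
bleach_correct <- function(trace, model) {
  t <- trace$time - trace$time[1]
  rebuild_trace(trace, trace$roi / exp(-model$rate * t))
}

#' Normalize a FLAP trace between baseline and conversion peak
#'
#' Affine map sending the mean of the pre-conversion frames to 0 and the
#' intensity immediately after photoconversion to 1. By default "immediately
#' after" is the single first post-conversion frame; `peak_frames` averages
#' the first few instead.
#'
#' @param trace A background-subtracted, bleach-corrected [flap_trace()].
#' @param peak_frames Number of initial post-conversion frames averaged to
#'   define the conversion peak (default 1).
#' @return A normalized `flap_trace` (pre-conversion frames near 0, first
#'   post-conversion frame at 1).
#' @export
normalize_trace <- function(trace, peak_frames = 1L) {
  ci <- attr(trace, "conversion_index")
  base <- mean(trace$roi[seq_len(ci - 1L)])
  peak_idx <- ci:min(ci + peak_frames - 1L, nrow(trace))
  peak <- mean(trace$roi[peak_idx])
  if (peak <= base)
    stop("post-conversion peak does not exceed the pre-conversion baseline; ",
         "no photoconversion detected")
  rebuild_trace(trace, (trace$roi - base) / (peak - base))
}

#' Centered moving average of a trace
#'
#' Odd window; every output value is the mean of `window` consecutive
#' frames, centred where possible and shifted inward at the trace edges so
#' the window always lies inside the trace. Window 1 is the identity.
#'
#' @param x Numeric vector or [flap_trace()].
#' @param window Odd integer window length (frames).
#' @return Same type as `x`, smoothed.
#' @export
smooth_trace <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (inherits(x, "flap_trace")) return(rebuild_trace(x, smooth_trace(x$roi, window)))
  if (window == 1L) return(x)
  h <- window %/% 2L
  n <- length(x)
  if (window >= n) return(rep(mean(x), n))
  vapply(seq_len(n), function(i) {
    lo <- min(max(1L, i - h), n - window + 1L)
    mean(x[lo:(lo + window - 1L)])
  }, numeric(1))
}

#' Estimate immobile fraction and redistribution half-time
#'
#' Works on the post-conversion portion of a normalized trace, which decays
#' from 1 toward the immobile fraction as converted molecules exchange with
#' the unconverted pool. The immobile fraction is the mean of the final
#' plateau (last `plateau_fraction` of post-conversion frames, at least 5),
#' clamped to \[0, 1\]. The half-time is the time after conversion at which
#' the smoothed curve first drops below the midpoint of the mobile span,
#' `(1 + f) / 2`, with linear interpolation between frames — the standard
#' convention for recovery/loss half-times. If the curve never crosses the
#' midpoint the half-time is undefined (`NA`), never silently zero.
#'
#' @param trace A normalized [flap_trace()].
#' @param plateau_fraction Fraction of trailing post-conversion frames
#'   averaged for the plateau (default 0.1).
#' @param smoothing_window Odd moving-average window applied before the
#'   crossing search (default 5).
#' @return A `flap_estimate` list: `immobile_fraction`, `half_time` (s, or
#'   `NA`), `plateau_frames`, `smoothing_window`.
#' @export
flap_estimate <- function(trace, plateau_fraction = 0.1, smoothing_window = 5L) {
  ci <- attr(trace, "conversion_index")
  post <- trace$roi[ci:nrow(trace)]
  tpost <- trace$time[ci:nrow(trace)] - trace$time[ci]
  npost <- length(post)
  k <- max(5L, ceiling(plateau_fraction * npost))
  k <- min(k, npost)
  f <- clamp(mean(post[(npost - k + 1L):npost]), 0, 1)
  sm <- smooth_trace(post, smoothing_window)
  # warn when the window is too short to see the plateau
  mid <- (1 + f) / 2
  below <- which(sm < mid)
  if (!length(below)) {
    half <- NA_real_
  } else {
    i <- below[1]
    if (i == 1L) half <- 0
    else half <- tpost[i - 1] + (tpost[i] - tpost[i - 1]) *
        (sm[i - 1] - mid) / (sm[i - 1] - sm[i])
    if (is.finite(half) && tpost[npost] < 3 * half)
      warning("trace spans fewer than 3 estimated half-times; ",
              "plateau estimate may be biased")
  }
  structure(list(immobile_fraction = f, half_time = half,
                 plateau_frames = k, smoothing_window = as.integer(smoothing_window)),
            class = "flap_estimate")
}

#' @export
print.flap_estimate <- function(x, ...) {
  cat(sprintf("<flap_estimate> immobile fraction %.3f, half-time %s\n",
              x$immobile_fraction,
              if (is.na(x$half_time)) "undefined (no midpoint crossing)"
              else sprintf("%.1f s", x$half_time)))
  cat(sprintf("  plateau: last %d frames; smoothing window: %d frames\n",
              x$plateau_frames, x$smoothing_window))
  invisible(x)
}

#' Full FLAP pipeline: background, bleaching, normalization, estimation
#'
#' @param trace Experimental [flap_trace()].
#' @param control Fixed-cell [flap_trace()] with the same acquisition, used
#'   to fit the bleaching model.
#' @param plateau_fraction,smoothing_window Passed to [flap_estimate()].
#' @param peak_frames Passed to [normalize_trace()].
#' @return A `flap_estimate` with the fitted `bleach_model` attached as
#'   attribute `bleach_model`.
#' @export
flap_pipeline <- function(trace, control, plateau_fraction = 0.1,
                          smoothing_window = 5L, peak_frames = 1L) {
  model <- fit_bleach(subtract_background(control))
  corrected <- bleach_correct(subtract_background(trace), model)
  normalized <- normalize_trace(corrected, peak_frames)
  est <- flap_estimate(normalized, plateau_fraction, smoothing_window)
  attr(est, "bleach_model") <- model
  est
}
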