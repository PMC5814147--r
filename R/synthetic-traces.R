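#' Specification of a synthetic photoconversion trace
#'
#' The noiseless, bleach-free, background-free post-conversion signal obeys
#' `I(t) = f + (1 - f) * 2^(-t / t_half)` with `t = 0` at the first
#' post-conversion frame; pre-conversion frames sit at the background level.
#' The raw trace is `(background + amplitude * I(t)) * exp(-k_b * t_global)`
#' plus additive Gaussian noise, where `t_global` runs from acquisition
#' start (the microscope bleaches from the first frame, pre-conversion
#' included). Defaults follow a 15 min acquisition at 10 s resolution.
#'
#' @param immobile_fraction `f` in \[0, 1\].
#' @param half_time Redistribution half-time, s (> 0).
#' @param n_pre Pre-conversion frames (>= 1).
#' @param frame_interval Frame spacing, s (> 0).
#' @param duration Post-conversion observation span, s. Should cover several
#'   half-times for the plateau to be meaningful.
#' @param bleach_rate `k_b`, 1/s (>= 0).
#' @param background Background intensity level.
#' @param amplitude Post-conversion signal amplitude above background.
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param seed Integer seed.
#' @return A `flap_trace_spec` list.
#' @export
flap_trace_spec <- function(immobile_fraction = 0.3, half_time = 90,
                            n_pre = 6L, frame_interval = 10, duration = 900,
                            bleach_rate = 0, background = 10,
                            amplitude = 100, noise_sd = 0, seed = 1L) {
  stopifnot(immobile_fraction >= 0, immobile_fraction <= 1, half_time > 0,
            n_pre >= 1, bleach_rate >= 0, noise_sd >= 0)
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (duration < 3 * half_time)
    warning("duration under 3 half-times: plateau estimation will be biased")
  structure(list(immobile_fraction = immobile_fraction, half_time = half_time,
                 n_pre = as.integer(n_pre), frame_interval = frame_interval,
                 duration = duration, bleach_rate = bleach_rate,
                 background = background, amplitude = amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "flap_trace_spec")
}

#' Generate a synthetic FLAP trace and its fixed-cell control
#'
#' The control trace shares the acquisition and bleach rate but has
#' `I(t) == 1` after conversion (fixed cells: everything immobile), which is
#' exactly what the bleach model is fitted on. The per-frame background
#' series carries the same bleaching and independent noise.
#'
#' @param spec A [flap_trace_spec()].
#' @return List with `trace` and `control`, both [flap_trace()] objects, and
#'   `truth` (the spec's `immobile_fraction` and `half_time`).
#' @export
gen_flap_trace <- function(spec) {
  stopifnot(inherits(spec, "flap_trace_spec"))
  with_seed(spec$seed, function() {
    dt <- spec$frame_interval
    n_post <- as.integer(floor(spec$duration / dt)) + 1L
    n <- spec$n_pre + n_post
    t_global <- (seq_len(n) - 1) * dt
    ci <- spec$n_pre + 1L
    t_post <- t_global[ci:n] - t_global[ci]
    make <- function(I_post) {
      I_full <- c(rep(0, spec$n_pre), I_post)
      decay <- exp(-spec$bleach_rate * t_global)
      roi <- (spec$background + spec$amplitude * I_full) * decay +
        stats::rnorm(n, 0, spec$noise_sd)
      bg <- spec$background * decay + stats::rnorm(n, 0, spec$noise_sd)
      flap_trace(t_global, roi, bg, ci)
    }
    f <- spec$immobile_fraction
    list(trace = make(f + (1 - f) * 2^(-t_post / spec$half_time)),
         control = make(rep(1, n_post)),
         truth = list(immobile_fraction = f, half_time = spec$half_time))
  })
}
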