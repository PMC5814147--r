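# Synthetic image generators with known ground truth. Every generator is a
# pure function of its spec (including the seed): identical spec gives
# bit-identical output, and ground truth is always returned alongside the
# rendering so analyzer tests never run blind.

#' Specification of a synthetic nematic nucleus field
#'
#' Describes a DAPI-like monolayer: elliptical nuclei at random
#' non-overlapping positions whose long-axis orientations follow a spatially
#' correlated nematic director field.
#'
#' @param n_nuclei Number of nuclei.
#' @param field_size Field side length, µm (square field).
#' @param correlation_length Director correlation length xi, µm. `0` gives
#'   i.i.d. uniform orientations; `Inf` a single common orientation.
#' @param orientation_noise Per-nucleus jitter kappa: the standard deviation
#'   (radians) of wrapped-normal noise applied to the doubled angle
#'   (von-Mises-like; `0` means no jitter).
#' @param major_axis,minor_axis Full nucleus axes, µm (endothelial nuclei
#'   are about 14 x 7 µm).
#' @param pixel_size Rendering calibration, µm/px.
#' @param seed Integer seed.
#' @return A `nematic_field_spec` list.
#' @export
nematic_field_spec <- function(n_nuclei, field_size = 1000,
                               correlation_length = 100,
                               orientation_noise = 0.2,
                               major_axis = 14, minor_axis = 7,
                               pixel_size = 1, seed = 1L) {
  stopifnot(n_nuclei >= 0, field_size > 0, correlation_length >= 0,
            orientation_noise >= 0, major_axis >= minor_axis, minor_axis > 0)
  structure(list(n_nuclei = as.integer(n_nuclei), field_size = field_size,
                 correlation_length = correlation_length,
                 orientation_noise = orientation_noise,
                 major_axis = major_axis, minor_axis = minor_axis,
                 pixel_size = check_pixel_size(pixel_size),
                 seed = as.integer(seed)),
            class = "nematic_field_spec")
}

#' Generate a synthetic nematic monolayer
#'
#' Orientations come from a smooth nematic director: complex white noise of
#' the doubled angle is Gaussian-smoothed with kernel width xi and the
#' argument halved (smoothing the doubled-angle representation avoids the
#' pi-wraparound artifacts of smoothing angles directly). Per-nucleus
#' wrapped-normal jitter of sd kappa is then added on the doubled angle.
#' Nuclei are placed by rejection sampling with a minimum centre spacing of
#' one major axis, which guarantees non-overlap; rendering is binary filled
#' ellipses (no anti-aliasing, so segmentation tests are deterministic).
#'
#' @param spec A [nematic_field_spec()].
#' @param render If `FALSE`, skip rasterization (and the non-overlap
#'   constraint, which only matters for rendering): positions are plain
#'   i.i.d. uniform. Useful for large statistical runs on the records alone.
#' @return List with `records` (ground-truth nucleus records, same schema as
#'   [nucleus_records()]) and `image` (a [calibrated_image()], or `NULL` if
#'   `render = FALSE`).
#' @export
gen_nematic_field <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "nematic_field_spec"))
  with_seed(spec$seed, function() {
    n <- spec$n_nuclei
    W <- spec$field_size
    ps <- spec$pixel_size
    margin <- if (render) spec$major_axis / 2 else 0
    if (render && 2 * margin >= W) stop("field too small to hold a nucleus")
    pos <- sample_positions(n, W, margin,
                            min_spacing = if (render) spec$major_axis else 0)
    theta <- sample_director(pos, spec)
    records <- data.frame(
      id = seq_len(n), x = pos[, 1], y = pos[, 2], theta = theta,
      major_axis = rep(spec$major_axis, n), minor_axis = rep(spec$minor_axis, n),
      area = rep(pi * spec$major_axis * spec$minor_axis / 4, n),
      image_id = rep("synthetic", n), stringsAsFactors = FALSE)
    if (n == 0L) records <- empty_nucleus_records()
    image <- NULL
    if (render) {
      npx <- max(2L, as.integer(round(W / ps)))
      img <- matrix(0, npx, npx)
      for (k in seq_len(n))
        img <- fill_ellipse(img, pos[k, 1] / ps, pos[k, 2] / ps, theta[k],
                            spec$major_axis / 2 / ps, spec$minor_axis / 2 / ps)
      image <- calibrated_image(img, ps, "synthetic nuclei")
    }
    list(records = records, image = image)
  })
}

sample_positions <- function(n, W, margin, min_spacing) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo <- margin; hi <- W - margin
  if (min_spacing <= 0)
    return(cbind(stats::runif(n, lo, hi), stats::runif(n, lo, hi)))
  xs <- numeric(n); ys <- numeric(n)
  got <- 0L
  attempts <- 0L; max_attempts <- 200L * n
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("infeasible packing: placed %d of %d nuclei after %d attempts",
                   got, n, attempts - 1L))
    cx <- stats::runif(1, lo, hi); cy <- stats::runif(1, lo, hi)
    if (got == 0L ||
        min((xs[seq_len(got)] - cx)^2 + (ys[seq_len(got)] - cy)^2) >= min_spacing^2) {
      got <- got + 1L
      xs[got] <- cx; ys[got] <- cy
    }
  }
  cbind(xs, ys)
}

sample_director <- function(pos, spec) {
  n <- nrow(pos)
  if (n == 0L) return(numeric(0))
  xi <- spec$correlation_length
  if (xi == 0) {
    base <- stats::runif(n, 0, pi)
  } else if (is.infinite(xi)) {
    base <- rep(stats::runif(1, 0, pi), n)
  } else {
    ps <- spec$pixel_size
    npx <- max(8L, as.integer(round(spec$field_size / ps)))
    re <- matrix(stats::rnorm(npx * npx), npx, npx)
    im <- matrix(stats::rnorm(npx * npx), npx, npx)
    sig <- xi / ps
    re <- gauss_smooth_fft(re, sig)
    im <- gauss_smooth_fft(im, sig)
    r <- clamp(as.integer(round(pos[, 2] / ps)) + 1L, 1L, npx)
    c <- clamp(as.integer(round(pos[, 1] / ps)) + 1L, 1L, npx)
    base <- (atan2(im[cbind(r, c)], re[cbind(r, c)]) / 2) %% pi
  }
  if (spec$orientation_noise > 0)
    base <- (base + stats::rnorm(n, 0, spec$orientation_noise) / 2) %% pi
  base
}

# fill a binary ellipse (value 1) centred at 0-based pixel (cx, cy),
# semi-axes a >= b in px, major axis at angle theta to the x (column) axis
fill_ellipse <- function(img, cx, cy, theta, a, b) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cy - a) + 1L); r1 <- min(nr, ceiling(cy + a) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(nc, ceiling(cx + a) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  Y <- matrix(rows - 1, length(rows), length(cols)) - cy
  X <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE) - cx
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[rows, cols][inside] <- 1
  img
}

#' Specification of a synthetic vessel network
#'
#' A perturbed triangular-lattice Voronoi tessellation whose cell walls are
#' dilated to the vessel width: the bounded lacunae between vessels are the
#' loops of the plexus.
#'
#' @param n_loops Target number of interior loops.
#' @param mean_loop_area Mean Voronoi cell area, µm² (sets the lattice
#'   spacing).
#' @param perturbation Seed-point displacement as a fraction of the lattice
#'   spacing (0 = perfectly regular lattice).
#' @param vessel_width Vessel (wall) width, µm.
#' @param pixel_size Rendering calibration, µm/px.
#' @param seed Integer seed.
#' @return A `vessel_network_spec` list.
#' @export
vessel_network_spec <- function(n_loops = 50, mean_loop_area = 900,
                                perturbation = 0.2, vessel_width = 5,
                                pixel_size = 1, seed = 1L) {
  stopifnot(n_loops >= 1, mean_loop_area > 0, perturbation >= 0,
            vessel_width > 0)
  structure(list(n_loops = as.integer(n_loops),
                 mean_loop_area = mean_loop_area,
                 perturbation = perturbation, vessel_width = vessel_width,
                 pixel_size = check_pixel_size(pixel_size),
                 seed = as.integer(seed)),
            class = "vessel_network_spec")
}

#' Generate a synthetic vessel network mask with ground-truth loops
#'
#' Seeds are laid on a triangular lattice (whose Voronoi cells are regular
#' hexagons of `mean_loop_area`), each displaced uniformly within a disc of
#' radius `perturbation * spacing`. The discrete Voronoi boundary is dilated
#' to `vessel_width` with an exact Euclidean disc. Ground-truth loop records
#' are measured from the rendered mask itself with [extract_loops()] (no
#' size filter), so generator and analyzer share one geometric definition.
#'
#' @param spec A [vessel_network_spec()].
#' @return List with `mask` (a [binary_mask()]), `loops` (ground-truth loop
#'   records), and `n_loops_closed` — how many loops survived rendering
#'   (a vessel width so large that loops close entirely shows up here).
#' @export
gen_vessel_network <- function(spec) {
  stopifnot(inherits(spec, "vessel_network_spec"))
  with_seed(spec$seed, function() {
    s <- sqrt(2 * spec$mean_loop_area / sqrt(3))   # triangular lattice spacing
    dy <- s * sqrt(3) / 2
    side <- ceiling(sqrt(spec$n_loops))
    nx <- side + 3L; ny <- side + 3L   # frame of sacrificial border cells
    cx <- outer(rep(1, ny), seq_len(nx) - 1) * s
    cx <- cx + (seq_len(ny) %% 2) * (s / 2)        # offset alternate rows
    cy <- outer(seq_len(ny) - 1, rep(1, nx)) * dy
    if (spec$perturbation > 0) {
      ang <- stats::runif(nx * ny, 0, 2 * pi)
      rad <- spec$perturbation * s * sqrt(stats::runif(nx * ny))
      cx <- cx + rad * cos(ang); cy <- cy + rad * sin(ang)
    }
    ps <- spec$pixel_size
    W <- (nx - 1) * s; H <- (ny - 1) * dy
    ncp <- as.integer(round(W / ps)); nrp <- as.integer(round(H / ps))
    px <- (seq_len(ncp) - 1) * ps; py <- (seq_len(nrp) - 1) * ps
    # nearest-seed label per pixel, running minimum over seeds
    best <- matrix(Inf, nrp, ncp); lab <- matrix(0L, nrp, ncp)
    sx <- as.vector(cx); sy <- as.vector(cy)
    for (k in seq_along(sx)) {
      d2 <- outer((py - sy[k])^2, (px - sx[k])^2, "+")
      upd <- d2 < best
      best[upd] <- d2[upd]; lab[upd] <- k
    }
    boundary <- matrix(FALSE, nrp, ncp)
    boundary[, -ncp] <- boundary[, -ncp] | (lab[, -ncp] != lab[, -1])
    boundary[-nrp, ] <- boundary[-nrp, ] | (lab[-nrp, ] != lab[-1, ])
    dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image(!boundary))) * ps
    mask <- binary_mask(dmap <= spec$vessel_width / 2, ps)
    loops <- extract_loops(mask, min_loop_area = 0)
    list(mask = mask, loops = loops, n_loops_closed = nrow(loops))
  })
}

#' Specification of a synthetic front-decaying marker image
#'
#' Expected normalized intensity at distance `d` from the front is
#' `plateau + (amplitude - plateau) * exp(-d / decay_length)` inside the
#' vasculature, and 1 outside (all in fold-over-extravascular units).
#'
#' @param decay_length Exponential decay length lambda, µm.
#' @param amplitude Fold-over-background at the front.
#' @param plateau Fold-over-background far from the front.
#' @param extravascular_mean Mean raw intensity outside the vessels.
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param seed Integer seed.
#' @return A `gradient_spec` list.
#' @export
gradient_spec <- function(decay_length = 50, amplitude = 3, plateau = 1,
                          extravascular_mean = 100, noise_sd = 0, seed = 1L) {
  stopifnot(decay_length > 0, extravascular_mean > 0, noise_sd >= 0)
  structure(list(decay_length = decay_length, amplitude = amplitude,
                 plateau = plateau, extravascular_mean = extravascular_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gradient_spec")
}

#' Generate a marker image decaying with distance from the front
#'
#' @param spec A [gradient_spec()].
#' @param mask Vessel [binary_mask()].
#' @param front Front [binary_mask()] (same geometry, non-empty).
#' @return A [calibrated_image()].
#' @export
gen_front_gradient <- function(spec, mask, front) {
  stopifnot(inherits(spec, "gradient_spec"))
  check_same_geometry(mask, front)
  if (!any(front$pixels)) stop("front mask is empty")
  with_seed(spec$seed, function() {
    d <- distance_to_front(front)
    A <- spec$amplitude; B <- spec$plateau
    val <- matrix(spec$extravascular_mean, nrow(d), ncol(d))
    val[mask$pixels] <- spec$extravascular_mean *
      (B + (A - B) * exp(-d[mask$pixels] / spec$decay_length))
    if (spec$noise_sd > 0)
      val <- val + matrix(stats::rnorm(length(val), 0, spec$noise_sd),
                          nrow(val), ncol(val))
    calibrated_image(val, mask$pixel_size, "synthetic marker")
  })
}

#' Generate synthetic two-channel pulse-chase junction patches
#'
#' Each patch contains junction-like curvilinear structures. The surface
#' channel stains all junctions; the pulse channel retains a fraction of the
#' label that depends on the patch's turnover class, drawn from three
#' well-separated distributions: low turnover keeps a high retained ratio,
#' high turnover a low one.
#'
#' @param category_mix Named fractions over `c(high, intermediate, low)`
#'   turnover classes, summing to 1.
#' @param n_patches Number of patches.
#' @param seed Integer seed.
#' @param patch_size Patch side length, µm.
#' @param pixel_size µm/px.
#' @param ratio_means Mean retained ratio per class.
#' @param ratio_sd SD of the retained ratio within a class.
#' @param junction_intensity,background,noise_sd Intensity model parameters.
#' @param as_field If `TRUE`, additionally assemble the patches into square
#'   two-channel field images (requires `n_patches` to be a perfect square).
#' @return List with `patches` (each a list of `pulse` and `surface`
#'   [calibrated_image()]s), `labels` (ground-truth turnover class per
#'   patch), `ratios` (ground-truth retained ratio), and — when
#'   `as_field` — `field`, a list of `pulse`/`surface` full-field images
#'   tiled row-major from the patches.
#' @export
gen_pulse_chase_patches <- function(category_mix = c(high = 0.44,
                                                     intermediate = 0.24,
                                                     low = 0.32),
                                    n_patches = 100, seed = 1L,
                                    patch_size = 16, pixel_size = 0.25,
                                    ratio_means = c(high = 0.15,
                                                    intermediate = 0.5,
                                                    low = 0.85),
                                    ratio_sd = 0.03,
                                    junction_intensity = 100, background = 5,
                                    noise_sd = 2, as_field = FALSE) {
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0))
    stop("category_mix fractions must be non-negative and sum to 1")
  classes <- c("high", "intermediate", "low")
  if (!all(classes %in% names(category_mix)))
    stop("category_mix must be named with high/intermediate/low")
  with_seed(seed, function() {
    npx <- as.integer(round(patch_size / pixel_size))
    labels <- sample(classes, n_patches, replace = TRUE,
                     prob = category_mix[classes])
    ratios <- clamp(stats::rnorm(n_patches, ratio_means[labels], ratio_sd), 0, 1)
    patches <- vector("list", n_patches)
    for (k in seq_len(n_patches)) {
      jmask <- draw_junctions(npx, pixel_size)
      surface <- background + junction_intensity * jmask +
        matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx)
      pulse <- background + ratios[k] * junction_intensity * jmask +
        matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx)
      patches[[k]] <- list(
        pulse = calibrated_image(pulse, pixel_size, "pulse"),
        surface = calibrated_image(surface, pixel_size, "surface"))
    }
    out <- list(patches = patches, labels = labels, ratios = ratios)
    if (as_field) {
      side <- sqrt(n_patches)
      if (side != round(side))
        stop("as_field requires n_patches to be a perfect square")
      side <- as.integer(side)
      assemble <- function(ch) {
        big <- matrix(0, side * npx, side * npx)
        for (k in seq_len(n_patches)) {
          r <- (k - 1) %/% side; c <- (k - 1) %% side
          big[r * npx + seq_len(npx), c * npx + seq_len(npx)] <-
            patches[[k]][[ch]]$pixels
        }
        calibrated_image(big, pixel_size, ch)
      }
      out$field <- list(pulse = assemble("pulse"), surface = assemble("surface"))
    }
    out
  })
}

# random curvilinear junction structures across a patch: 1-2 quadratic
# Bezier chords, stroked to ~1.2 um width
draw_junctions <- function(npx, pixel_size) {
  pts <- matrix(FALSE, npx, npx)
  n_curves <- sample(1:2, 1)
  for (j in seq_len(n_curves)) {
    edge_pt <- function() {
      side <- sample(4, 1)
      u <- stats::runif(1, 0, npx - 1)
      switch(side, c(0, u), c(npx - 1, u), c(u, 0), c(u, npx - 1))
    }
    p0 <- edge_pt(); p2 <- edge_pt()
    p1 <- c(stats::runif(1, 0.25, 0.75) * npx, stats::runif(1, 0.25, 0.75) * npx)
    tt <- seq(0, 1, length.out = 4L * npx)
    bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    r <- clamp(as.integer(round(by)) + 1L, 1L, npx)
    c <- clamp(as.integer(round(bx)) + 1L, 1L, npx)
    pts[cbind(r, c)] <- TRUE
  }
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(!pts))) * pixel_size
  (d <= 0.6) * 1
}
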