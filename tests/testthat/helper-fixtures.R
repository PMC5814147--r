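# Fixtures built in code; no binary files.

# rasterize a filled ellipse independently of the package's renderer
# (centre cx, cy and semi-axes in 0-based pixel units, theta to the x axis)
raster_ellipse <- function(nr, nc, cx, cy, a, b, theta) {
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - cx
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc) - cy
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

# a rectangular vessel ring whose single lacuna is hole_px x hole_px pixels
ring_mask <- function(hole_px, wall_px = 3, pixel_size = 1) {
  n <- hole_px + 2 * wall_px + 4       # 2 px background frame at the border
  m <- matrix(FALSE, n, n)
  lo <- 3; hi <- 2 + 2 * wall_px + hole_px
  m[lo:hi, lo:hi] <- TRUE
  h0 <- lo + wall_px; h1 <- h0 + hole_px - 1
  m[h0:h1, h0:h1] <- FALSE
  binary_mask(m, pixel_size)
}

# mask with a disc-shaped lacuna of radius r_px
disc_hole_mask <- function(r_px, pixel_size = 1) {
  n <- 2 * r_px + 21
  cx <- (n - 1) / 2
  X <- matrix(rep(0:(n - 1), each = n), n, n) - cx
  Y <- matrix(rep(0:(n - 1), n), n, n) - cx
  vessel <- matrix(FALSE, n, n)
  vessel[3:(n - 2), 3:(n - 2)] <- TRUE
  vessel[X^2 + Y^2 <= r_px^2] <- FALSE
  binary_mask(vessel, pixel_size)
}

# uniform-random nucleus records (no rendering), i.i.d. uniform orientations
random_records <- function(n, field = 1000, seed = 1) {
  g <- gen_nematic_field(
    nematic_field_spec(n, field_size = field, correlation_length = 0,
                       orientation_noise = 0, seed = seed),
    render = FALSE)
  g$records
}
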