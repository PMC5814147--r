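# Internal geometry and RNG helpers shared across modules.

# Evaluate f() under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are pure functions of their spec.
with_seed <- function(seed, f) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  f()
}

# 4-connected labeling of a logical matrix by row-run union-find.
# EBImage::bwlabel is 8-connected; loop extraction needs the complementary
# 4-connectivity for background components.
label_4conn <- function(m) {
  stopifnot(is.logical(m))
  nr <- nrow(m); nc <- ncol(m)
  # runs of TRUE along each row
  runs <- vector("list", nr)
  nrun <- 0L
  for (r in seq_len(nr)) {
    v <- m[r, ]
    if (!any(v)) { runs[[r]] <- matrix(integer(0), 0, 3); next }
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    s <- starts[keep]; e <- ends[keep]
    id <- nrun + seq_along(s)
    nrun <- nrun + length(s)
    runs[[r]] <- cbind(s, e, id)
  }
  if (nrun == 0L) return(matrix(0L, nr, nc))
  parent <- seq_len(nrun)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (r in 2:nr) {
    a <- runs[[r - 1]]; b <- runs[[r]]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    ia <- 1L; ib <- 1L
    while (ia <= nrow(a) && ib <= nrow(b)) {
      # column overlap between run a[ia,] and b[ib,] means 4-adjacency
      if (a[ia, 1] <= b[ib, 2] && b[ib, 1] <= a[ia, 2]) union_(a[ia, 3], b[ib, 3])
      if (a[ia, 2] < b[ib, 2]) ia <- ia + 1L else ib <- ib + 1L
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  lab_of_root <- integer(nrun)
  uroots <- unique(root)
  lab_of_root[uroots] <- seq_along(uroots)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    b <- runs[[r]]
    if (nrow(b) == 0L) next
    for (k in seq_len(nrow(b))) out[r, b[k, 1]:b[k, 2]] <- lab_of_root[root[b[k, 3]]]
  }
  out
}

# Perimeter of each labeled object by corrected chain-code length
# (Vossepoel-Smeulders weights) on the traced outer contour. Returns a
# numeric vector indexed by label, in pixel units.
perimeter_chain <- function(labels) {
  labs <- sort(unique(labels[labels > 0L]))
  if (length(labs) == 0L) return(numeric(0))
  oc <- EBImage::ocontour(EBImage::Image(labels))
  out <- numeric(length(labs))
  for (k in seq_along(labs)) {
    pts <- oc[[labs[k]]]
    if (is.null(pts) || nrow(pts) < 2L) { out[k] <- 4; next } # single pixel
    st <- diff(rbind(pts, pts[1, , drop = FALSE]))
    l1 <- abs(st[, 1]) + abs(st[, 2])
    ne <- sum(l1 == 1); no <- sum(l1 == 2)
    dirs <- atan2(st[, 2], st[, 1])
    ncorner <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
    out[k] <- 0.980 * ne + 1.406 * no - 0.091 * ncorner
  }
  names(out) <- labs
  out
}

# Moment-equivalent ellipse of a pixel set given as (row, col) indices.
# Returns centroid (x, y in 0-based pixels), orientation in [0, pi) measured
# from the +x (column) axis, and full major/minor axis lengths in pixels.
ellipse_moments <- function(coords) {
  x <- coords[, 2] - 1
  y <- coords[, 1] - 1
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  mu20 <- sum((x - mx)^2) / n
  mu02 <- sum((y - my)^2) / n
  mu11 <- sum((x - mx) * (y - my)) / n
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  theta <- theta %% pi
  list(cx = mx, cy = my, theta = theta,
       major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 0)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian smoothing by multiplication in the Fourier domain (periodic
# boundary); unlike a spatial kernel it has no restriction that the kernel
# fit inside the image, so the correlation length may approach the field.
gauss_smooth_fft <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  H <- outer(exp(-2 * pi^2 * sigma^2 * fr^2), exp(-2 * pi^2 * sigma^2 * fc^2))
  Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (nr * nc)
}

# half-open distance binning: bin k covers [ (k-1)*w, k*w )
bin_index <- function(d, width, max_distance) {
  idx <- floor(d / width) + 1L
  idx[d >= max_distance | d < 0] <- NA_integer_
  idx
}

bin_edges <- function(width, max_distance) {
  lo <- seq(0, max_distance - width, by = width)
  cbind(lo = lo, hi = lo + width)
}
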