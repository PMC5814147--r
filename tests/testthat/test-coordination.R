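test_that("alignment score hits the anchor values and the nematic symmetries", {
  expect_identical(pair_alignment(0, 0), 1)
  expect_identical(pair_alignment(0, pi / 4), 0)
  expect_identical(pair_alignment(0, pi / 2), -1)
  expect_equal(pair_alignment(0, pi / 6), 0.5)   # 30 degrees

  set.seed(21)
  t1 <- runif(200, -2 * pi, 2 * pi); t2 <- runif(200, -2 * pi, 2 * pi)
  expect_equal(pair_alignment(t1, t2), pair_alignment(t2, t1))
  expect_equal(pair_alignment(t1 + pi, t2), pair_alignment(t1, t2))
  expect_equal(pair_alignment(t1, t2 + pi), pair_alignment(t1, t2))
  expect_equal(pair_alignment(t1, t1), rep(1, 200))
  expect_equal(pair_alignment(t1, t1 + pi / 2), rep(-1, 200))
})

test_that("moment ellipse orientation is exact on axis-aligned rectangles", {
  rect <- cbind(rep(1:6, 20), rep(1:20, each = 6))   # 20 px wide in x
  rec <- fit_ellipse(rect, pixel_size = 1)
  expect_equal(rec$theta, 0)
  rot <- rect[, 2:1]                                  # 20 px tall in y
  expect_equal(fit_ellipse(rot, 1)$theta, pi / 2)
  expect_error(fit_ellipse(rect[1:4, ], 1), "5 pixels")
})

test_that("render-and-refit recovers orientation and axes of a known ellipse", {
  ps <- 0.25
  img <- raster_ellipse(200, 200, 99.5, 99.5, (12 / 2) / ps, (5 / 2) / ps, 0.7)
  coords <- which(img > 0, arr.ind = TRUE)
  rec <- fit_ellipse(coords, ps)
  expect_lt(abs(rec$theta - 0.7), 0.05)
  expect_lt(abs(rec$major_axis - 12) / 12, 0.1)
  expect_lt(abs(rec$minor_axis - 5) / 5, 0.1)
})

test_that("segmentation recovers nearly all non-overlapping synthetic nuclei", {
  g <- gen_nematic_field(nematic_field_spec(200, field_size = 620,
                                            correlation_length = 80, seed = 9))
  labels <- segment_nuclei(g$image, min_area = 30, max_area = 200)
  recs <- nucleus_records(labels, g$image$pixel_size)
  expect_gte(nrow(recs), 190)
  # each segmented nucleus matches a distinct ground-truth centroid within 2 um
  d2 <- outer(recs$x, g$records$x, "-")^2 + outer(recs$y, g$records$y, "-")^2
  nearest <- apply(d2, 1, which.min)
  expect_lt(max(sqrt(d2[cbind(seq_len(nrow(recs)), nearest)])), 2)
  expect_equal(length(unique(nearest)), nrow(recs))
})

test_that("segmentation edge cases: blank image, border exclusion", {
  blank <- calibrated_image(matrix(0, 50, 50), 1)
  expect_warning(labs <- segment_nuclei(blank), "constant")
  expect_equal(max(labs), 0)

  img <- raster_ellipse(80, 80, 39, 39, 8, 4, 0.3) +
    raster_ellipse(80, 80, 2, 40, 8, 4, 1.2)        # second one cut by border
  labs <- segment_nuclei(calibrated_image(img, 1), min_area = 10, max_area = 500)
  expect_equal(max(labs), 1)
})

test_that("coordination curve: parallel cells score 1 in every occupied bin", {
  recs <- random_records(100, field = 500, seed = 3)
  recs$theta <- 1.1
  cv <- coordination_curve(recs, bin_width = 25, max_distance = 500)
  occ <- cv$pair_count > 0
  expect_true(any(occ))
  expect_equal(cv$mean_alignment[occ], rep(1, sum(occ)))
  expect_true(all(is.na(cv$mean_alignment[!occ])))
  expect_lte(sum(cv$pair_count), 100 * 99 / 2)
})

test_that("random orientations give near-zero mean alignment (null model)", {
  recs <- random_records(150, field = 400, seed = 5)     # ~11k pairs
  cv <- coordination_curve(recs, bin_width = 600, max_distance = 600)
  npairs <- sum(cv$pair_count)
  expect_gte(npairs, 1e4)
  # Var(cos 2*dtheta) = 1/2 under iid uniform orientations; 3 sigma bound
  global <- sum(cv$mean_alignment * cv$pair_count, na.rm = TRUE) / npairs
  expect_lt(abs(global), 3 / sqrt(2 * npairs))
})

test_that("curve is invariant under record order and respects pair rules", {
  recs <- random_records(60, field = 300, seed = 8)
  cv1 <- coordination_curve(recs, 25, 300)
  cv2 <- coordination_curve(recs[sample(nrow(recs)), ], 25, 300)
  # same pairs, summed in a different order: equal to summation roundoff
  expect_equal(cv1$mean_alignment, cv2$mean_alignment, tolerance = 1e-12)
  expect_identical(cv1$pair_count, cv2$pair_count)

  # a pair at exactly max_distance is excluded (half-open bins)
  two <- data.frame(id = 1:2, x = c(0, 100), y = c(0, 0), theta = c(0, 0),
                    major_axis = 14, minor_axis = 7, area = 77, image_id = "i")
  cv <- coordination_curve(two, 25, 100)
  expect_equal(sum(cv$pair_count), 0)

  expect_error(coordination_curve(recs[1, , drop = FALSE]), "at least 2")
  recs2 <- recs; recs2$image_id[1] <- "other"
  expect_error(coordination_curve(recs2), "cross images")
})

test_that("curve aggregation is pair-count weighted", {
  recs <- random_records(40, field = 300, seed = 2)
  cv <- coordination_curve(recs, 25, 300)
  agg1 <- aggregate_curves(list(cv))
  expect_equal(agg1$mean_alignment, cv$mean_alignment)
  expect_equal(agg1$pair_count, cv$pair_count)

  cva <- cv; cvb <- cv
  cvb$mean_alignment <- -cvb$mean_alignment
  opp <- aggregate_curves(list(cva, cvb))
  occ <- opp$pair_count > 0
  expect_equal(opp$mean_alignment[occ], rep(0, sum(occ)))

  # hand-computed weighted mean: counts (10, 30), values (1, 0) -> 0.25
  mk <- function(v, n) {
    df <- data.frame(bin_lo = 0, bin_hi = 25, mean_alignment = v,
                     pair_count = n)
    structure(df, n_nuclei = 10L, class = c("alignment_curve", "data.frame"))
  }
  expect_equal(aggregate_curves(list(mk(1, 10), mk(0, 30)))$mean_alignment, 0.25)
  expect_error(aggregate_curves(list(cv, mk(1, 10))), "mismatched")
})
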