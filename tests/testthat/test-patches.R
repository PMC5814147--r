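field_image <- function(side_um = 160, ps = 1, value = 0) {
  n <- round(side_um / ps)
  calibrated_image(matrix(value, n, n), ps)
}

test_that("a (160 um)^2 field tiles into exactly 100 patches of (16 um)^2", {
  pset <- make_patches(field_image(), patch_size = 16, seed = 1)
  expect_equal(nrow(pset$manifest), 100)
  expect_equal(length(pset$patches), 100)
  expect_true(all(vapply(pset$patches, function(p) all(dim(p$pixels) == 16), TRUE)))
})

test_that("the shuffle is reproducible from its seed and blind in the names", {
  a <- make_patches(field_image(), seed = 42)
  b <- make_patches(field_image(), seed = 42)
  expect_identical(a$manifest, b$manifest)
  c <- make_patches(field_image(), seed = 43)
  expect_false(identical(a$manifest$row, c$manifest$row))
  # anonymous names carry no positional information
  expect_true(all(grepl("^patch_[0-9]+$", a$manifest$patch_name)))
  expect_equal(anyDuplicated(a$manifest$patch_name), 0)
})

test_that("the blind/de-blind round trip is lossless across images", {
  # encode the source position in the pixel values, then recover it blind
  enc <- matrix(0, 160, 160)
  for (r in 1:10) for (c in 1:10)
    enc[(r - 1) * 16 + 1:16, (c - 1) * 16 + 1:16] <- r * 100 + c
  imgs <- list(one = calibrated_image(enc, 1),
               two = calibrated_image(enc + 1e4, 1))
  pset <- make_patches(imgs, patch_size = 16, seed = 7)
  expect_equal(nrow(pset$manifest), 200)
  for (k in sample(200, 25)) {
    m <- pset$manifest[k, ]
    val <- pset$patches[[m$patch_name]]$pixels[1, 1]
    expect_equal(val %% 1e4, m$row * 100 + m$col)
    expect_equal(val >= 1e4, m$image_id == "two")
  }
  # pixel conservation: every field pixel lands in exactly one patch
  tot <- sum(vapply(pset$patches, function(p) length(p$pixels), 0))
  expect_equal(tot, 2 * 160 * 160)
})

test_that("fields that are not patch multiples drop the remainder with a warning", {
  img <- calibrated_image(matrix(0, 170, 150), 1)
  expect_warning(pset <- make_patches(img, 16, seed = 1), "remainder")
  expect_equal(nrow(pset$manifest), 10 * 9)
  expect_error(make_patches(field_image(), patch_size = 300), "larger than")
})

test_that("label ingestion validates names and duplicates, then de-blinds", {
  pset <- make_patches(field_image(), seed = 5)
  empty <- ingest_labels(pset, data.frame(patch_name = character(0),
                                          morphology = character(0),
                                          turnover = character(0)))
  expect_equal(nrow(empty), 0)

  lab <- data.frame(patch_name = pset$manifest$patch_name[1:3],
                    morphology = c("straight", "reticular", "fingers"),
                    turnover = c("low", "high", "high"))
  out <- ingest_labels(pset, lab)
  expect_equal(nrow(out), 3)
  expect_true(all(c("image_id", "row", "col") %in% names(out)))

  bad <- lab; bad$patch_name[1] <- "patch_9999"
  expect_error(ingest_labels(pset, bad), "unknown patch name")
  dup <- rbind(lab, lab[1, ])
  expect_error(ingest_labels(pset, dup), "duplicate")
  wrong <- lab; wrong$morphology[1] <- "wavy"
  expect_error(ingest_labels(pset, wrong), "invalid morphology")
})

test_that("crosstab reproduces marginal percentages and is order-invariant", {
  pset <- make_patches(field_image(), seed = 2)
  nm <- pset$manifest$patch_name
  lab <- data.frame(
    patch_name = nm,
    morphology = rep(c("straight", "thick", "reticular"), length.out = 100),
    turnover = rep(c("high", "intermediate", "low"),
                   times = c(44, 24, 32)))
  out <- ingest_labels(pset, lab)
  rep1 <- crosstab_labels(out)
  expect_equal(as.numeric(rep1$turnover_percent), c(44, 24, 32))
  expect_equal(sum(rep1$turnover_percent), 100)
  rep2 <- crosstab_labels(out[rev(seq_len(nrow(out))), ])
  expect_identical(rep1$turnover_counts, rep2$turnover_counts)
  expect_identical(rep1$table, rep2$table)

  # one-category margin and the <5-patches reliability flag
  lab2 <- data.frame(patch_name = nm[1:10],
                     morphology = c(rep("straight", 7), rep("reticular", 3)),
                     turnover = rep("high", 10))
  rep3 <- crosstab_labels(ingest_labels(pset, lab2))
  expect_equal(as.numeric(rep3$turnover_percent), c(100, 0, 0))
  expect_true("reticular" %in% rep3$unreliable_morphologies)

  # unscorable patches leave the denominators
  lab3 <- data.frame(patch_name = nm[1:10],
                     morphology = c(rep("straight", 8), rep("unscorable", 2)),
                     turnover = c(rep("high", 5), rep("low", 3), rep("unscored", 2)))
  rep4 <- crosstab_labels(ingest_labels(pset, lab3))
  expect_equal(rep4$n_scored_morphology, 8)
  expect_equal(rep4$n_excluded_turnover, 2)
  expect_equal(as.numeric(rep4$turnover_percent), c(5, 0, 3) / 8 * 100)
})

test_that("turnover score: ratio identities and unscorable patches", {
  ps <- 0.25
  base <- matrix(10, 32, 32); base[10:20, ] <- 200
  surface <- calibrated_image(base, ps)
  mask <- binary_mask(base > 100, ps)
  expect_equal(turnover_score(surface, surface, mask), 1)
  zero <- calibrated_image(matrix(0, 32, 32), ps)
  expect_equal(turnover_score(zero, surface, mask), 0)
  none <- binary_mask(matrix(FALSE, 32, 32), ps)
  expect_true(is.na(turnover_score(surface, surface, none)))
})

test_that("scores on separated synthetic patches classify >= 95% correctly", {
  pc <- gen_pulse_chase_patches(n_patches = 120, seed = 8)
  scores <- vapply(pc$patches, function(p) turnover_score(p$pulse, p$surface), 0)
  pred <- classify_turnover(scores)
  expect_gte(mean(pred == pc$labels, na.rm = TRUE), 0.95)
})
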