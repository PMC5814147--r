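test_that("generators are pure functions of their spec (bit-identical reruns)", {
  s <- nematic_field_spec(30, field_size = 250, correlation_length = 40, seed = 5)
  a <- gen_nematic_field(s); b <- gen_nematic_field(s)
  expect_identical(a$records, b$records)
  expect_identical(a$image$pixels, b$image$pixels)

  fs <- flap_trace_spec(0.4, 70, noise_sd = 2, seed = 9)
  expect_identical(gen_flap_trace(fs)$trace$roi, gen_flap_trace(fs)$trace$roi)

  pc1 <- gen_pulse_chase_patches(n_patches = 10, seed = 3)
  pc2 <- gen_pulse_chase_patches(n_patches = 10, seed = 3)
  expect_identical(pc1$labels, pc2$labels)
  expect_identical(pc1$patches[[4]]$pulse$pixels, pc2$patches[[4]]$pulse$pixels)

  # and the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_nematic_field(s, render = FALSE))
  expect_identical(runif(1), before)
})

test_that("nematic field limits: infinite correlation, zero correlation, empty field", {
  all_same <- gen_nematic_field(
    nematic_field_spec(40, 300, correlation_length = Inf,
                       orientation_noise = 0, seed = 2), render = FALSE)
  expect_equal(diff(range(all_same$records$theta)), 0)

  iid <- gen_nematic_field(
    nematic_field_spec(1e4, 2000, correlation_length = 0,
                       orientation_noise = 0, seed = 4), render = FALSE)
  th <- iid$records$theta
  expect_true(all(th >= 0 & th < pi))
  # resultant length of doubled angles ~ 1/sqrt(n) under uniformity
  rbar <- Mod(mean(exp(2i * th)))
  expect_lt(rbar, 0.03)

  empty <- gen_nematic_field(nematic_field_spec(0, 100, seed = 1))
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$image$pixels), 0)
})

test_that("rendered nuclei are non-overlapping binary ellipses of the right size", {
  g <- gen_nematic_field(nematic_field_spec(60, 400, seed = 11))
  expect_true(all(g$image$pixels %in% c(0, 1)))
  dmin <- min(stats::dist(g$records[, c("x", "y")]))
  expect_gte(dmin, 14)       # centre spacing >= major axis, so no overlap
  # total rendered area matches n * pi * a * b / 4 within rasterization error
  expect_lt(abs(sum(g$image$pixels) - sum(g$records$area)) / sum(g$records$area),
            0.05)
  expect_error(gen_nematic_field(nematic_field_spec(200, 60, seed = 1)),
               "infeasible packing")
})

test_that("regular hexagonal lattice gives equal loops matching the analytic area", {
  spec <- vessel_network_spec(25, mean_loop_area = 900, perturbation = 0,
                              vessel_width = 5, seed = 1)
  net <- gen_vessel_network(spec)
  expect_gte(net$n_loops_closed, 25)
  a <- net$loops$area
  expect_lt(stats::sd(a) / mean(a), 0.02)            # rasterization only
  s <- sqrt(2 * 900 / sqrt(3))
  analytic <- 2 * sqrt(3) * (s / 2 - 5 / 2)^2        # hexagon inset by w/2
  expect_lt(abs(mean(a) - analytic) / analytic, 0.05)
})

test_that("flap generator obeys its closed form at key points", {
  flat <- gen_flap_trace(flap_trace_spec(1, 60, seed = 1))
  ci <- attr(flat$trace, "conversion_index")
  post <- flat$trace$roi[ci:nrow(flat$trace)]
  expect_equal(diff(range(post)), 0)        # f = 1, no bleach, no noise

  half <- gen_flap_trace(flap_trace_spec(0, 60, seed = 1))
  tr <- half$trace
  i60 <- which(tr$time - tr$time[ci] == 60 & seq_len(nrow(tr)) >= ci)
  background <- tr$roi[1]; peak <- tr$roi[ci]
  expect_equal(tr$roi[i60], (background + peak) / 2)

  expect_error(flap_trace_spec(0.3, 60, frame_interval = 0), "positive")
  expect_warning(flap_trace_spec(0.3, 400, duration = 900), "3 half-times")
})

test_that("front gradient limits: infinite decay length and flat contrast", {
  vessel <- binary_mask(rbind(matrix(TRUE, 20, 40), matrix(FALSE, 20, 40)), 1)
  front <- binary_mask(cbind(TRUE, matrix(FALSE, 40, 39)), 1)
  inf <- gen_front_gradient(
    gradient_spec(decay_length = Inf, amplitude = 3, plateau = 1,
                  extravascular_mean = 50), vessel, front)
  expect_equal(inf$pixels[vessel$pixels], rep(150, sum(vessel$pixels)))

  flat <- gen_front_gradient(
    gradient_spec(decay_length = 30, amplitude = 2, plateau = 2,
                  extravascular_mean = 50), vessel, front)
  expect_equal(flat$pixels[vessel$pixels], rep(100, sum(vessel$pixels)))

  empty_front <- binary_mask(matrix(FALSE, 40, 40), 1)
  expect_error(gen_front_gradient(gradient_spec(), vessel, empty_front), "empty")
})

test_that("pulse-chase patches: label mix, ratio separation, degenerate mixes", {
  pure <- gen_pulse_chase_patches(c(high = 1, intermediate = 0, low = 0),
                                  n_patches = 10, seed = 2)
  expect_true(all(pure$labels == "high"))

  mix <- c(high = 0.44, intermediate = 0.24, low = 0.32)
  pc <- gen_pulse_chase_patches(mix, n_patches = 400, seed = 6)
  prop <- table(factor(pc$labels, names(mix))) / 400
  expect_lt(max(abs(prop - mix)), 0.1)     # multinomial fluctuation bound

  means <- tapply(pc$ratios, pc$labels, mean)
  expect_true(means["high"] < means["intermediate"] &
              means["intermediate"] < means["low"])
  expect_error(gen_pulse_chase_patches(c(high = 0.6, intermediate = 0.6,
                                         low = -0.2), 10, 1), "sum to 1")
})
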