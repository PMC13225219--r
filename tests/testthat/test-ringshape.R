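# Ring segmentation, contour extraction, Fourier smoothing, circularity,
# trajectories and the trend model.

test_that("denoisers behave on their trivial fixtures", {
  img <- matrix(rnorm(256, 10, 1), 16, 16)
  expect_identical(denoise(img, "none"), img)
  const <- matrix(4, 16, 16)
  expect_equal(denoise(const, "gaussian", 1), const, tolerance = 1e-6)
  # median removes isolated impulses on the ring fixture
  s <- gen_ring_series(ring_series_spec(n_frames = 2, noise_sd = 0, seed = 80))
  fr <- get_plane(s$stack, t = 1)
  spiked <- fr
  idx <- cbind(sample(10:150, 25), sample(10:150, 25))
  spiked[idx] <- 1000
  cleaned <- denoise(spiked, "median", 2)
  expect_equal(sum(cleaned > 500), 0)
})

test_that("ring segmentation finds the band and flags blank frames", {
  s <- gen_ring_series(ring_series_spec(n_frames = 2, noise_sd = 0, seed = 81))
  fr <- get_plane(s$stack, t = 1)
  seg <- segment_ring(fr)
  expect_false(seg$failed)
  # mask matches the band region within a 1-px rim: all full-intensity band
  # pixels are in the mask, and the mask stays within the dilated band
  band_core <- fr > 0.9 * max(fr)
  expect_true(all(seg$mask[band_core]))
  blank <- segment_ring(matrix(5, 64, 64))
  expect_true(blank$failed)
  # threshold is invariant under an intensity offset (within one bin)
  seg2 <- segment_ring(fr + 50)
  expect_equal(sum(xor(seg$mask, seg2$mask)), 0)
})

test_that("inner-edge extraction recovers the hole radius and topology", {
  ann <- make_annulus(64, 12, 20)
  poly <- extract_inner_outline(ann)
  expect_identical(poly[1, ], poly[nrow(poly), ])  # closed
  c0 <- (64 + 1) / 2
  rad <- sqrt((poly[, 1] - c0)^2 + (poly[, 2] - c0)^2)
  expect_lt(abs(mean(rad) - 12), 0.5)
  # filled disc: no hole
  disc <- make_annulus(64, 0, 20)
  expect_error(extract_inner_outline(disc), "0 hole")
  # two holes
  two <- make_annulus(64, 8, 28)
  two[20, 20] <- FALSE
  expect_error(extract_inner_outline(two), "2 hole")
})

test_that("Fourier smoothing is a low-pass with exact identity limits", {
  th <- 2 * pi * (0:127) / 128
  circle <- cbind(x = 40 + 10 * cos(th), y = 40 + 10 * sin(th))
  sm <- fourier_smooth(circle, 8)
  expect_lt(max(abs(sm - circle)), 1e-6)
  expect_equal(fourier_smooth(circle, 100), circle, tolerance = 1e-9)
  # circle + high-frequency radial ripple: smoothing moves circularity to 1
  set.seed(82)
  rippled <- cbind(x = 40 + (10 + 0.6 * cos(20 * th)) * cos(th),
                   y = 40 + (10 + 0.6 * cos(20 * th)) * sin(th))
  c_raw <- measure_circularity(rippled)$circularity
  c_sm <- measure_circularity(fourier_smooth(rippled, 8))$circularity
  expect_gt(c_sm, c_raw)
  expect_gt(c_sm, 0.999)
  expect_error(fourier_smooth(circle[1:5, ]), "at least 8")
})

test_that("smoothing never lowers circularity on convex-plus-ripple shapes", {
  th <- 2 * pi * (0:127) / 128
  set.seed(83)
  for (i in 1:20) {
    base <- 8 + runif(1, 0, 4)
    k <- sample(15:40, 1)
    amp <- runif(1, 0.1, 0.5)
    p <- cbind(x = (base + amp * cos(k * th)) * cos(th),
               y = (base + amp * sin(k * th)) * sin(th))
    c_raw <- measure_circularity(p, check_simple = FALSE)$circularity
    c_sm <- measure_circularity(fourier_smooth(p, 8),
                                check_simple = FALSE)$circularity
    expect_gte(c_sm, c_raw - 1e-9)
  }
})

test_that("circularity matches closed forms and its invariances", {
  expect_equal(measure_circularity(regular_polygon(6))$circularity,
               sqrt(3) * pi / 6, tolerance = 1e-12)
  expect_equal(measure_circularity(regular_polygon(4))$circularity,
               pi / 4, tolerance = 1e-12)
  expect_equal(measure_circularity(regular_polygon(256))$circularity,
               1, tolerance = 1e-3)
  # scale and rotation invariance to 1e-10
  set.seed(84)
  p <- regular_polygon(7, radius = 3, center = c(5, -2))
  c0 <- measure_circularity(p)$circularity
  for (i in 1:5) {
    lam <- runif(1, 0.1, 20)
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    q <- lam * (p %*% R)
    expect_equal(measure_circularity(q)$circularity, c0, tolerance = 1e-10)
  }
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(measure_circularity(bowtie), "self-intersecting")
})

test_that("trajectories measure, order, and apply the exclusion rule", {
  series <- gen_ring_series(ring_series_spec(n_frames = 6, seed = 85))
  tr <- build_trajectory(series$stack, time_zero_frame = 2)
  expect_true(tr$included)
  expect_equal(tr$frames$time_min[2], 0)
  expect_true(all(diff(tr$frames$time_min) > 0))
  # constant-area series is excluded with a reason
  flat_spec <- ring_series_spec(n_frames = 5, area_contraction = 1,
                                circularity_profile = rep(0.95, 5), seed = 86)
  flat <- gen_ring_series(flat_spec)
  tr2 <- build_trajectory(flat$stack)
  expect_false(tr2$included)
  expect_equal(tr2$exclusion_reason, "no contraction")
  # a blank middle frame becomes a missing row without breaking order
  px <- series$stack$pixels
  px[3, 1, 1, , ] <- 0
  broken <- image_stack(px, time_interval_s = series$stack$time_interval_s)
  tr3 <- build_trajectory(broken)
  expect_true(is.na(tr3$frames$circularity[3]))
  expect_false(any(is.na(tr3$frames$circularity[c(2, 4)])))
  expect_equal(tr3$frames$frame, 1:6)
})

test_that("trend model recovers smooth structure and its limits", {
  set.seed(87)
  times <- seq(0, 45, by = 3)
  truth_fun <- function(t) 0.9 - 0.08 * exp(-t / 12)
  mk_data <- function(n_samples, offset_sd, noise_sd) {
    do.call(rbind, lapply(seq_len(n_samples), function(s) {
      data.frame(time = times,
                 circularity = truth_fun(times) + rnorm(1, 0, offset_sd) +
                   rnorm(length(times), 0, noise_sd),
                 sample = paste0("s", s), genotype = "wt")
    }))
  }
  # identical samples: random-intercept variance ~ 0 and flat residuals
  ident <- mk_data(4, 0, 0.001)
  fit0 <- fit_circularity_trend(ident)
  re_var <- mgcv::gam.vcomp(fit0$fits$wt)
  expect_lt(re_var["s(sample)", "std.dev"], 0.01)
  # trend-free data: fitted curve near-constant at the mean
  flat <- mk_data(5, 0.0, 0.02)
  flat$circularity <- 0.93 + rnorm(nrow(flat), 0, 0.02)
  fitf <- fit_circularity_trend(flat)
  expect_lt(diff(range(fitf$curves$fit)), 0.03)
  expect_lt(abs(mean(fitf$curves$fit) - 0.93), 0.02)
  # monotone truth gives a non-decreasing fitted trend within SE
  mono <- mk_data(8, 0.03, 0.01)
  fitm <- fit_circularity_trend(mono)
  wt <- fitm$curves
  expect_true(all(diff(wt$fit) > -2 * wt$se[-1]))
  expect_error(fit_circularity_trend(mk_data(2, 0, 0.01)), "3 samples")
})

test_that("trajectory lists feed the trend model", {
  trs <- lapply(1:3, function(i) {
    s <- gen_ring_series(ring_series_spec(n_frames = 8, seed = 90 + i))
    build_trajectory(s$stack, sample_id = paste0("s", i), genotype = "wt")
  })
  fit <- fit_circularity_trend(trs)
  expect_s3_class(fit, "trend_fit")
  expect_true(all(fit$curves$fit > 0.8 & fit$curves$fit < 1.05))
})
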