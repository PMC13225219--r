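# Synthetic-data generators: determinism, noise model, ground-truth records.

test_that("generators are pure functions of their spec", {
  spec <- coloc_field_spec(seed = 60)
  f1 <- gen_coloc_field(spec)
  f2 <- gen_coloc_field(spec)
  expect_identical(f1$channel_a$pixels, f2$channel_a$pixels)
  expect_identical(f1$channel_b$pixels, f2$channel_b$pixels)
  expect_identical(f1$truth$network, f2$truth$network)
  r1 <- gen_ring_series(ring_series_spec(n_frames = 3, seed = 61))
  r2 <- gen_ring_series(ring_series_spec(n_frames = 3, seed = 61))
  expect_identical(r1$stack$pixels, r2$stack$pixels)
  t1 <- gen_attachment_table(attachment_sim_spec(seed = 62))
  t2 <- gen_attachment_table(attachment_sim_spec(seed = 62))
  expect_identical(t1$length, t2$length)
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_coloc_field(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("control fields follow the stated noise model", {
  flat <- coloc_field_spec(background_sd = 0, n_spots = 0L, seed = 63)
  ctl <- gen_control_field(flat, "a")
  expect_equal(unique(as.vector(ctl$pixels)), flat$background_mean)
  # law of large numbers: empirical mean within 3 sd / sqrt(N)
  noisy <- coloc_field_spec(image_shape = c(128L, 128L), background_sd = 8,
                            n_spots = 0L, seed = 64)
  px <- as.vector(gen_control_field(noisy, "a")$pixels)
  expect_lt(abs(mean(px) - noisy$background_mean), 3 * 8 / sqrt(length(px)))
  # paired controls share spot coordinates (same spec, same scaffold)
  sp <- coloc_field_spec(background_sd = 0, seed = 65)
  ca <- get_plane(gen_control_field(sp, "a"))
  cb <- get_plane(gen_control_field(sp, "b"))
  expect_identical(which(ca > sp$background_mean + sp$spot_amplitude / 2),
                   which(cb > sp$background_mean + sp$spot_amplitude / 2))
})

test_that("perfect-colocalization limit yields tPCC ~ 1 through the pipeline", {
  spec <- coloc_field_spec(coloc_fraction = 1, independent_signal_level = 0,
                           background_sd = 0.25, seed = 66)
  out <- pipeline_coloc_once(spec)
  expect_gt(out$result$tpcc, 0.99)
  expect_gt(out$result$m1, 0.99)
})

test_that("ring series truth matches closed forms", {
  # single frame rendering a circle
  circ_spec <- ring_series_spec(n_frames = 2, n_sides = 256L, noise_sd = 0,
                                circularity_profile = c(1, 1), seed = 67)
  s <- gen_ring_series(circ_spec)
  expect_equal(s$truth$circularity[1], 1, tolerance = 1e-3)
  # regular hexagon: sqrt(3) * pi / 6
  hexv <- measure_circularity(regular_polygon(6))$circularity
  expect_equal(hexv, sqrt(3) * pi / 6)
  hex_spec <- ring_series_spec(n_frames = 2, noise_sd = 0,
                               circularity_profile = rep(hexv, 2), seed = 68)
  sh <- gen_ring_series(hex_spec)
  expect_equal(sh$truth$circularity[1], hexv, tolerance = 1e-9)
  expect_true(all(sh$truth$area > 0))
  # default profile is monotone non-decreasing and the area contracts
  sd_ <- gen_ring_series(ring_series_spec(seed = 69))
  expect_true(all(diff(sd_$truth$circularity) >= -1e-9))
  expect_lt(sd_$truth$area[15], 0.6 * sd_$truth$area[1])
})

test_that("attachment tables follow the gamma GLMM generative model", {
  # degenerate limit: no effects, no random variation, huge shape
  deg <- gen_attachment_table(attachment_sim_spec(
    beta_closed = 0, beta_ko = 0, delta = 0, intercept = 0,
    gamma_shape = 1e6, sd_sample = 0, sd_image = 0, seed = 70))
  expect_lt(max(abs(deg$length - 1)), 0.02)
  # moment check at n = 10^4 per genotype: mean ~ exp(beta + sd^2/2 terms)
  big <- attachment_sim_spec(n_flies_per_genotype = 50L, n_images_per_fly = 4L,
                             n_sites_per_image = 50L, seed = 71)
  tab <- gen_attachment_table(big)
  truth <- attr(tab, "truth")
  adj <- (big$sd_sample^2 + big$sd_image^2) / 2
  for (g in levels(tab$genotype)) {
    expected <- exp(big$intercept + truth$beta[[g]] + adj)
    got <- mean(tab$length[tab$genotype == g])
    expect_lt(abs(got - expected) / expected, 0.03)
  }
  # delta = 0: double-mutant mean consistent with additivity
  add <- gen_attachment_table(attachment_sim_spec(
    delta = 0, n_flies_per_genotype = 60L, n_images_per_fly = 3L,
    n_sites_per_image = 30L, seed = 72))
  gm <- function(g) mean(log(add$length[add$genotype == g]))
  expect_lt(abs((gm("double") - gm("wt")) -
                ((gm("closed") - gm("wt")) + (gm("ko") - gm("wt")))), 0.05)
})

test_that("intensity series expose the planted recruitment curve", {
  sim <- gen_intensity_series(noise_sd = 0, seed = 73)
  ci <- cortical_intensity(sim$signal[[1]], sim$control[[1]])
  curve_norm <- as.numeric(minmax_normalize(sim$truth$recruitment_curve))
  expect_equal(ci$values, curve_norm, tolerance = 1e-12)
  expect_true(all(ci$values >= 0 & ci$values <= 1))
  # peak time recovered within +-1 frame at moderate noise
  noisy <- gen_intensity_series(n_samples = 6L, noise_sd = 10, seed = 74)
  peak_truth <- which.max(noisy$truth$recruitment_curve)
  hits <- vapply(1:6, function(s) {
    ci_s <- cortical_intensity(noisy$signal[[s]], noisy$control[[s]])
    which.max(ci_s$values)
  }, numeric(1))
  expect_true(all(abs(hits - peak_truth) <= 1))
})
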