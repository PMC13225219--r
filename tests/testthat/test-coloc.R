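# Colocalization statistic stack.

test_that("compute_coloc reproduces the hand-worked 3x3 example", {
  a <- matrix(c(5, 0, 0, 0, 9, 0, 0, 0, 2), 3, byrow = TRUE)
  b <- matrix(c(7, 0, 0, 0, 0, 0, 0, 0, 4), 3, byrow = TRUE)
  r <- compute_coloc(channel_pair(a, b, t_a = 1, t_b = 1))
  expect_equal(r$m1, (5 + 2) / (5 + 9 + 2))  # 0.4375
  expect_equal(r$m2, 1.0)
  expect_equal(r$tpcc, 1.0)  # two joint pixels, perfectly collinear
  expect_equal(c(r$n_a, r$n_b, r$n_ab), c(3L, 2L, 2L))
})

test_that("identical channels give perfect colocalization; disjoint give zero", {
  set.seed(50)
  a <- matrix(runif(100, 0, 10), 10, 10)
  r <- compute_coloc(channel_pair(a, a, t_a = 4, t_b = 4))
  expect_equal(r$m1, 1); expect_equal(r$m2, 1); expect_equal(r$tpcc, 1)
  b <- matrix(0, 10, 10); b[a <= 4] <- 9
  r2 <- compute_coloc(channel_pair(a, b, t_a = 4, t_b = 4))
  expect_equal(r2$m1, 0); expect_equal(r2$m2, 0)
  expect_true(is.na(r2$tpcc))
  expect_true(r2$n_ab <= min(r2$n_a, r2$n_b))
})

test_that("statistics are invariant to rescaling a channel with its threshold", {
  set.seed(51)
  a <- matrix(rgamma(144, 2, 0.5), 12, 12)
  b <- 0.6 * a + matrix(rgamma(144, 2, 1), 12, 12)
  r <- compute_coloc(channel_pair(a, b, t_a = 3, t_b = 3))
  r2 <- compute_coloc(channel_pair(a * 7.5, b, t_a = 3 * 7.5, t_b = 3))
  expect_equal(r2$m1, r$m1)
  expect_equal(r2$m2, r$m2)
  expect_equal(r2$tpcc, r$tpcc)
  expect_equal(r2$n_ab, r$n_ab)
})

test_that("compute_coloc matches the brute-force oracle on random integer pairs", {
  set.seed(52)
  for (rep in 1:60) {
    a <- matrix(sample(0:4, 9, TRUE), 3, 3)
    b <- matrix(sample(0:4, 9, TRUE), 3, 3)
    ta <- runif(1, -0.5, 4); tb <- runif(1, -0.5, 4)
    roi <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 9, TRUE), 3, 3)
    if (!any(roi)) roi[1, 1] <- TRUE
    got <- compute_coloc(channel_pair(a, b, roi, t_a = ta, t_b = tb))
    want <- brute_coloc(a, b, roi, ta, tb)
    expect_identical(got$m1, want$m1)
    expect_identical(got$m2, want$m2)
    expect_equal(got$tpcc, want$tpcc, tolerance = 1e-12)
    expect_identical(c(got$n_a, got$n_b, got$n_ab),
                     c(want$n_a, want$n_b, want$n_ab))
  }
})

test_that("estimate_threshold pools control pixels with count weights", {
  expect_equal(estimate_threshold(list(matrix(10, 5, 5))), 10)
  two <- list(matrix(8, 10, 10), matrix(12, 10, 30))
  # hand-pooled: mean (100*8 + 300*12)/400 = 11; sd over the combined pixels
  pooled <- c(rep(8, 100), rep(12, 300))
  expect_equal(estimate_threshold(two), mean(pooled) + 3 * sd(pooled))
  # masked variant
  img <- matrix(c(5, 5, 100, 100), 2, 2)
  msk <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(estimate_threshold(list(list(image = img, mask = msk))), 5)
  expect_error(estimate_threshold(list(list(image = img,
                                            mask = matrix(FALSE, 2, 2)))),
               "degenerate")
})

test_that("randomize_channel permutes only the ROI and is seed-stable", {
  set.seed(53)
  img <- matrix(rnorm(400, 50, 10), 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[5:16, 5:16] <- TRUE
  p1 <- randomize_channel(img, roi, seed = 99)
  p2 <- randomize_channel(img, roi, seed = 99)
  expect_identical(p1, p2)
  expect_identical(sort(p1[roi]), sort(img[roi]))
  expect_identical(p1[!roi], img[!roi])
  expect_false(identical(p1[roi], img[roi]))
})

test_that("sample aggregation applies the statistic-specific pixel weights", {
  mk <- function(m1, m2, tpcc, n_a, n_b, n_ab) {
    structure(list(m1 = m1, m2 = m2, tpcc = tpcc,
                   n_a = n_a, n_b = n_b, n_ab = n_ab), class = "coloc_result")
  }
  one <- aggregate_sample(list(mk(0.7, 0.8, 0.3, 50, 60, 40)), "s1")
  expect_equal(one$m1_w, 0.7)
  expect_equal(one$tpcc_w, 0.3)
  two <- aggregate_sample(list(mk(0.8, 0.5, 0.2, 100, 10, 10),
                               mk(0.4, 0.5, 0.6, 300, 10, 30)))
  expect_equal(two$m1_w, (0.8 * 100 + 0.4 * 300) / 400)  # 0.5
  expect_equal(two$tpcc_w, (0.2 * 10 + 0.6 * 30) / 40)
  # equal weights reduce to the plain mean; weighted SD matches the formula
  eq <- aggregate_sample(list(mk(0.2, 0.2, 0.1, 50, 50, 50),
                              mk(0.6, 0.6, 0.5, 50, 50, 50)))
  expect_equal(eq$m1_w, 0.4)
  expect_equal(eq$sd_m1, sqrt(sum(50 * (c(0.2, 0.6) - 0.4)^2) / 99))
  # a missing statistic drops out with its weight
  with_na <- aggregate_sample(list(mk(0.8, NA, NA, 100, 0, 0),
                                   mk(0.4, 0.5, 0.2, 100, 20, 10)))
  expect_equal(with_na$m1_w, 0.6)
  expect_equal(with_na$m2_w, 0.5)
  expect_equal(with_na$tpcc_w, 0.2)
})

test_that("Fisher z transform round-trips and guards its domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z_inverse(fisher_z(0.73)), 0.73)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_true(is.finite(fisher_z(1 - 1e-6)))
})

test_that("population inference uses the z scale for tPCC", {
  mk <- function(m1, tpcc, id) structure(list(sample_id = id, m1_w = m1,
                                              m2_w = m1, tpcc_w = tpcc),
                                         class = "sample_summary")
  same <- lapply(1:4, function(i) mk(0.9, 0.4, i))
  pm <- population_inference(same, "m1")
  expect_equal(pm$mean, 0.9)
  expect_equal(pm$ci_low, pm$ci_high)
  expect_lt(pm$p, 1e-12)
  set.seed(54)
  summ <- lapply(1:9, function(i) mk(0.9, tanh(rnorm(1, atanh(0.6), 0.2)), i))
  pt_ <- population_inference(summ, "tpcc")
  expect_true(pt_$ci_low > -1 && pt_$ci_high < 1)
  # symmetric z-scale interval maps to an asymmetric r-scale interval
  expect_gt((pt_$mean - pt_$ci_low) - (pt_$ci_high - pt_$mean), 0)
  # sample means at r = 1 are clamped with a warning, not an error
  hot <- lapply(1:3, function(i) mk(1, 1, i))
  expect_warning(pi1 <- population_inference(hot, "tpcc"), "clamped")
  expect_lt(pi1$mean, 1)
  expect_error(population_inference(same[1], "m1"), "at least 2")
})
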