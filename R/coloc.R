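# Control-calibrated colocalization statistics: thresholded Manders M1/M2,
# thresholded Pearson correlation, pixel-randomization nulls, pixel-count
# weighted aggregation, and Fisher-z population inference.

#' Pair two registered channels with an ROI and thresholds
#'
#' @param a,b numeric `(y, x)` matrices of the two channels (same shape).
#' @param roi logical inclusion mask (default: all pixels).
#' @param t_a,t_b per-channel global intensity thresholds; pixels strictly
#'   above the threshold are "above" (ties excluded, matching ImageJ upper
#'   class thresholding).
#' @return A list of class `channel_pair`.
#' @export
channel_pair <- function(a, b, roi = NULL, t_a, t_b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  stopifnot(is.logical(roi), all(dim(roi) == dim(a)))
  stopifnot_scalar_num(t_a, "t_a")
  stopifnot_scalar_num(t_b, "t_b")
  structure(list(a = a, b = b, roi = roi, t_a = t_a, t_b = t_b),
            class = "channel_pair")
}

#' Per-image colocalization statistics
#'
#' Over the ROI pixels, with "above" meaning strictly above the channel's
#' global threshold:
#' * `m1` = sum of above-threshold channel-A intensities at pixels where B
#'   is also above, divided by the sum of all above-threshold A intensities;
#' * `m2` = the symmetric quantity for channel B;
#' * `tpcc` = Pearson correlation of the `(a, b)` intensities over the
#'   pixels above threshold in both channels.
#'
#' The informative pixel counts used later as aggregation weights are
#' returned alongside: `n_a` (A above), `n_b` (B above), `n_ab` (both
#' above). `m1`/`m2` are `NA` when their denominator count is zero; `tpcc`
#' is `NA` when fewer than 2 joint pixels remain or either channel has zero
#' variance on them.
#'
#' @param pair a [channel_pair()].
#' @return A list of class `coloc_result` with fields `m1`, `m2`, `tpcc`,
#'   `n_a`, `n_b`, `n_ab`.
#' @examples
#' a <- matrix(c(5, 0, 0, 0, 9, 0, 0, 0, 2), 3, byrow = TRUE)
#' b <- matrix(c(7, 0, 0, 0, 0, 0, 0, 0, 4), 3, byrow = TRUE)
#' compute_coloc(channel_pair(a, b, t_a = 1, t_b = 1))  # m1 = 7/16, m2 = 1
#' @export
compute_coloc <- function(pair) {
  stopifnot(inherits(pair, "channel_pair"))
  sel <- pair$roi
  if (!any(sel)) stop("ROI is empty")
  a <- pair$a[sel]
  b <- pair$b[sel]
  above_a <- a > pair$t_a
  above_b <- b > pair$t_b
  joint <- above_a & above_b
  n_a <- sum(above_a)
  n_b <- sum(above_b)
  n_ab <- sum(joint)
  m1 <- if (n_a > 0) sum(a[joint]) / sum(a[above_a]) else NA_real_
  m2 <- if (n_b > 0) sum(b[joint]) / sum(b[above_b]) else NA_real_
  tpcc <- NA_real_
  if (n_ab >= 2) {
    aj <- a[joint]; bj <- b[joint]
    if (var(aj) > 0 && var(bj) > 0) tpcc <- cor(aj, bj)
  }
  structure(list(m1 = m1, m2 = m2, tpcc = tpcc,
                 n_a = n_a, n_b = n_b, n_ab = n_ab),
            class = "coloc_result")
}

#' Estimate a global channel threshold from single-fluorophore controls
#'
#' Pools the masked pixels of all control images: the weighted mean (image
#' means weighted by masked pixel count, i.e. the pooled pixel mean) plus
#' `k_sd` pooled standard deviations. One threshold per channel per
#' experiment, applied to every image of that channel.
#'
#' @param control_images a list where each element is either a numeric
#'   matrix or a `list(image =, mask =)` pair with a logical mask.
#' @param k_sd number of standard deviations above the mean (default 3).
#' @return Threshold on the intensity scale.
#' @export
estimate_threshold <- function(control_images, k_sd = 3) {
  stopifnot(is.list(control_images), length(control_images) >= 1)
  px <- unlist(lapply(control_images, function(ci) {
    if (is.list(ci) && !is.null(ci$image)) {
      img <- ci$image
      msk <- ci$mask %||% array(TRUE, dim(img))
      as.numeric(img[as.logical(msk)])
    } else {
      as.numeric(ci)
    }
  }), use.names = FALSE)
  if (length(px) == 0) stop("degenerate input: all control masks are empty")
  mu <- mean(px)
  s <- if (length(px) > 1) sd(px) else 0
  mu + k_sd * s
}

#' Randomize a channel within the ROI
#'
#' Uniform random permutation of the pixel values inside the ROI; pixels
#' outside are unchanged and the multiset of ROI values is preserved. Used
#' to build the pixel-scrambling null for the colocalization statistics.
#'
#' @param image numeric `(y, x)` matrix.
#' @param roi logical mask.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @return Permuted matrix.
#' @export
randomize_channel <- function(image, roi = NULL, seed = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(is.logical(roi), all(dim(roi) == dim(image)))
  out <- image
  v <- image[roi]
  out[roi] <- with_local_seed(seed, sample(v))
  out
}

# Weighted mean and frequency-weighted SD (sum w (x - xbar)^2 / (sum w - 1)).
weighted_stats <- function(x, w) {
  keep <- !is.na(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, weight = 0))
  W <- sum(w)
  m <- sum(w * x) / W
  s <- if (W > 1) sqrt(sum(w * (x - m)^2) / (W - 1)) else NA_real_
  c(mean = m, sd = s, weight = W)
}

#' Aggregate per-image colocalization results to a sample summary
#'
#' Weighted means and standard deviations of M1, M2 and tPCC over the
#' images of one sample, with statistic-specific pixel-count weights: M1 by
#' the count of channel-A above-threshold pixels, M2 by the channel-B
#' count, tPCC by the count of pixels above threshold in both channels.
#' Missing per-image values are excluded together with their weights.
#'
#' @param results list of [compute_coloc()] results for one sample.
#' @param sample_id identifier carried into the summary.
#' @return A list of class `sample_summary`.
#' @export
aggregate_sample <- function(results, sample_id = NA) {
  stopifnot(is.list(results), length(results) >= 1,
            all(vapply(results, inherits, TRUE, "coloc_result")))
  g <- function(f) vapply(results, `[[`, numeric(1), f)
  s_m1 <- weighted_stats(g("m1"), g("n_a"))
  s_m2 <- weighted_stats(g("m2"), g("n_b"))
  s_tp <- weighted_stats(g("tpcc"), g("n_ab"))
  structure(list(sample_id = sample_id,
                 m1_w = s_m1[["mean"]], sd_m1 = s_m1[["sd"]], w_m1 = s_m1[["weight"]],
                 m2_w = s_m2[["mean"]], sd_m2 = s_m2[["sd"]], w_m2 = s_m2[["weight"]],
                 tpcc_w = s_tp[["mean"]], sd_tpcc = s_tp[["sd"]], w_tpcc = s_tp[["weight"]],
                 n_images = length(results)),
            class = "sample_summary")
}

#' Fisher z-transform and its inverse
#'
#' `fisher_z(r) = atanh(r)` maps correlations in (-1, 1) to the real line;
#' `fisher_z_inverse` is `tanh`. The forward transform requires `|r| < 1`.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @param z real value(s).
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("fisher_z requires |r| < 1; clamp upstream if sample means reach 1")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Population-level inference on sample summaries
#'
#' One-sample two-sided t-test against zero and a 95% t-interval over the
#' per-sample weighted means. For `m1`/`m2` the test and interval are on the
#' raw scale and the interval is left unclipped (it may exceed 1). For
#' `tpcc` the sample means are Fisher z-transformed first, the t machinery
#' runs on the z scale, and the point estimate and interval bounds are
#' back-transformed, so the interval stays inside (-1, 1). Sample means
#' with `|r| >= 1` (possible on synthetic data) are clamped to
#' `1 - 1e-6` with a warning.
#'
#' @param sample_summaries list of [aggregate_sample()] results.
#' @param statistic `"m1"`, `"m2"` or `"tpcc"`.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `population_inference` with `statistic`, `mean`,
#'   `ci_low`, `ci_high`, `p`, `n_samples`.
#' @export
population_inference <- function(sample_summaries, statistic = c("m1", "m2", "tpcc"),
                                 conf_level = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(sample_summaries))
  field <- switch(statistic, m1 = "m1_w", m2 = "m2_w", tpcc = "tpcc_w")
  x <- vapply(sample_summaries, `[[`, numeric(1), field)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("population inference needs at least 2 samples")
  transform <- statistic == "tpcc"
  if (transform) {
    hit <- abs(x) >= 1
    if (any(hit)) {
      warning("tPCC sample mean(s) at |r| >= 1 clamped to 1 - 1e-6 before Fisher z")
      x[hit] <- sign(x[hit]) * (1 - 1e-6)
    }
    x <- fisher_z(x)
  }
  m <- mean(x)
  se <- sd(x) / sqrt(n)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci <- c(m - tq * se, m + tq * se)
  p <- if (se > 0) 2 * pt(-abs(m / se), df = n - 1) else if (m == 0) 1 else 0
  if (transform) {
    m <- fisher_z_inverse(m)
    ci <- fisher_z_inverse(ci)
  }
  structure(list(statistic = statistic, mean = m,
                 ci_low = ci[1], ci_high = ci[2], p = p, n_samples = n),
            class = "population_inference")
}
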