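# Independent oracles: deliberately naive loop-based implementations used
# to cross-check the vectorized package code.

# Brute-force colocalization: explicit per-pixel loops over the defining
# sums; Pearson correlation from accumulated moments.
brute_coloc <- function(a, b, roi = NULL, t_a, t_b) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  num1 <- den1 <- num2 <- den2 <- 0
  n_a <- n_b <- n_ab <- 0L
  sx <- sy <- sxx <- syy <- sxy <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (!roi[i, j]) next
      av <- a[i, j]; bv <- b[i, j]
      aa <- av > t_a; bb <- bv > t_b
      if (aa) { n_a <- n_a + 1L; den1 <- den1 + av }
      if (bb) { n_b <- n_b + 1L; den2 <- den2 + bv }
      if (aa && bb) {
        n_ab <- n_ab + 1L
        num1 <- num1 + av; num2 <- num2 + bv
        sx <- sx + av; sy <- sy + bv
        sxx <- sxx + av * av; syy <- syy + bv * bv; sxy <- sxy + av * bv
      }
    }
  }
  m1 <- if (n_a > 0) num1 / den1 else NA_real_
  m2 <- if (n_b > 0) num2 / den2 else NA_real_
  tpcc <- NA_real_
  if (n_ab >= 2) {
    vx <- sxx - sx * sx / n_ab
    vy <- syy - sy * sy / n_ab
    if (vx > 0 && vy > 0) tpcc <- (sxy - sx * sy / n_ab) / sqrt(vx * vy)
  }
  list(m1 = m1, m2 = m2, tpcc = tpcc, n_a = n_a, n_b = n_b, n_ab = n_ab)
}

# Brute-force Otsu on a 256-bin histogram: evaluate the between-class
# variance at every candidate split and return all maximizing splits.
brute_otsu_bins <- function(h) {
  n <- length(h)
  p <- h / sum(h)
  mids <- seq_len(n) - 1
  bcv <- rep(NA_real_, n - 1)
  for (k in 1:(n - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):n] * mids[(k + 1):n]) / w1
    bcv[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  list(bcv = bcv, best = which(bcv >= max(bcv, na.rm = TRUE) - 1e-12) - 1L)
}

# Histogram of masked pixels, matching the package binning convention.
hist256 <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  bw <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / bw), n_bins - 1L)
  tabulate(idx + 1L, nbins = n_bins)
}

# Binary annulus mask on an H x H grid.
make_annulus <- function(H, r_in, r_out) {
  c0 <- (H + 1) / 2
  yy <- matrix(rep(seq_len(H), H), H, H)
  xx <- matrix(rep(seq_len(H), each = H), H, H)
  d <- sqrt((yy - c0)^2 + (xx - c0)^2)
  d >= r_in & d <= r_out
}

# Full end-to-end colocalization of one synthetic field: ROI macro +
# control thresholds + per-image statistics.
pipeline_coloc_once <- function(spec) {
  fl <- gen_coloc_field(spec)
  a <- get_plane(fl$channel_a)
  b <- get_plane(fl$channel_b)
  t_a <- estimate_threshold(list(get_plane(gen_control_field(spec, "a"))))
  t_b <- estimate_threshold(list(get_plane(gen_control_field(spec, "b"))))
  roi <- build_embryo_roi(a, spot_channels = list(a, b),
                          background_value = spec$background_mean)
  list(result = compute_coloc(channel_pair(a, b, roi$roi, t_a = t_a, t_b = t_b)),
       roi = roi, truth = fl$truth, t_a = t_a, t_b = t_b, a = a, b = b)
}
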