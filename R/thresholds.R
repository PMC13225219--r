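#' Histogram-based automatic thresholding
#'
#' Computes a global intensity threshold from a 256-bin histogram of the
#' (optionally masked) pixels, following the ImageJ AutoThreshold
#' conventions: the histogram is built on min-max rescaled intensities (as
#' ImageJ does for 16-bit data), the algorithm picks a split bin `k`
#' (foreground = bins above `k`), and the returned threshold is mapped back
#' to the intensity scale as the upper edge of bin `k`. Pixels strictly
#' above the returned value form the foreground class.
#'
#' Methods:
#' * `"otsu"` — maximizes the between-class variance (Otsu 1979).
#' * `"maxentropy"` — maximizes the sum of foreground and background
#'   Shannon entropies (Kapur, Sahoo & Wong 1985).
#' * `"huang"` — minimizes the fuzzy Shannon entropy of the induced
#'   membership function (Huang & Wang 1995).
#'
#' @param image numeric matrix (or vector) of intensities.
#' @param method `"otsu"`, `"maxentropy"` or `"huang"`.
#' @param mask optional logical matrix; only `TRUE` pixels enter the
#'   histogram.
#' @param n_bins number of histogram bins (default 256).
#' @return Threshold on the intensity scale (numeric scalar), with the
#'   chosen split bin in attribute `"bin"`.
#' @examples
#' x <- c(rep(10, 50), rep(200, 50))
#' auto_threshold(x, "otsu")   # between 10 and 200
#' @export
auto_threshold <- function(image, method = c("otsu", "maxentropy", "huang"),
                           mask = NULL, n_bins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(image)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(v))
    v <- v[as.logical(mask)]
  }
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 pixels to threshold")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate input: image is constant within the mask")
  bw <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / bw), n_bins - 1L)
  h <- tabulate(idx + 1L, nbins = n_bins)
  k <- switch(method,
    otsu = otsu_bin(h),
    maxentropy = kapur_bin(h),
    huang = huang_bin(h))
  t_val <- lo + (k + 1) * bw
  attr(t_val, "bin") <- k
  t_val
}

# Otsu: split bin k maximizing between-class variance, classes {<=k}, {>k}.
otsu_bin <- function(h) {
  n <- length(h)
  p <- h / sum(h)
  mids <- seq_len(n) - 1
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n]
  ks <- 1:(n - 1)
  w0k <- w0[ks]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, n - 1)
  bcv[valid] <- (mu_t * w0k[valid] - mu[ks][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  which.max(bcv) - 1L  # 0-based split bin
}

# Kapur maximum-entropy: maximize H_background(k) + H_foreground(k).
kapur_bin <- function(h) {
  n <- length(h)
  p <- h / sum(h)
  P <- cumsum(p)
  # entropy accumulators, skipping empty bins
  ent <- ifelse(p > 0, -p * log(p), 0)
  Hc <- cumsum(ent)
  Ht <- Hc[n]
  best <- -Inf
  best_k <- 0L
  for (k in 0:(n - 2)) {
    P1 <- P[k + 1]
    P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 0) next
    Hb <- Hc[k + 1] / P1 + log(P1)
    Hf <- (Ht - Hc[k + 1]) / P2 + log(P2)
    tot <- Hb + Hf
    if (tot > best) {
      best <- tot
      best_k <- k
    }
  }
  best_k
}

# Huang & Wang fuzzy thresholding: minimize the fuzzy entropy of the
# membership u(x) = 1 / (1 + |x - mu_class| / C).
huang_bin <- function(h) {
  n <- length(h)
  first <- which(h > 0)[1] - 1L
  last <- tail(which(h > 0), 1L) - 1L
  if (first == last) return(first)
  C <- last - first
  mids <- 0:(n - 1)
  W <- cumsum(h)
  S <- cumsum(h * mids)
  Wt <- W[n]; St <- S[n]
  best <- Inf
  best_k <- first
  for (k in first:(last - 1L)) {
    w0 <- W[k + 1]
    mu0 <- if (w0 > 0) S[k + 1] / w0 else 0
    w1 <- Wt - w0
    mu1 <- if (w1 > 0) (St - S[k + 1]) / w1 else 0
    mu_of <- ifelse(mids <= k, mu0, mu1)
    u <- 1 / (1 + abs(mids - mu_of) / C)
    hf <- -u * log(u) - (1 - u) * log(1 - u)
    hf[u >= 1 - 1e-12 | u <= 1e-12] <- 0
    ent <- sum(h * hf)
    if (ent < best) {
      best <- ent
      best_k <- k
    }
  }
  best_k
}
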