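# Actomyosin-ring morphometry: per-frame segmentation, sub-pixel inner-edge
# contours, Fourier-descriptor smoothing, circularity, trajectory assembly
# and the group trend model.

#' Classical denoising
#'
#' @param image numeric `(y, x)` matrix.
#' @param method `"none"`, `"gaussian"` or `"median"`.
#' @param strength Gaussian sigma, or median window radius in pixels.
#' @return Denoised matrix.
#' @export
denoise <- function(image, method = c("none", "gaussian", "median"), strength = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  switch(method,
    none = image,
    gaussian = EBImage::gblur(image, sigma = strength),
    median = {
      sc <- rescale01(image)
      if (sc$constant) image
      else EBImage::medianFilter(sc$x, size = max(1L, as.integer(strength))) *
        sc$scale + sc$lo
    })
}

#' Segment the ring band in one frame
#'
#' Huang-thresholds the (optionally denoised) frame and keeps the largest
#' connected above-threshold component.
#'
#' @param frame numeric `(y, x)` matrix containing one dominant bright ring.
#' @param denoise_method,denoise_strength passed to [denoise()].
#' @return Logical mask, or `NULL` with attribute-free `NA` handling: when
#'   no foreground component exists the function returns a structure with
#'   `failed = TRUE`.
#' @export
segment_ring <- function(frame, denoise_method = "none", denoise_strength = 1) {
  stopifnot(is.matrix(frame))
  f <- denoise(frame, denoise_method, denoise_strength)
  t_h <- tryCatch(auto_threshold(f, "huang"), error = function(e) NULL)
  if (is.null(t_h)) return(structure(list(mask = NULL, failed = TRUE), class = "ring_segmentation"))
  mask <- f > t_h
  if (!any(mask)) return(structure(list(mask = NULL, failed = TRUE), class = "ring_segmentation"))
  lab <- EBImage::bwlabel(mask * 1.0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  structure(list(mask = lab == keep, failed = FALSE, threshold = as.numeric(t_h)),
            class = "ring_segmentation")
}

#' Extract the sub-pixel inner-edge outline of an annular mask
#'
#' The mask must be topologically annular (exactly one hole). The binary
#' mask is lightly Gaussian-blurred and the 0.5 iso-level is traced with
#' marching squares (`contourLines`), giving a sub-pixel contour; the inner
#' edge is the traced contour that encloses the hole. The polygon is
#' returned counter-clockwise (in x right / y down image coordinates,
#' positive shoelace area) and closed (first vertex repeated at the end).
#'
#' @param mask logical `(y, x)` matrix.
#' @param smooth_sigma Gaussian sigma applied to the 0/1 mask before
#'   contouring (sub-pixel anti-aliasing; 0 disables).
#' @return Two-column matrix of `(x, y)` vertices, closed.
#' @export
extract_inner_outline <- function(mask, smooth_sigma = 0.5) {
  stopifnot(is.logical(mask), is.matrix(mask))
  inv <- !mask
  lab <- EBImage::bwlabel(inv * 1.0)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  hole_labels <- setdiff(unique(as.vector(lab)), c(0, border_labels))
  if (length(hole_labels) != 1L) {
    stop(sprintf("mask is not annular: found %d hole(s)", length(hole_labels)))
  }
  hole_px <- which(lab == hole_labels, arr.ind = TRUE)
  hole_centroid <- colMeans(hole_px)  # (row, col)
  z <- mask * 1.0
  if (smooth_sigma > 0) z <- EBImage::gblur(z, sigma = smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("no 0.5 iso-contour found")
  # pick the contour enclosing the hole centroid with the smallest area
  encl <- vapply(cl, function(cc) {
    point_in_polygon(hole_centroid[1], hole_centroid[2], cc$x, cc$y)
  }, logical(1))
  if (!any(encl)) stop("no contour encloses the hole; mask inner edge not traceable")
  areas <- vapply(cl, function(cc) abs(shoelace(cc$x, cc$y)), numeric(1))
  pick <- which(encl)[which.min(areas[encl])]
  # contourLines: $x follows rows (our y), $y follows columns (our x)
  poly <- cbind(x = cl[[pick]]$y, y = cl[[pick]]$x)
  poly <- ensure_ccw(poly)
  close_polygon(poly)
}

shoelace <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

point_in_polygon <- function(px, py, vx, vy) {
  # even-odd ray casting; polygon vertex lists follow contourLines order
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

ensure_ccw <- function(poly) {
  if (shoelace(poly[, 1], poly[, 2]) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

close_polygon <- function(poly) {
  n <- nrow(poly)
  if (poly[1, 1] != poly[n, 1] || poly[1, 2] != poly[n, 2]) {
    poly <- rbind(poly, poly[1, ])
  }
  poly
}

open_polygon <- function(poly) {
  n <- nrow(poly)
  if (n > 1 && poly[1, 1] == poly[n, 1] && poly[1, 2] == poly[n, 2]) {
    poly <- poly[-n, , drop = FALSE]
  }
  poly
}

#' Resample a closed polygon to equally spaced vertices
#'
#' Linear interpolation along arc length; used before Fourier smoothing so
#' that percentage-based descriptor truncation is well defined.
#'
#' @param polygon two-column vertex matrix (open or closed).
#' @param n number of output vertices (open form; default 128).
#' @return `n x 2` matrix of vertices (open form, not closed).
#' @export
resample_polygon <- function(polygon, n = 128L) {
  p <- open_polygon(as.matrix(polygon))
  pc <- rbind(p, p[1, ])
  seg <- sqrt(diff(pc[, 1])^2 + diff(pc[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(x = approx(s, pc[, 1], xout = target)$y,
        y = approx(s, pc[, 2], xout = target)$y)
}

#' Fourier-descriptor shape smoothing
#'
#' Treats the vertex sequence as complex numbers, takes the discrete
#' Fourier transform, retains the lowest `max(2, round(pct/100 * n))`
#' frequency pairs (a symmetric low-pass including the centroid term) and
#' inverse-transforms. Vertex count is preserved. With
#' `relative_descriptors_pct = 100` the polygon is returned unchanged.
#'
#' @param polygon two-column vertex matrix with at least 8 vertices (open
#'   or closed; a closed input returns a closed output).
#' @param relative_descriptors_pct percentage of descriptor pairs retained
#'   (default 8, the shape-smoothing plugin's relative mode).
#' @param n_descriptors absolute number of pairs to retain; overrides the
#'   percentage when given.
#' @return Smoothed polygon, same vertex count and closure as the input.
#' @export
fourier_smooth <- function(polygon, relative_descriptors_pct = 8,
                           n_descriptors = NULL) {
  closed <- {
    p <- as.matrix(polygon)
    nrow(p) > 1 && p[1, 1] == p[nrow(p), 1] && p[1, 2] == p[nrow(p), 2]
  }
  p <- open_polygon(as.matrix(polygon))
  n <- nrow(p)
  if (n < 8) stop("need at least 8 vertices")
  if (abs(shoelace(p[, 1], p[, 2])) < 1e-12) stop("degenerate polygon: zero area")
  m <- if (!is.null(n_descriptors)) as.integer(n_descriptors)
       else max(2L, as.integer(round(relative_descriptors_pct / 100 * n)))
  z <- complex(real = p[, 1], imaginary = p[, 2])
  F <- fft(z)
  keep <- rep(FALSE, n)
  keep[1] <- TRUE  # DC / centroid
  if (m >= 1) {
    ks <- seq_len(min(m, floor(n / 2)))
    keep[1 + ks] <- TRUE          # +k
    keep[n + 1 - ks] <- TRUE      # -k
  }
  F[!keep] <- 0
  zs <- fft(F, inverse = TRUE) / n
  out <- cbind(x = Re(zs), y = Im(zs))
  if (closed) close_polygon(out) else out
}

#' Polygon area, perimeter and circularity
#'
#' Area by the shoelace formula, perimeter by summed vertex distances
#' (including the closing edge), circularity by the ImageJ convention
#' `4 * pi * area / perimeter^2` (1 for a circle). Self-intersecting
#' polygons are rejected.
#'
#' @param polygon two-column vertex matrix (open or closed).
#' @param check_simple verify the polygon is simple (default TRUE).
#' @return A list with `area`, `perimeter`, `circularity`.
#' @examples
#' hexagon <- regular_polygon(6, radius = 10)
#' measure_circularity(hexagon)$circularity  # sqrt(3)*pi/6 = 0.9069
#' @export
measure_circularity <- function(polygon, check_simple = TRUE) {
  p <- open_polygon(as.matrix(polygon))
  n <- nrow(p)
  if (n < 3) stop("polygon needs at least 3 vertices")
  if (check_simple && self_intersects(p)) stop("polygon is self-intersecting")
  a <- abs(shoelace(p[, 1], p[, 2]))
  pc <- rbind(p, p[1, ])
  per <- sum(sqrt(diff(pc[, 1])^2 + diff(pc[, 2])^2))
  if (a <= 0 || per <= 0) stop("degenerate polygon")
  list(area = a, perimeter = per, circularity = 4 * pi * a / per^2)
}

# O(n^2) proper-crossing test between non-adjacent edges.
self_intersects <- function(p) {
  n <- nrow(p)
  x <- c(p[, 1], p[1, 1]); y <- c(p[, 2], p[1, 2])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n is adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(x[i], y[i], x[i + 1], y[i + 1], x[js], y[js])
    d2 <- cross(x[i], y[i], x[i + 1], y[i + 1], x[js + 1], y[js + 1])
    d3 <- numeric(length(js)); d4 <- numeric(length(js))
    for (k in seq_along(js)) {
      j <- js[k]
      d3[k] <- cross(x[j], y[j], x[j + 1], y[j + 1], x[i], y[i])
      d4[k] <- cross(x[j], y[j], x[j + 1], y[j + 1], x[i + 1], y[i + 1])
    }
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Vertices of a regular polygon
#'
#' @param n_sides number of sides.
#' @param radius circumradius.
#' @param center `(x, y)` center.
#' @param phase rotation in radians.
#' @return `n_sides x 2` vertex matrix (open form).
#' @export
regular_polygon <- function(n_sides, radius = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n_sides) - 1) / n_sides
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' Build a ring trajectory from a time-lapse stack
#'
#' Per frame: segment the ring (Huang threshold, largest component), trace
#' the sub-pixel inner-edge outline, resample to equally spaced vertices,
#' Fourier smooth, and measure area / perimeter / circularity. The
#' descriptor truncation is relative to the contour's own sampling density
#' (the smoothing plugin's "relative proportion" mode): by default the
#' resample count equals the traced contour's vertex count, so the retained
#' pair count is `round(pct/100 * n_contour)`. Fixing `n_vertices` (e.g. at
#' 128) is possible but biases sharp-cornered shapes: fewer retained
#' harmonics round their corners and inflate circularity. Frames whose
#' segmentation or contour extraction fails are recorded as missing without
#' breaking the time ordering. Time zero is the first frame after the 14th
#' nuclear division (`time_zero_frame`); earlier frames get negative times.
#' The exclusion rule flags trajectories whose final area has not dropped
#' below `(1 - min_contraction_frac)` times the initial area.
#'
#' @param stack an [image_stack()] (channel/slice 1 is used).
#' @param time_zero_frame 1-based frame index set to time 0.
#' @param sample_id,genotype identifiers carried into the result.
#' @param relative_descriptors_pct Fourier smoothing level (default 8).
#' @param n_vertices contour resampling count; `NULL` (default) matches the
#'   traced contour's own vertex count.
#' @param denoise_method,denoise_strength optional classical denoising.
#' @param min_contraction_frac minimum relative area loss required for
#'   inclusion (default 0.2).
#' @return A list of class `ring_trajectory` with a per-frame data.frame
#'   `frames` (`frame`, `time_min`, `area`, `perimeter`, `circularity`),
#'   `included` flag and `exclusion_reason`.
#' @export
build_trajectory <- function(stack, time_zero_frame = 1L, sample_id = NA,
                             genotype = NA, relative_descriptors_pct = 8,
                             n_vertices = NULL, denoise_method = "none",
                             denoise_strength = 1, min_contraction_frac = 0.2) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  nt <- d[1]
  interval_min <- stack$time_interval_s / 60
  rows <- vector("list", nt)
  outlines <- vector("list", nt)
  for (t in seq_len(nt)) {
    frame <- get_plane(stack, t = t)
    res <- tryCatch({
      seg <- segment_ring(frame, denoise_method, denoise_strength)
      if (seg$failed) stop("segmentation failed")
      poly <- extract_inner_outline(seg$mask)
      nv <- n_vertices %||% (nrow(poly) - 1L)
      poly <- resample_polygon(poly, nv)
      poly <- fourier_smooth(poly, relative_descriptors_pct)
      c(list(poly = poly), measure_circularity(poly))
    }, error = function(e) NULL)
    if (is.null(res)) {
      rows[[t]] <- data.frame(frame = t, time_min = (t - time_zero_frame) * interval_min,
                              area = NA_real_, perimeter = NA_real_,
                              circularity = NA_real_)
    } else {
      outlines[[t]] <- res$poly
      rows[[t]] <- data.frame(frame = t, time_min = (t - time_zero_frame) * interval_min,
                              area = res$area, perimeter = res$perimeter,
                              circularity = res$circularity)
    }
  }
  frames <- do.call(rbind, rows)
  ok <- which(!is.na(frames$area))
  included <- TRUE
  reason <- NA_character_
  if (!length(ok)) {
    included <- FALSE
    reason <- "no measurable frames"
  } else {
    a0 <- frames$area[ok[1]]
    a1 <- frames$area[ok[length(ok)]]
    if (a1 > (1 - min_contraction_frac) * a0) {
      included <- FALSE
      reason <- "no contraction"
    }
  }
  structure(list(sample_id = sample_id, genotype = genotype, frames = frames,
                 outlines = outlines, included = included,
                 exclusion_reason = reason),
            class = "ring_trajectory")
}

#' Fit the circularity-vs-time trend model
#'
#' Per genotype, a penalized cubic-spline smooth of circularity on time
#' plus a zero-mean random intercept per sample, fitted by REML
#' (`mgcv::gam` with `s(time, bs = "cr")` and `s(sample, bs = "re")`).
#' Returns the population-level fitted curve (random intercepts excluded)
#' and its pointwise standard error on a uniform time grid. With
#' `pre_average = TRUE` circularity is first averaged per time point and
#' the random intercept is dropped.
#'
#' @param data data.frame with columns `circularity`, `time`, `sample`,
#'   `genotype` (or a list of [build_trajectory()] results, from which the
#'   included trajectories' frames are pooled).
#' @param k spline basis dimension (default 10).
#' @param grid_n grid resolution (default 50).
#' @param pre_average average circularity per time point before fitting.
#' @return A list of class `trend_fit`: per-genotype data.frames with
#'   `time`, `fit`, `se`, plus the fitted `gam` objects.
#' @export
fit_circularity_trend <- function(data, k = 10, grid_n = 50, pre_average = FALSE) {
  if (is.list(data) && !is.data.frame(data) &&
      all(vapply(data, inherits, TRUE, "ring_trajectory"))) {
    data <- do.call(rbind, lapply(data, function(tr) {
      if (!tr$included) return(NULL)
      cbind(tr$frames, sample = tr$sample_id, genotype = tr$genotype)
    }))
    names(data)[names(data) == "time_min"] <- "time"
  }
  stopifnot(is.data.frame(data),
            all(c("circularity", "time", "sample", "genotype") %in% names(data)))
  data <- data[complete.cases(data[, c("circularity", "time", "sample")]), ]
  fits <- list()
  curves <- list()
  for (g in unique(data$genotype)) {
    dg <- data[data$genotype == g, ]
    dg$sample <- factor(dg$sample)
    if (length(unique(dg$sample)) < 3) stop("need at least 3 samples per genotype")
    if (length(unique(dg$time)) < 4) stop("need at least 4 time points")
    kk <- min(k, length(unique(dg$time)))
    if (pre_average) {
      agg <- stats::aggregate(circularity ~ time, dg, mean)
      fit <- mgcv::gam(circularity ~ s(time, bs = "cr", k = kk),
                       data = agg, method = "REML")
    } else {
      fit <- mgcv::gam(circularity ~ s(time, bs = "cr", k = kk) + s(sample, bs = "re"),
                       data = dg, method = "REML")
    }
    grid <- data.frame(time = seq(min(dg$time), max(dg$time), length.out = grid_n),
                       sample = dg$sample[1])
    pr <- predict(fit, newdata = grid, se.fit = TRUE,
                  exclude = if (!pre_average) "s(sample)" else NULL,
                  newdata.guaranteed = TRUE)
    curves[[as.character(g)]] <- data.frame(genotype = g, time = grid$time,
                                            fit = as.numeric(pr$fit),
                                            se = as.numeric(pr$se.fit))
    fits[[as.character(g)]] <- fit
  }
  structure(list(curves = do.call(rbind, curves), fits = fits),
            class = "trend_fit")
}
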