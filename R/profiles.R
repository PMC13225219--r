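# Intensity-course analyses: cortical recruitment curves, depth profiles
# aligned on the reference-channel peak, myotube displacement series, and
# local-regression fits.

#' Min-max normalize a series
#'
#' Maps to `[0, 1]`; a constant series returns all zeros with attribute
#' `"constant" = TRUE` (division by zero guarded).
#'
#' @param x numeric vector.
#' @return Normalized vector.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (hi <= lo) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (x - lo) / (hi - lo)
  attr(out, "constant") <- FALSE
  out
}

#' Cortical intensity time course
#'
#' Per time point, the mean intensity over `n_slices` z slices starting at
#' the embryo edge; the background (the matched control stack's mean over
#' the same slices) is subtracted per time point, and the series is min-max
#' normalized per sample.
#'
#' @param stack_series list of [image_stack()]s, one per time point.
#' @param control_series matched list of control stacks (same length).
#' @param n_slices number of slices from the edge (default 7).
#' @param edge_slice 1-based index of the first (edge) slice, or `"auto"`
#'   to take the first slice whose mean exceeds the control's mean + 3 sd.
#' @param times optional time axis (defaults to the index).
#' @param sample_id identifier.
#' @return A list of class `intensity_series` with `times`, `values`
#'   (normalized), `raw_values`, `background_values`, `constant` flag.
#' @export
cortical_intensity <- function(stack_series, control_series, n_slices = 7L,
                               edge_slice = 1L, times = NULL, sample_id = NA) {
  stopifnot(is.list(stack_series), is.list(control_series))
  if (length(stack_series) != length(control_series)) {
    stop("signal and control series must cover the same time points")
  }
  n_t <- length(stack_series)
  if (is.null(times)) times <- seq_len(n_t)
  band_mean <- function(stack, from, n) {
    d <- dim(stack$pixels)
    to <- min(d[2], from + n - 1L)
    mean(stack$pixels[, from:to, 1, , ])
  }
  raw <- numeric(n_t); bg <- numeric(n_t)
  for (t in seq_len(n_t)) {
    stk <- stack_series[[t]]
    ctl <- control_series[[t]]
    from <- if (identical(edge_slice, "auto")) {
      zmeans <- apply(stk$pixels[, , 1, , , drop = FALSE], 2, mean)
      cm <- mean(ctl$pixels); cs <- sd(as.numeric(ctl$pixels))
      hit <- which(zmeans > cm + 3 * cs)
      if (!length(hit)) 1L else hit[1]
    } else as.integer(edge_slice)
    raw[t] <- band_mean(stk, from, n_slices)
    bg[t] <- band_mean(ctl, from, n_slices)
  }
  corrected <- raw - bg
  values <- minmax_normalize(corrected)
  structure(list(sample_id = sample_id, times = times,
                 values = as.numeric(values), raw_values = raw,
                 background_values = bg,
                 constant = isTRUE(attr(values, "constant"))),
            class = "intensity_series")
}

#' Vertical (depth) intensity profile
#'
#' Mean intensity per z plane within an optional ROI; depth is the plane
#' index times the z step.
#'
#' @param stack an [image_stack()] (first time point used).
#' @param channel 1-based channel index.
#' @param roi optional logical `(y, x)` mask.
#' @return A list of class `depth_profile` with `depths_um`, `intensity`,
#'   `peak_depth_um`.
#' @export
depth_profile <- function(stack, channel = 1L, roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  prof <- vapply(seq_len(d[2]), function(z) {
    plane <- matrix(stack$pixels[1, z, channel, , ], d[4], d[5])
    if (is.null(roi)) mean(plane) else mean(plane[roi])
  }, numeric(1))
  depths <- (seq_len(d[2]) - 1) * stack$z_step_um
  structure(list(depths_um = depths, intensity = prof,
                 peak_depth_um = depths[which.max(prof)]),
            class = "depth_profile")
}

#' Align two-channel depth profiles on the reference channel's peak
#'
#' Each sample contributes a pair of profiles (same depth axis); all pairs
#' are shifted so the reference channel's interior intensity maximum sits
#' at depth 0, linearly interpolated onto a shared grid (step = the native
#' z step), and averaged across samples per depth.
#'
#' @param profile_pairs list of `list(reference =, other =)` pairs of
#'   [depth_profile()] objects.
#' @return A list of class `aligned_profiles`: `grid_um`, `reference_mean`,
#'   `other_mean`, `shifts_um`, and the per-sample aligned matrices.
#' @export
align_profiles <- function(profile_pairs) {
  stopifnot(is.list(profile_pairs), length(profile_pairs) >= 1)
  shifts <- numeric(length(profile_pairs))
  for (i in seq_along(profile_pairs)) {
    ref <- profile_pairs[[i]]$reference
    k <- which.max(ref$intensity)
    if (k == 1L || k == length(ref$intensity)) {
      stop(sprintf("sample %d: reference profile has no interior maximum", i))
    }
    shifts[i] <- ref$depths_um[k]
  }
  step <- min(vapply(profile_pairs, function(p) min(diff(p$reference$depths_um)),
                     numeric(1)))
  lo <- min(vapply(seq_along(profile_pairs), function(i) {
    min(profile_pairs[[i]]$reference$depths_um) - shifts[i]
  }, numeric(1)))
  hi <- max(vapply(seq_along(profile_pairs), function(i) {
    max(profile_pairs[[i]]$reference$depths_um) - shifts[i]
  }, numeric(1)))
  grid <- seq(lo, hi, by = step)
  interp <- function(prof, shift) {
    approx(prof$depths_um - shift, prof$intensity, xout = grid)$y
  }
  ref_mat <- t(vapply(seq_along(profile_pairs), function(i) {
    interp(profile_pairs[[i]]$reference, shifts[i])
  }, numeric(length(grid))))
  oth_mat <- t(vapply(seq_along(profile_pairs), function(i) {
    interp(profile_pairs[[i]]$other, shifts[i])
  }, numeric(length(grid))))
  structure(list(grid_um = grid,
                 reference_mean = colMeans(ref_mat, na.rm = TRUE),
                 other_mean = colMeans(oth_mat, na.rm = TRUE),
                 shifts_um = shifts,
                 reference_aligned = ref_mat, other_aligned = oth_mat),
            class = "aligned_profiles")
}

#' Myotube displacement and normalized intensity series
#'
#' Displacement is the tendon-myotube junction x coordinate minus its value
#' at the first time point; the fluorophore intensity is background
#' corrected with the per-time-point control mean and min-max normalized.
#'
#' @param times time axis (e.g. hours after pupal formation).
#' @param junction_x junction x coordinate per time point.
#' @param intensity_means mean fluorophore intensity per time point.
#' @param control_means matched control means per time point.
#' @param sample_id identifier.
#' @return A list of class `displacement_series` with `times`,
#'   `displacement`, `intensity` (normalized).
#' @export
displacement_series <- function(times, junction_x, intensity_means,
                                control_means, sample_id = NA) {
  n <- length(times)
  stopifnot(length(junction_x) == n, length(intensity_means) == n,
            length(control_means) == n)
  corrected <- intensity_means - control_means
  structure(list(sample_id = sample_id, times = times,
                 displacement = junction_x - junction_x[1],
                 intensity = as.numeric(minmax_normalize(corrected))),
            class = "displacement_series")
}

#' Align displacement series across samples
#'
#' Shifts each sample's time axis so the minimum junction displacement
#' (maximal compaction) coincides, then sets the first time point to a
#' common origin (default 24 h APF).
#'
#' @param series_list list of [displacement_series()] objects.
#' @param origin time value assigned to the earliest aligned time point.
#' @return The input list with adjusted `times`, plus attribute
#'   `"time_shifts"`.
#' @export
align_displacement_series <- function(series_list, origin = 24) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  tmin <- vapply(series_list, function(s) s$times[which.min(s$displacement)],
                 numeric(1))
  shifts <- tmin - tmin[1]
  out <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    s$times <- s$times - shifts[i]
    s
  })
  start <- min(vapply(out, function(s) min(s$times), numeric(1)))
  out <- lapply(out, function(s) { s$times <- s$times - start + origin; s })
  attr(out, "time_shifts") <- shifts
  out
}

#' Local (tricube-weighted polynomial) regression on a grid
#'
#' Classical LOESS via `stats::loess`, evaluated on a uniform grid.
#'
#' @param x,y data.
#' @param span smoothing span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param grid_n grid resolution (default 100).
#' @return data.frame with columns `x`, `fit`.
#' @export
local_regression <- function(x, y, span = 0.75, degree = 2, grid_n = 100L) {
  stopifnot(length(x) == length(y), length(x) >= degree + 2)
  fit <- loess(y ~ x, span = span, degree = degree,
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = grid_n)
  data.frame(x = grid, fit = as.numeric(predict(fit, newdata = data.frame(x = grid))))
}
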