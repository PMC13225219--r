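#' Construct an image stack
#'
#' The common container for all image data in the package: a 5-dimensional
#' non-negative intensity array indexed `(t, z, c, y, x)` together with
#' physical voxel metadata. A plain 2-D image is a stack with singleton
#' time, slice and channel axes. Axis order is canonical throughout the
#' package: time, z-slice, channel, image row (y, increasing downward),
#' image column (x).
#'
#' @param pixels numeric array with 2 to 5 dimensions. Dimensions are
#'   right-aligned onto `(t, z, c, y, x)`: a 2-D input is taken as
#'   `(y, x)`, a 3-D input as `(c, y, x)`, and so on.
#' @param pixel_size_um physical pixel size `(dy, dx)` in micrometres.
#' @param z_step_um slice spacing in micrometres.
#' @param time_interval_s frame interval in seconds.
#' @param channel_names optional character vector of channel labels.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(matrix(runif(64), 8, 8))
#' dim(s$pixels)  # 1 1 1 8 8
#' @export
image_stack <- function(pixels, pixel_size_um = c(1, 1), z_step_um = 1,
                        time_interval_s = 1, channel_names = NULL) {
  if (!is.numeric(pixels)) stop("`pixels` must be numeric")
  d <- dim(pixels) %||% length(pixels)
  if (length(d) < 2L || length(d) > 5L) {
    stop("`pixels` must have 2 to 5 dimensions")
  }
  dim(pixels) <- c(rep(1L, 5L - length(d)), d)
  if (any(!is.finite(pixels))) stop("all intensities must be finite")
  if (any(pixels < 0)) stop("negative intensities are not allowed")
  if (length(pixel_size_um) == 1L) pixel_size_um <- rep(pixel_size_um, 2L)
  if (any(pixel_size_um <= 0) || z_step_um <= 0 || time_interval_s <= 0) {
    stop("physical metadata (pixel size, z step, time interval) must be > 0")
  }
  nc <- dim(pixels)[3L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("`channel_names` length must match the channel axis")
  }
  structure(
    list(pixels = pixels,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um),
         time_interval_s = as.numeric(time_interval_s),
         channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_stack> t=%d z=%d c=%d y=%d x=%d | px %.3gx%.3g um, dz %.3g um, dt %.3g s\n",
    d[1], d[2], d[3], d[4], d[5],
    x$pixel_size_um[1], x$pixel_size_um[2], x$z_step_um, x$time_interval_s))
  invisible(x)
}

#' Extract a single 2-D plane from a stack
#'
#' @param stack an [image_stack()].
#' @param t,z,c 1-based indices on the time, slice and channel axes.
#' @return A numeric `(y, x)` matrix.
#' @export
get_plane <- function(stack, t = 1L, z = 1L, c = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (t < 1 || t > d[1] || z < 1 || z > d[2] || c < 1 || c > d[3]) {
    stop("plane index out of range")
  }
  matrix(stack$pixels[t, z, c, , ], d[4], d[5])
}

#' Project a stack along the z or t axis
#'
#' Collapses an inclusive index range of the chosen axis into a singleton by
#' the per-pixel sum, mean or maximum, as used for cortical XY projections
#' (e.g. the mean of several slices from the embryo edge, or the sum of
#' three slices around the actomyosin ring).
#'
#' @param stack an [image_stack()].
#' @param method one of `"sum"`, `"mean"`, `"max"`.
#' @param axis `"z"` or `"t"`.
#' @param index_range inclusive 1-based `(from, to)` bounds on the axis;
#'   default spans the whole axis.
#' @return An [image_stack()] whose projected axis is a singleton.
#' @export
project <- function(stack, method = c("sum", "mean", "max"), axis = c("z", "t"),
                    index_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  axis <- match.arg(axis)
  ax <- if (axis == "t") 1L else 2L
  d <- dim(stack$pixels)
  if (is.null(index_range)) index_range <- c(1L, d[ax])
  from <- as.integer(index_range[1]); to <- as.integer(index_range[2])
  if (from > to) stop("empty index range")
  if (from < 1 || to > d[ax]) stop("index range outside axis extent")
  idx <- from:to
  px <- if (ax == 1L) stack$pixels[idx, , , , , drop = FALSE]
        else stack$pixels[, idx, , , , drop = FALSE]
  fun <- switch(method, sum = sum, mean = mean, max = max)
  out <- apply(px, setdiff(1:5, ax), fun)
  dim(out) <- if (ax == 1L) c(1L, d[2:5]) else c(d[1], 1L, d[3:5])
  s <- stack
  s$pixels <- out
  s
}

#' Reslice a stack into a sagittal (XZ) view
#'
#' Reproduces the ImageJ "Reslice" + sum-projection step: the output plane
#' is indexed by z (vertical) and x (horizontal), with the intensity at
#' `(z, x)` equal to the sum over the selected y rows. Physical anisotropy
#' is carried through: the output row spacing is the z step and the column
#' spacing the original x pixel size.
#'
#' @param stack an [image_stack()].
#' @param y_range inclusive 1-based `(from, to)` bounds on the y axis.
#' @param projection only `"sum"` is supported.
#' @return An [image_stack()] with shape `(t, 1, c, Z, X)`.
#' @export
reslice_sagittal <- function(stack, y_range = NULL, projection = "sum") {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(projection, "sum")) stop("only sum projection is supported")
  d <- dim(stack$pixels)
  if (is.null(y_range)) y_range <- c(1L, d[4])
  from <- as.integer(y_range[1]); to <- as.integer(y_range[2])
  if (from > to || from < 1 || to > d[4]) stop("y range outside image")
  out <- array(0, dim = c(d[1], 1L, d[3], d[2], d[5]))
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[3])) {
      # (z, y, x) block -> sum over y -> (z, x)
      blk <- array(stack$pixels[t, , c, from:to, ], dim = c(d[2], to - from + 1L, d[5]))
      out[t, 1L, c, , ] <- apply(blk, c(1L, 3L), sum)
    }
  }
  image_stack(out,
              pixel_size_um = c(stack$z_step_um, stack$pixel_size_um[2]),
              z_step_um = stack$z_step_um,
              time_interval_s = stack$time_interval_s,
              channel_names = stack$channel_names)
}
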