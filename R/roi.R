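# Reconstruction of the embryo ROI-building macro: segment the analyzable
# boundary-network region from the Filamin channel, exclude nuclei (which
# fall below the Otsu threshold), bright autofluorescent spots, and manual
# exclusions.

#' ROI construction parameters
#'
#' Defaults mirror the original ImageJ macro: mean filter radius 4 px for
#' the ROI branch, radius 3 px for the spot branch, 50 px rolling-ball
#' radius, one binary dilation of the spot mask, Otsu for the ROI threshold
#' and MaxEntropy for the spot threshold.
#'
#' @param mean_radius_roi_px disc mean-filter radius for the ROI branch.
#' @param mean_radius_spot_px disc mean-filter radius for the spot branch.
#' @param rolling_ball_radius_px rolling-ball background radius.
#' @param dilation_iterations binary dilations applied to the spot mask.
#' @param roi_threshold_method,spot_threshold_method threshold algorithms
#'   (see [auto_threshold()]).
#' @return A list of class `roi_params`.
#' @export
roi_params <- function(mean_radius_roi_px = 4L, mean_radius_spot_px = 3L,
                       rolling_ball_radius_px = 50L, dilation_iterations = 1L,
                       roi_threshold_method = "otsu",
                       spot_threshold_method = "maxentropy") {
  stopifnot(mean_radius_roi_px >= 1, mean_radius_spot_px >= 1,
            rolling_ball_radius_px >= 1, dilation_iterations >= 0)
  structure(list(mean_radius_roi_px = as.integer(mean_radius_roi_px),
                 mean_radius_spot_px = as.integer(mean_radius_spot_px),
                 rolling_ball_radius_px = as.integer(rolling_ball_radius_px),
                 dilation_iterations = as.integer(dilation_iterations),
                 roi_threshold_method = roi_threshold_method,
                 spot_threshold_method = spot_threshold_method),
            class = "roi_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the image with a flat disc structuring element of the given radius and
#' subtracts it, clipping at zero. A flat background of any level is removed
#' entirely, and features narrower than the disc are preserved.
#'
#' @param image numeric `(y, x)` matrix.
#' @param radius_px structuring-element radius in pixels (>= 1).
#' @return Background-subtracted matrix (non-negative).
#' @export
rolling_ball_background <- function(image, radius_px = 50L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius_px < 1) stop("radius must be >= 1")
  if (2 * radius_px + 1 > min(dim(image))) {
    stop("rolling-ball radius larger than the image extent")
  }
  # EBImage grayscale morphology clamps to [0,1]; erosion/dilation commute
  # with increasing affine maps, so rescale around the call (exact).
  sc <- rescale01(image)
  if (sc$constant) return(array(0, dim(image)))
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  bg01 <- EBImage::opening(sc$x, brush)
  bg <- bg01 * sc$scale + sc$lo
  pmax(image - bg, 0)
}

#' Disc mean filter
#'
#' Replaces each pixel by the mean over the ImageJ-convention circular
#' neighborhood `dy^2 + dx^2 <= r^2`; image borders are handled by
#' reflection.
#'
#' @param image numeric `(y, x)` matrix.
#' @param radius_px neighborhood radius (>= 1).
#' @return Smoothed matrix of the same size.
#' @export
mean_filter <- function(image, radius_px) {
  stopifnot(is.matrix(image), is.numeric(image))
  r <- as.integer(radius_px)
  if (r < 1) stop("radius must be >= 1")
  k <- disc_kernel(r)
  k <- k / sum(k)
  padded <- reflect_pad(image, r)
  f <- EBImage::filter2(padded, k, boundary = "circular")
  f[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image)), drop = FALSE]
}

# One binary dilation with the ImageJ default 3x3 (8-connected) element.
dilate3x3 <- function(mask, iterations = 1L) {
  m <- mask
  if (iterations >= 1L) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(iterations)) {
      m <- EBImage::dilate(m * 1.0, brush) > 0.5
    }
  }
  m
}

#' Bright-spot mask for one channel
#'
#' Detects compact high-intensity autofluorescent spots: rolling-ball
#' background subtraction, then the difference between the
#' background-subtracted image and its disc mean filter (a high-pass that
#' isolates features smaller than the disc), MaxEntropy thresholding of the
#' difference, and binary dilation of the result.
#'
#' @param channel numeric `(y, x)` matrix.
#' @param params a [roi_params()].
#' @return Logical spot mask.
#' @export
build_spot_mask <- function(channel, params = roi_params()) {
  stopifnot(inherits(params, "roi_params"))
  rb <- rolling_ball_background(channel, params$rolling_ball_radius_px)
  m <- mean_filter(rb, params$mean_radius_spot_px)
  d <- rb - m
  t_spot <- tryCatch(auto_threshold(d, params$spot_threshold_method),
                     error = function(e) NULL)
  if (is.null(t_spot)) {
    # featureless difference image: nothing to exclude
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  dilate3x3(d > t_spot, params$dilation_iterations)
}

#' Build the embryo analysis ROI from the Filamin channel
#'
#' Reconstruction of the ImageJ macro that defines the analyzable region
#' for embryo colocalization: subtract the scalar background level, apply a
#' disc mean filter, Otsu-threshold the result and keep the above-threshold
#' pixels (the bright cell-boundary network; dark nucleus interiors fall
#' below), then remove manual exclusions and the bright-spot masks of every
#' supplied channel.
#'
#' @param filamin_channel numeric `(y, x)` matrix used for segmentation.
#' @param params a [roi_params()].
#' @param spot_channels list of channel matrices from which spot masks are
#'   built and excluded (default: the Filamin channel only).
#' @param manual_exclusion optional logical matrix of manually excluded
#'   pixels (e.g. high-autofluorescence embryo edges).
#' @param background_value scalar background level subtracted before
#'   filtering, typically the control-image background mean (default 0).
#' @return A list of class `roi_result` with elements `roi` (logical mask),
#'   `spot_masks` (list of logical masks), `empty` (flag set when the
#'   combined ROI has no pixels), `threshold` and `provenance`.
#' @export
build_embryo_roi <- function(filamin_channel, params = roi_params(),
                             spot_channels = NULL, manual_exclusion = NULL,
                             background_value = 0) {
  stopifnot(is.matrix(filamin_channel), inherits(params, "roi_params"))
  if (is.null(spot_channels)) spot_channels <- list(filamin_channel)
  x <- pmax(filamin_channel - background_value, 0)
  f <- mean_filter(x, params$mean_radius_roi_px)
  t_roi <- tryCatch(auto_threshold(f, params$roi_threshold_method),
                    error = function(e) NULL)
  if (is.null(t_roi)) {
    # constant (all-background) image: flagged-empty result, not an error
    empty <- matrix(FALSE, nrow(filamin_channel), ncol(filamin_channel))
    return(structure(list(roi = empty, spot_masks = list(), empty = TRUE,
                          threshold = NA_real_,
                          provenance = list(params = unclass(params),
                                            background_value = background_value)),
                     class = "roi_result"))
  }
  roi <- f > t_roi
  if (!is.null(manual_exclusion)) {
    stopifnot(is.logical(manual_exclusion),
              all(dim(manual_exclusion) == dim(filamin_channel)))
    roi <- roi & !manual_exclusion
  }
  spot_masks <- lapply(spot_channels, build_spot_mask, params = params)
  for (sm in spot_masks) roi <- roi & !sm
  structure(list(
    roi = roi,
    spot_masks = spot_masks,
    empty = !any(roi),
    threshold = as.numeric(t_roi),
    provenance = list(params = unclass(params),
                      background_value = background_value,
                      order = "subtract-scalar-background, mean-filter, otsu, manual-exclude, spot-exclude")
  ), class = "roi_result")
}
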