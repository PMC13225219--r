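# Synthetic actomyosin-ring time series: a polygonal ring that relaxes
# from hexagonal toward circular while its area contracts, rendered as an
# anti-aliased bright band with analytic ground-truth circularity.

#' Specification for a synthetic ring time series
#'
#' Defaults emulate an early-cellularization recording at desk scale: 15
#' frames at 3-minute intervals in a 160 x 160 px field, a ring of initial
#' circumradius 60 px (a ~9 um ring at 0.08 um/px confocal sampling) that
#' relaxes from a regular hexagon (circularity
#' `sqrt(3) * pi / 6` = 0.9069) to a circle over the first 10 frames while
#' the enclosed area contracts to half.
#'
#' @param n_frames number of frames.
#' @param frame_interval_min minutes between frames.
#' @param image_shape `(H, W)` in pixels.
#' @param n_sides sides of the initial regular polygon (default 6).
#' @param initial_radius_px initial circumradius.
#' @param circularity_profile target circularity per frame, non-decreasing
#'   in `(0, 1]`; default ramps from the regular-hexagon value to 1 by
#'   frame 10.
#' @param area_contraction final / initial enclosed area (default 0.5).
#' @param ring_thickness_px rendered band thickness.
#' @param amplitude,background band and background intensity.
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return A list of class `ring_series_spec`.
#' @export
ring_series_spec <- function(n_frames = 15L, frame_interval_min = 3,
                             image_shape = c(160L, 160L), n_sides = 6L,
                             initial_radius_px = 60,
                             circularity_profile = NULL,
                             area_contraction = 0.5,
                             ring_thickness_px = 4, amplitude = 200,
                             background = 20, noise_sd = 0, seed = 1L) {
  if (is.null(circularity_profile)) {
    c0 <- measure_circularity(regular_polygon(n_sides))$circularity
    ramp <- min(10L, n_frames)
    circularity_profile <- c(seq(c0, 1, length.out = ramp),
                             rep(1, max(0, n_frames - ramp)))
  }
  stopifnot(length(circularity_profile) == n_frames,
            all(circularity_profile > 0), all(circularity_profile <= 1),
            all(diff(circularity_profile) >= -1e-9),
            area_contraction > 0, ring_thickness_px > 0)
  structure(as.list(environment()), class = "ring_series_spec")
}

# Radial blend between a regular n-gon and the unit circle: the radial
# support function r(theta) = (1 - s) * r_ngon(theta) + s, with s chosen by
# root finding so the polygon hits the target circularity.
blend_shape_polygon <- function(target_circ, n_sides, n_vertices = NULL,
                                center = c(0, 0), scale = 1, phase = 0) {
  # sample a multiple of n_sides angles so polygon corners are vertices and
  # the s = 0 limit is the exact regular polygon
  if (is.null(n_vertices)) {
    n_vertices <- as.integer(n_sides * max(1, round(128 / n_sides)))
  }
  th <- phase + 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  # regular polygon radial function (apothem 1 scaled to circumradius 1)
  apoth <- cos(pi / n_sides)
  local_ang <- ((th - phase) %% (2 * pi / n_sides)) - pi / n_sides
  r_ngon <- apoth / cos(local_ang)
  poly_at <- function(s) {
    r <- (1 - s) * r_ngon + s
    cbind(x = center[1] + scale * r * cos(th), y = center[2] + scale * r * sin(th))
  }
  circ_at <- function(s) measure_circularity(poly_at(s), check_simple = FALSE)$circularity
  c_lo <- circ_at(0)
  if (target_circ <= c_lo + 1e-12) return(poly_at(0))
  if (target_circ >= circ_at(1) - 1e-12) return(poly_at(1))
  s <- uniroot(function(s) circ_at(s) - target_circ, c(0, 1), tol = 1e-10)$root
  poly_at(s)
}

# Minimum distance from each pixel center to a closed polygon's boundary.
polygon_boundary_distance <- function(H, W, poly) {
  p <- rbind(poly, poly[1, ])
  yy <- as.vector(matrix(rep(seq_len(H), W), H, W))
  xx <- as.vector(matrix(rep(seq_len(W), each = H), H, W))
  dmin <- rep(Inf, H * W)
  for (i in seq_len(nrow(p) - 1L)) {
    ax <- p[i, 1]; ay <- p[i, 2]
    bx <- p[i + 1, 1]; by <- p[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((xx - ax) * vx + (yy - ay) * vy) / L2)) else 0
    d <- sqrt((xx - (ax + t * vx))^2 + (yy - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
  }
  matrix(dmin, H, W)
}

#' Generate a synthetic ring time series
#'
#' Each frame renders the ring as an anti-aliased bright band of
#' `ring_thickness_px` around the frame's polygon. Truth circularity is
#' computed analytically from the polygon vertices (shoelace `4*pi*A/P^2`),
#' not from the rendering.
#'
#' @param spec a [ring_series_spec()].
#' @return A list with `stack` (an [image_stack()], one frame per time
#'   point) and `truth` (data.frame `frame`, `time_min`, `circularity`,
#'   `area`, `radius_scale`, plus the vertex list `polygons`).
#' @export
gen_ring_series <- function(spec = ring_series_spec()) {
  stopifnot(inherits(spec, "ring_series_spec"))
  with_local_seed(spec$seed, {
    H <- spec$image_shape[1]; W <- spec$image_shape[2]
    center <- c((W + 1) / 2, (H + 1) / 2)
    # enclosed area contracts linearly to area_contraction * initial area;
    # the scale compensates for the area change of the hexagon-to-circle
    # radial blend so the contraction is exact
    area_frac <- seq(1, spec$area_contraction, length.out = spec$n_frames)
    unit_polys <- lapply(seq_len(spec$n_frames), function(t) {
      blend_shape_polygon(spec$circularity_profile[t], spec$n_sides)
    })
    unit_areas <- vapply(unit_polys, function(p) {
      measure_circularity(p, check_simple = FALSE)$area
    }, numeric(1))
    area_target <- spec$initial_radius_px^2 * unit_areas[1] * area_frac
    scales <- sqrt(area_target / unit_areas)
    px <- array(0, dim = c(spec$n_frames, 1L, 1L, H, W))
    polys <- vector("list", spec$n_frames)
    truth <- data.frame(frame = seq_len(spec$n_frames),
                        time_min = (seq_len(spec$n_frames) - 1) * spec$frame_interval_min,
                        circularity = NA_real_, area = NA_real_,
                        radius_scale = scales / spec$initial_radius_px)
    for (t in seq_len(spec$n_frames)) {
      poly <- cbind(x = center[1] + scales[t] * unit_polys[[t]][, 1],
                    y = center[2] + scales[t] * unit_polys[[t]][, 2])
      polys[[t]] <- poly
      m <- measure_circularity(poly, check_simple = FALSE)
      truth$circularity[t] <- m$circularity
      truth$area[t] <- m$area
      d <- polygon_boundary_distance(H, W, poly)
      band <- pmin(1, pmax(0, spec$ring_thickness_px / 2 + 0.5 - d))
      frame <- spec$background + spec$amplitude * band
      if (spec$noise_sd > 0) frame <- pmax(frame + rnorm(H * W, 0, spec$noise_sd), 0)
      px[t, 1, 1, , ] <- frame
    }
    list(stack = image_stack(px, time_interval_s = spec$frame_interval_min * 60),
         truth = truth, polygons = polys)
  })
}
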