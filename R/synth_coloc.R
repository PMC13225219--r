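# Synthetic two-channel confocal fields with known ground truth: a bright
# cell-boundary network surrounding dark elliptical nuclei, shared
# autofluorescent spots, a tunable colocalized signal fraction, and
# Gaussian background noise.

#' Specification for a synthetic colocalization field
#'
#' Defaults describe a realistic blastoderm-like field at desk scale: a
#' 128 x 128 px image with ~12 nuclei of radius 10 px, a 4 px-wide bright
#' boundary network between them, 6 shared autofluorescent spots, and a
#' Gaussian background (mean 100, sd 5) with the network ~150 counts above
#' it. The colocalized fraction `coloc_fraction` is the mixing proportion
#' between the channel-A texture and a channel-B-private texture on the
#' shared boundary-network scaffold: the expected thresholded Pearson
#' correlation is `f / sqrt(f^2 + (1-f)^2)`, i.e. 0 at `f = 0` and 1 at
#' `f = 1`.
#'
#' @param image_shape `(H, W)` in pixels (>= 32 x 32).
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius_px `(mean, sd)` of nucleus radii.
#' @param boundary_width_px width of the boundary network band.
#' @param boundary_amplitude network brightness above background.
#' @param texture_sd relative sd of the multiplicative network texture.
#' @param coloc_fraction fraction `f` in `[0, 1]` of channel-A structural
#'   signal shared with channel B.
#' @param gain gain `g` applied to the shared signal in channel B.
#' @param independent_signal_level amplitude of channel-B-only blobs.
#' @param n_spots number of autofluorescent spots (identical coordinates
#'   and amplitudes in both channels).
#' @param spot_amplitude,spot_sigma_px spot brightness and Gaussian width.
#' @param background_mean,background_sd Gaussian background parameters.
#' @param nucleus_dim multiplicative background attenuation inside nuclei
#'   (both fluorophores are mostly absent from nuclei).
#' @param poisson_noise add Poisson shot noise on top of the Gaussian
#'   background (off by default).
#' @param seed RNG seed; generators are pure functions of the spec.
#' @return A list of class `coloc_field_spec`.
#' @export
coloc_field_spec <- function(image_shape = c(128L, 128L), n_nuclei = 12L,
                             nucleus_radius_px = c(10, 1),
                             boundary_width_px = 4,
                             boundary_amplitude = 150, texture_sd = 0.25,
                             coloc_fraction = 0.5, gain = 1,
                             independent_signal_level = 100,
                             n_spots = 6L, spot_amplitude = 600,
                             spot_sigma_px = 1.5,
                             background_mean = 100, background_sd = 5,
                             nucleus_dim = 0.5, poisson_noise = FALSE,
                             seed = 1L) {
  stopifnot(all(image_shape >= 32), coloc_fraction >= 0, coloc_fraction <= 1,
            background_sd >= 0, n_nuclei >= 1, boundary_width_px > 0,
            spot_sigma_px > 0, nucleus_dim >= 0, nucleus_dim <= 1)
  structure(as.list(environment()), class = "coloc_field_spec")
}

# Shared geometry + texture scaffold; everything derived deterministically
# from the spec seed so signal and control fields stay coordinated.
coloc_scaffold <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  yy <- matrix(rep(seq_len(H), W), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  # jittered-grid nucleus centers
  gsz <- ceiling(sqrt(spec$n_nuclei))
  cy <- rep(seq(0.5, gsz - 0.5) / gsz * H, gsz)
  cx <- rep(seq(0.5, gsz - 0.5) / gsz * W, each = gsz)
  jit <- 0.25 * min(H, W) / gsz
  cy <- cy + runif(length(cy), -jit, jit)
  cx <- cx + runif(length(cx), -jit, jit)
  pick <- sample(length(cy), spec$n_nuclei)
  cy <- cy[pick]; cx <- cx[pick]
  radii <- pmax(2, rnorm(spec$n_nuclei, spec$nucleus_radius_px[1],
                         spec$nucleus_radius_px[2]))
  # per-pixel distance to nearest and second-nearest nucleus center
  dmat <- matrix(Inf, H * W, 2L)
  nearest <- integer(H * W)
  for (i in seq_len(spec$n_nuclei)) {
    di <- sqrt((as.vector(yy) - cy[i])^2 + (as.vector(xx) - cx[i])^2)
    swap1 <- di < dmat[, 1]
    dmat[swap1, 2] <- dmat[swap1, 1]
    dmat[swap1, 1] <- di[swap1]
    nearest[swap1] <- i
    swap2 <- !swap1 & di < dmat[, 2]
    dmat[swap2, 2] <- di[swap2]
  }
  d1 <- matrix(dmat[, 1], H, W)
  d2 <- matrix(dmat[, 2], H, W)
  nucleus_mask <- d1 <= matrix(radii[nearest], H, W)
  # boundary network: Voronoi ridge band, anti-aliased, outside nuclei
  # hard band edges: a partial-intensity rim would put scaffold geometry
  # into both channels as a shared signal and bias the f = 0 correlation
  ridge <- d2 - d1
  band <- matrix(as.numeric(ridge <= spec$boundary_width_px), H, W)
  band[nucleus_mask] <- 0
  # multiplicative textures: smooth lognormal-ish fields
  tex_field <- function() {
    f <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = 2)
    f <- f / sd(f) * spec$texture_sd
    pmax(0.2, 1 + f)
  }
  tex_a <- tex_field()
  tex_b_private <- tex_field()
  # shared spots
  sy <- runif(spec$n_spots, 4, H - 3)
  sx <- runif(spec$n_spots, 4, W - 3)
  spots <- matrix(0, H, W)
  for (i in seq_len(spec$n_spots)) {
    spots <- spots + spec$spot_amplitude *
      exp(-((yy - sy[i])^2 + (xx - sx[i])^2) / (2 * spec$spot_sigma_px^2))
  }
  # channel-B-only blobs (independent structure)
  n_blobs <- 5L
  by <- runif(n_blobs, 8, H - 7); bx <- runif(n_blobs, 8, W - 7)
  blobs <- matrix(0, H, W)
  for (i in seq_len(n_blobs)) {
    blobs <- blobs + exp(-((yy - by[i])^2 + (xx - bx[i])^2) / (2 * 4^2))
  }
  bg_shape <- 1 - (1 - spec$nucleus_dim) * nucleus_mask
  list(H = H, W = W, band = band, nucleus_mask = nucleus_mask,
       network_mask = band > 0.5, tex_a = tex_a, tex_b_private = tex_b_private,
       spots = spots, spot_mask = spots > 0.5 * spec$spot_amplitude,
       blobs = blobs, bg_shape = bg_shape,
       centers = cbind(y = cy, x = cx), radii = radii)
}

add_noise <- function(signal, spec) {
  out <- signal + rnorm(length(signal), 0, spec$background_sd)
  if (spec$poisson_noise) {
    out <- out + (stats::rpois(length(signal), pmax(signal, 0)) - pmax(signal, 0))
  }
  matrix(pmax(out, 0), nrow(signal), ncol(signal))
}

#' Generate a two-channel colocalization field
#'
#' Channel A carries the full boundary-network structure; channel B carries
#' the gain-scaled mixture `f * texture_A + (1 - f) * texture_B` on the same
#' network scaffold plus channel-B-only blobs. Autofluorescent spots are
#' identical in both channels; nuclei are intensity voids in both. The truth
#' record contains the per-pixel structure masks and `f`, sufficient to
#' score any downstream quantity without re-running the generator.
#'
#' @param spec a [coloc_field_spec()].
#' @return A list with `channel_a`, `channel_b` ([image_stack()]s) and
#'   `truth` (masks `network`, `nuclei`, `spots`; `coloc_fraction`;
#'   `centers`, `radii`).
#' @export
gen_coloc_field <- function(spec = coloc_field_spec()) {
  stopifnot(inherits(spec, "coloc_field_spec"))
  with_local_seed(spec$seed, {
    sc <- coloc_scaffold(spec)
    f <- spec$coloc_fraction
    struct_a <- spec$boundary_amplitude * sc$tex_a * sc$band
    mix <- f * sc$tex_a + (1 - f) * sc$tex_b_private
    struct_b <- spec$gain * spec$boundary_amplitude * mix * sc$band +
      spec$independent_signal_level * sc$blobs
    base <- spec$background_mean * sc$bg_shape
    a <- add_noise(base + struct_a + sc$spots, spec)
    b <- add_noise(base + struct_b + sc$spots, spec)
    list(channel_a = image_stack(a),
         channel_b = image_stack(b),
         truth = list(network = sc$network_mask, nuclei = sc$nucleus_mask,
                      spots = sc$spot_mask, coloc_fraction = f,
                      centers = sc$centers, radii = sc$radii))
  })
}

#' Generate a single-fluorophore control field
#'
#' Background plus the shared autofluorescent spots only, under the same
#' noise model as [gen_coloc_field()]; with the same spec (same seed) the
#' spots sit at identical coordinates in the paired a/b controls and in the
#' signal field.
#'
#' @param spec a [coloc_field_spec()].
#' @param channel `"a"` or `"b"` (controls differ only in their noise
#'   draw).
#' @return An [image_stack()].
#' @export
gen_control_field <- function(spec = coloc_field_spec(), channel = c("a", "b")) {
  channel <- match.arg(channel)
  stopifnot(inherits(spec, "coloc_field_spec"))
  with_local_seed(spec$seed, {
    sc <- coloc_scaffold(spec)
    base <- spec$background_mean + sc$spots
    if (channel == "b") rnorm(1)  # decouple the a/b noise streams
    image_stack(add_noise(base, spec))
  })
}
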