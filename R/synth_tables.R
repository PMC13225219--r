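# Generative twin of the attachment-site study: gamma-distributed
# attachment-site lengths with log-scale genotype effects and nested
# (sample / image) random intercepts.

#' Specification for the attachment-site length simulation
#'
#' Defaults mirror the study design: four genotypes (wild type reference,
#' Filamin-closed, Drak-KO, and the double mutant) with 13/13/14/15 flies,
#' two images per fly and 10 sites per image (~20 sites per fly). Effects
#' are on the log scale: the double-mutant mean is
#' `exp(beta_closed + beta_ko + delta)` relative to wild type, so `delta`
#' is the epistatic (non-additive) interaction. Default effect sizes are a
#' clearly longer Filamin-closed (+0.25), a slightly shorter Drak-KO
#' (-0.08), and a positive epistasis (+0.2); the gamma shape 25 gives a
#' ~20% coefficient of variation.
#'
#' @param beta_closed,beta_ko,delta log-scale fixed effects.
#' @param intercept log baseline length (default `log(3)` micrometres).
#' @param gamma_shape gamma shape parameter `alpha` (> 0).
#' @param sd_sample,sd_image random-intercept SDs on the log scale.
#' @param n_flies_per_genotype integer vector of length 4 (wt, closed, ko,
#'   double) or a single count.
#' @param n_images_per_fly,n_sites_per_image design counts.
#' @param seed RNG seed.
#' @return A list of class `attachment_sim_spec`.
#' @export
attachment_sim_spec <- function(beta_closed = 0.25, beta_ko = -0.08,
                                delta = 0.2, intercept = log(3),
                                gamma_shape = 25, sd_sample = 0.1,
                                sd_image = 0.05,
                                n_flies_per_genotype = c(13L, 13L, 14L, 15L),
                                n_images_per_fly = 2L, n_sites_per_image = 10L,
                                seed = 1L) {
  stopifnot(gamma_shape > 0, sd_sample >= 0, sd_image >= 0,
            all(n_flies_per_genotype >= 1), n_images_per_fly >= 1,
            n_sites_per_image >= 1)
  if (length(n_flies_per_genotype) == 1L) {
    n_flies_per_genotype <- rep(n_flies_per_genotype, 4L)
  }
  stopifnot(length(n_flies_per_genotype) == 4L)
  structure(as.list(environment()), class = "attachment_sim_spec")
}

#' Generate an attachment-site length table
#'
#' Lengths are drawn as `Gamma(shape = alpha, mean = exp(X beta + u_sample
#' + u_image))` with independent Gaussian random intercepts per fly
#' (sample) and per image within fly.
#'
#' @param spec an [attachment_sim_spec()].
#' @return A data.frame with columns `length`, `genotype` (factor with
#'   levels `wt`, `closed`, `ko`, `double`), `sample`, `image`, plus the
#'   true effects in attribute `"truth"`.
#' @export
gen_attachment_table <- function(spec = attachment_sim_spec()) {
  stopifnot(inherits(spec, "attachment_sim_spec"))
  with_local_seed(spec$seed, {
    levels <- c("wt", "closed", "ko", "double")
    beta <- c(wt = 0, closed = spec$beta_closed, ko = spec$beta_ko,
              double = spec$beta_closed + spec$beta_ko + spec$delta)
    rows <- list()
    fly_id <- 0L
    for (g in seq_along(levels)) {
      for (fl in seq_len(spec$n_flies_per_genotype[g])) {
        fly_id <- fly_id + 1L
        u_s <- rnorm(1, 0, spec$sd_sample)
        for (im in seq_len(spec$n_images_per_fly)) {
          u_i <- rnorm(1, 0, spec$sd_image)
          mu <- exp(spec$intercept + beta[[levels[g]]] + u_s + u_i)
          rows[[length(rows) + 1L]] <- data.frame(
            length = rgamma(spec$n_sites_per_image, shape = spec$gamma_shape,
                            rate = spec$gamma_shape / mu),
            genotype = levels[g],
            sample = sprintf("fly%03d", fly_id),
            image = sprintf("fly%03d_im%d", fly_id, im))
        }
      }
    }
    out <- do.call(rbind, rows)
    out$genotype <- factor(out$genotype, levels = levels)
    attr(out, "truth") <- list(beta = beta, delta = spec$delta,
                               intercept = spec$intercept,
                               gamma_shape = spec$gamma_shape,
                               sd_sample = spec$sd_sample,
                               sd_image = spec$sd_image)
    out
  })
}

#' Generate synthetic cortical-recruitment intensity series
#'
#' Emulates the cortical fluorescence time course during early
#' cellularization: per sample, a z-stack per time point whose first
#' `n_slices` slices from the embryo edge carry `background + curve(t)`
#' while deeper slices carry background only; matched control stacks lack
#' the recruitment signal.
#'
#' @param n_samples number of samples.
#' @param recruitment_curve numeric vector, signal amplitude per time point
#'   (default: a rise-and-plateau over 12 points).
#' @param background_mean,noise_sd background level and Gaussian noise sd.
#' @param n_slices slices carrying the cortical signal (default 7).
#' @param n_z total z slices per stack.
#' @param image_shape `(H, W)` of each plane.
#' @param seed RNG seed.
#' @return A list with `signal` and `control`: each a list (per sample) of
#'   lists (per time point) of [image_stack()]s, plus `truth` (the curve).
#' @export
gen_intensity_series <- function(n_samples = 3L, recruitment_curve = NULL,
                                 background_mean = 50, noise_sd = 0,
                                 n_slices = 7L, n_z = 12L,
                                 image_shape = c(16L, 16L), seed = 1L) {
  if (is.null(recruitment_curve)) {
    tt <- seq(0, 1, length.out = 12L)
    recruitment_curve <- 100 * pmin(1, tt / 0.4) * exp(-pmax(0, tt - 0.6) * 1.5)
  }
  with_local_seed(seed, {
    H <- image_shape[1]; W <- image_shape[2]
    n_t <- length(recruitment_curve)
    one_stack <- function(amp) {
      px <- array(background_mean, dim = c(1L, n_z, 1L, H, W))
      px[1, seq_len(n_slices), 1, , ] <- background_mean + amp
      if (noise_sd > 0) px <- array(pmax(px + rnorm(length(px), 0, noise_sd), 0), dim(px))
      image_stack(px)
    }
    signal <- lapply(seq_len(n_samples), function(s) {
      lapply(seq_len(n_t), function(t) one_stack(recruitment_curve[t]))
    })
    control <- lapply(seq_len(n_samples), function(s) {
      lapply(seq_len(n_t), function(t) one_stack(0))
    })
    list(signal = signal, control = control,
         truth = list(recruitment_curve = recruitment_curve,
                      background_mean = background_mean))
  })
}
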