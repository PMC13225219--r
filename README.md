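# flico

Quantitative image analysis for two-channel confocal fluorescence
microscopy of *Drosophila* development: pixel-level colocalization with
control-calibrated thresholds, contractile-ring shape dynamics, intensity
profiling, and mixed-model comparisons of morphological measurements.

## The problem

Live imaging of fluorescently tagged proteins (e.g. a GFP-tagged kinase
and an mCherry-tagged actin cross-linker) raises three recurring
quantitative questions that this package answers with tested, reusable
code:

1. **Do two proteins colocalize, and how strongly?** Over an analyzable
   region of interest (ROI), with per-channel global intensity thresholds
   `t_A`, `t_B` calibrated on single-fluorophore control images
   (threshold = pooled control mean + 3 SD), the package computes the
   thresholded Manders coefficients and the thresholded Pearson
   correlation:

   - `M1 = Σ A_i [A_i > t_A ∧ B_i > t_B] / Σ A_i [A_i > t_A]` —
     the intensity-weighted fraction of channel-A signal that overlaps
     above-threshold channel B (`M2` symmetrically);
   - `tPCC` — the Pearson correlation of `(A_i, B_i)` over pixels above
     threshold in **both** channels.

   Per-image values are aggregated to sample level with pixel-count
   weights (`n_A` for M1, `n_B` for M2, `n_AB` for tPCC), and population
   inference uses one-sample t machinery on sample means — on the Fisher-z
   scale (`z = atanh r`) for tPCC, back-transformed to the correlation
   scale. A pixel-randomization null (permuting one channel within the
   ROI) validates the statistic.

2. **How round is the contracting actomyosin ring over time?** Each frame
   is Huang-thresholded, the inner edge of the ring band is traced at
   sub-pixel resolution, smoothed by truncating its Fourier descriptors
   (8% of the contour's descriptor pairs retained), and measured as
   circularity `4πA/P²` (1 for a circle, `√3π/6 ≈ 0.907` for a regular
   hexagon). Trajectories without net contraction are excluded, and the
   per-genotype trend is fitted as a penalized cubic spline in time with a
   random intercept per sample (REML).

3. **Do genotypes differ in attachment-site length, and is a double
   mutant worse than additive?** Lengths are modelled with a gamma GLMM,
   log link, nested random intercepts (image within sample):
   `length ~ genotype + (1 | sample/image)`. Three prespecified Wald
   contrasts — closed-vs-wild-type, knockout-vs-wild-type, and the
   epistasis contrast `β_double − β_closed − β_KO` — are tested with
   model-based standard errors and Bonferroni correction.

Because the microscope images behind such studies are rarely deposited,
the package ships a first-class synthetic-data module
(`gen_coloc_field()`, `gen_control_field()`, `gen_ring_series()`,
`gen_attachment_table()`, `gen_intensity_series()`) that generates every
pipeline input with known ground truth: bright cell-boundary networks
around dark nuclei, shared autofluorescent spots, a tunable colocalized
fraction, hexagon-to-circle ring series with analytic circularity, and
gamma-distributed length tables with planted effects.

The ImageJ-style ROI macro is reconstructed in full: Otsu / Kapur
MaxEntropy / Huang auto-thresholds on 256-bin histograms, rolling-ball
background subtraction, disc mean filters, bright-spot detection with
dilation, and manual exclusion masks.

## Worked example

```r
library(flico)

# simulate a two-channel field with half of the structural signal shared
spec  <- coloc_field_spec(coloc_fraction = 0.5, seed = 42)
field <- gen_coloc_field(spec)
a <- get_plane(field$channel_a); b <- get_plane(field$channel_b)

# per-channel global thresholds from single-fluorophore controls
t_a <- estimate_threshold(list(get_plane(gen_control_field(spec, "a"))))
t_b <- estimate_threshold(list(get_plane(gen_control_field(spec, "b"))))
# both 195.3 = background 100 + 3 x control SD

# ROI macro: boundary network in, nuclei and bright spots out
roi <- build_embryo_roi(a, spot_channels = list(a, b),
                        background_value = spec$background_mean)
res <- compute_coloc(channel_pair(a, b, roi$roi, t_a = t_a, t_b = t_b))
```

prints (via `str(res)` or formatting):

```
M1 = 0.985  M2 = 0.934  tPCC = 0.573  (n_a=2501, n_b=2655, n_ab=2459)
```

M1/M2 near 1 say that almost all above-threshold signal in each channel
sits on pixels where the other channel is also above threshold (both
channels occupy the same boundary network); the tPCC of 0.57 reflects the
planted 50% shared-texture fraction (expected
`f/√(f²+(1−f)²) = 0.71` attenuated by noise and the channel-B-only
structure). Aggregating three simulated samples and running population
inference on the Fisher-z scale gives

```
population tPCC = 0.575 [0.464, 0.668], p = 2.89e-03 (n = 3 samples)
```

A ring time series and the attachment-site model run the same way:

```r
series <- gen_ring_series(ring_series_spec(noise_sd = 2, seed = 1))
tr     <- build_trajectory(series$stack)
# frame 1: circularity 0.917 (truth 0.907); frame 15: 0.999 (truth 1.000)

tab <- gen_attachment_table(attachment_sim_spec(seed = 1))
wald_contrasts(fit_gamma_glmm(tab))
#             contrast estimate     se     z    p_raw p_bonferroni
# 1       closed_vs_wt   0.3129 0.0482  6.49 8.75e-11     2.62e-10
# 2           ko_vs_wt  -0.0956 0.0474 -2.02 4.35e-02     1.31e-01
# 3 double_vs_additive   0.1711 0.0664  2.58 1.00e-02     3.00e-02
```

(the generator planted `β_closed = 0.25`, `β_KO = −0.08`, epistasis
`δ = 0.2`).

A thin command-line wrapper over the same functions lives at
`inst/cli/flico.R`
(`Rscript flico.R simulate --config cfg.yaml --out dir/ --seed 3`, with
tracks `simulate | roi | coloc | rings | rings-trend | attachment-stats`);
every run writes a provenance JSON and a hash manifest.

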