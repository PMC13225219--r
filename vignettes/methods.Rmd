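---
title: "Methods: colocalization, ring morphometry and mixed models in flico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalization, ring morphometry and mixed models in flico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in `flico`,
the assumptions behind them, the tunable parameters, the numerical
conventions, and the design choices that were genuinely open. The package
analyses two-channel confocal fluorescence recordings of *Drosophila*
development — embryonic cellularization and pupal flight-muscle
development — and ships synthetic-data generators that produce every
pipeline input with known ground truth.

## 1. Colocalization

### Model

For two registered channels $A$ and $B$ restricted to an inclusion ROI,
with per-channel global thresholds $t_A$, $t_B$:

$$M_1 = \frac{\sum_i A_i\,[A_i > t_A \wedge B_i > t_B]}{\sum_i A_i\,[A_i > t_A]},
\qquad
M_2 = \frac{\sum_i B_i\,[A_i > t_A \wedge B_i > t_B]}{\sum_i B_i\,[B_i > t_B]},$$

and tPCC is the Pearson correlation of $(A_i, B_i)$ over the pixels above
threshold in *both* channels. "Above" is strict (`>`): ties at the
threshold belong to the background class, matching ImageJ's thresholding
of the upper class; this must be fixed for bit-reproducibility and is
asserted against a brute-force oracle in the tests.

The thresholds are calibrated per channel on single-fluorophore control
images acquired with the same settings: the threshold is the pooled
control pixel mean plus `k_sd = 3` pooled standard deviations. "Weighted
mean" is resolved as weighting image means by their masked pixel counts,
which equals the pooled pixel mean; if control images all have the same
masked area this coincides with the unweighted mean of image means. On a
Gaussian background this leaves a known tail fraction
($\Phi(-3) \approx 0.13\%$) of control pixels above threshold, which the
acceptance script measures.

### Hierarchy and inference

$M_1$, $M_2$, tPCC are computed per image. Sample-level summaries are
weighted means and frequency-weighted standard deviations
($\sum w (x-\bar x_w)^2 / (\sum w - 1)$, weights = pixel counts: $n_A$ for
$M_1$, $n_B$ for $M_2$, $n_{AB}$ for tPCC; a missing per-image statistic
drops out with its weight). Population inference is a one-sample
two-sided t test and 95% t interval over the per-sample means: on the raw
scale for $M_1$/$M_2$ (the interval is deliberately left unclipped, so an
upper bound above 1 is possible), and on the Fisher-z scale
($z = \operatorname{atanh} r$) for tPCC with the point estimate and
interval back-transformed, which keeps the interval inside $(-1, 1)$ and
makes it asymmetric around the estimate. Sample means that reach
$|r| = 1$ — possible on clean synthetic data — are clamped to $1 - 10^{-6}$
with a warning rather than erroring.

Validity of the statistic is checked by the pixel-randomization null:
permuting one channel's values inside the ROI destroys the spatial
pairing while preserving the intensity multiset, and the mean tPCC over
many permutations must sit within Monte-Carlo error of zero.

### Degenerate inputs

$M_1$ is `NA` when no A pixel exceeds $t_A$ (likewise $M_2$); tPCC is `NA`
with fewer than 2 jointly-above pixels or zero variance in either channel
on them. Population inference requires at least 2 samples.

## 2. ROI construction (embryo macro)

The analyzable region is segmented from the Filamin channel only:

1. subtract a scalar background level (the control-image background mean —
   the rolling ball is reserved for the spot branch, since the original
   macro names it only there; the order is recorded in the result's
   provenance),
2. disc mean filter, radius 4 px,
3. Otsu threshold on a 256-bin histogram; pixels above form the candidate
   ROI (the bright cell-boundary network; dark nucleus interiors fall
   below),
4. subtract user-supplied manual exclusion masks (PNG, 0/255),
5. subtract per-channel bright-spot masks.

The spot branch per channel: rolling-ball background subtraction
(radius 50 px), disc mean filter (radius 3 px), difference image
(a high-pass isolating features smaller than the disc), MaxEntropy
threshold, one binary dilation with the 3×3 8-connected element (ImageJ's
binary Dilate default).

Numerical conventions: the "radius r" disc is the exact set
$\{(dy,dx): dy^2+dx^2 \le r^2\}$ (ImageJ's kernel differs by at most a
1-px rim); filter edges are reflected; histograms use 256 bins on
min–max-rescaled intensities (mirroring ImageJ AutoThreshold on 16-bit
data), and the returned threshold is the upper edge of the chosen split
bin, so an intensity offset shifts the threshold by the same amount
within one bin width. The rolling ball is implemented as grayscale
opening with a flat disc structuring element; this removes any flat
background exactly, is invariant to adding a constant, and preserves
features narrower than the disc, which is what the spot branch relies on.
A constant (all-background) image cannot be thresholded; the ROI builder
returns a flagged-empty result rather than an error, and an empty ROI
after combination is likewise flagged, not thrown.

Threshold algorithms implemented (each on the 256-bin histogram): Otsu
(maximum between-class variance; ties broken toward the lowest bin —
inside an empty histogram gap every split maximizes the criterion, so
implementations legitimately differ in the returned value while inducing
the same classification), Kapur–Sahoo–Wong maximum entropy (empty bins
skipped), and Huang–Wang fuzzy-entropy minimization (membership
$u = 1/(1+|x-\mu_{class}|/C)$ with $C$ the occupied histogram span).

## 3. Ring morphometry

### Pipeline

Per frame of a time-lapse: optional classical denoising (none / Gaussian /
median — a flagged substitute for ML-based denoising, which would pull in
trained weights without changing what the shape measurements test), Huang
threshold, keep the largest connected component, trace the *inner* edge of
the annular band, smooth, measure. The inner edge is extracted as the 0.5
iso-contour of the lightly blurred (σ = 0.5 px) binary mask via marching
squares, picking the traced contour that encloses the mask's single hole;
zero or multiple holes raise a topology error with the hole count. The
contour is resampled to equally spaced vertices and smoothed by Fourier
descriptors: the vertex sequence is treated as complex numbers, the DFT
taken, and only the lowest `max(2, round(pct/100 * n))` frequency pairs
retained (plus the centroid term), with `pct = 8` by default.

The descriptor proportion is taken **relative to the contour's own vertex
count** (the smoothing plugin's "relative proportion" mode), not relative
to a fixed resample size. This matters: truncating a sharp-cornered
polygon to 10 pairs (8% of a fixed 128) rounds its corners enough to
inflate circularity by ~0.03–0.04, while 8% of a typical full-resolution
contour (several hundred vertices) keeps enough harmonics that rendered
squares, hexagons and near-circles all measure within ±0.02 of their
closed forms — the accuracy the shape oracle demands. A fixed count is
available via `n_vertices` for users who want the plugin's absolute mode.

Circularity is ImageJ's $4\pi A / P^2$, area by the shoelace formula,
perimeter by summed vertex distances; it is scale- and
rotation-invariant (asserted to $10^{-10}$) and self-intersecting
polygons are rejected.

Trajectories set time zero at the first frame after the 14th nuclear
division (an input index, as in manual practice); frames whose
segmentation fails become missing rows without breaking time order. The
exclusion rule "no contraction after passing the basal level" is
operationalized as: excluded when the final measurable area exceeds
$(1 - f_{min})$ × the initial area, with `min_contraction_frac` default
0.2 (no number is stated in the source methods; 20% is a conservative
floor well below the ~50% contraction of real rings).

### Trend model

Per genotype, circularity is modelled as a penalized cubic-spline smooth
of time plus a zero-mean Gaussian random intercept per sample, fitted by
REML (`mgcv::gam`, basis dimension 10, capped at the number of distinct
time points). The fitted curve and pointwise SE are reported on a uniform
grid with the random intercepts excluded. The source analysis averaged
circularity per time point *and* used per-sample intercepts; fitting on
per-sample points is the coherent version of that structure, and a
`pre_average` flag reproduces the averaged variant (without intercepts)
for comparison. As the spline penalty grows the fit tends to the weighted
*linear* trend (the cubic penalty's null space), so "flatness at high
penalty" holds only for trend-free data — the tests assert exactly that.

## 4. Intensity profiles

Cortical recruitment: mean intensity of `n_slices = 7` z slices from the
embryo edge per time point; the edge slice is a per-sample input or
auto-detected as the first slice whose mean exceeds the control mean
+ 3 SD; background (matched control at the same time point) is subtracted
per time point, then the series is min–max normalized per sample. A
constant series normalizes to all zeros with a flag instead of dividing
by zero. When the control series is time-constant, correction followed by
normalization equals normalization alone — a property test.

Depth profiles: mean ROI intensity per z plane, depth = plane index × z
step. Alignment shifts each sample so the reference channel's interior
peak sits at depth 0 (a boundary maximum is an alignment error for that
sample), interpolates linearly onto a shared grid at the native z step,
and averages per depth. Displacement series subtract the first time
point's junction coordinate; across samples the time axes are shifted so
compaction minima coincide, with the configurable convention that the
earliest aligned point maps to 24 h APF. Local regression is classical
tricube LOESS (`stats::loess`, span 0.75, degree 2 defaults), exact on
polynomials up to the local degree.

## 5. Attachment-site gamma GLMM

Lengths are strictly positive and right-skewed, so the model is
$y \sim \Gamma(\alpha, \mu_{ij}/\alpha)$ with
$\log \mu_{ij} = x_{ij}^\top\beta + u_{s(ij)} + v_{i(ij)}$, genotype as a
treatment-coded fixed effect (wild-type reference; the double mutant is a
fourth level), and nested Gaussian intercepts for sample and image within
sample. Estimation is Laplace-approximated maximum likelihood via
`glmmTMB`. The original analysis called `lme4::glmer`; point estimates
from the two engines agree closely (asserted in the tests), but `glmer`'s
model-based Wald standard errors for gamma families are substantially
inflated relative to the empirical sampling spread at this design, which
would make the prespecified Wald tests conservative (near-zero type-I
rate) and the intervals over-cover. `glmmTMB` fits the identical model
with calibrated standard errors — verified by the simulation study the
acceptance script re-runs (bias, interval coverage, and epistasis type-I
rate at the study design scale of 13–15 flies per genotype, two images
per fly, ten sites per image).

Contrasts are linear combinations $c^\top\beta$ with model-based
$\mathrm{se} = \sqrt{c^\top V c}$, two-sided normal (Wald z) p values, and
Bonferroni correction with $m$ = the number of supplied contrasts
(default: the three prespecified ones, $m = 3$, not all pairwise). The
epistasis contrast is $\beta_{double} - \beta_{closed} - \beta_{KO}$ on
the log scale: it is zero exactly when the double mutant's log-mean
effect is the sum of the single-mutant effects. The contrast machinery is
cross-checked against `multcomp::glht` on a fixed-effect gamma GLM.

The Western-blot fold-change ratio is the trivial tabular operation:
per lane, phospho and total intensities are each divided by the mean over
the reference-genotype lanes, and the reported quantity is the ratio of
those fold changes.

## 6. The synthetic-data generators

All generators are pure functions of their spec (seed included): the same
spec yields bit-identical output, and the caller's RNG state is restored.
Truth records carry everything needed to score downstream results without
re-running the generator.

**Colocalization fields** emulate a blastoderm-stage embryo field shortly
after the 14th nuclear division: ~12 dark elliptical nuclei (intensity
voids in both channels) surrounded by a bright boundary network (the
Voronoi ridge between nuclei, 4 px wide, with hard edges — a
partial-intensity rim would inject scaffold geometry into both channels
as a shared signal and bias the zero-colocalization limit), sparse bright
spots at identical coordinates in both channels (autofluorescent debris),
and additive Gaussian background noise (mean 100, sd 5 counts; Poisson
shot noise optional behind a flag — Gaussian noise suffices to exercise
the thresholding logic). The colocalized fraction $f$ is the mixing
proportion between the channel-A texture and a channel-B-private texture
on the same network scaffold, plus channel-B-only blobs: under this
construction the expected tPCC is $f/\sqrt{f^2+(1-f)^2}$ — 0 at $f=0$,
1 at $f=1$, strictly increasing — which is what makes the
fraction-recovery study meaningful. (The alternative reading, duplicating
a random *subset* of network pixels, makes the jointly-above pixels exact
copies and pins tPCC near 1 for every $f > 0$, so it was rejected.) The
multiplicative network texture has relative sd 0.25: enough pixel-to-pixel
variation to carry correlation, mild enough that texture dips stay above
the Otsu threshold after mean filtering.

Control fields are flat background + the shared spots under the same
noise model, matching the "single-fluorophore flies imaged with the same
settings" design.

**Ring series** render a polygon that relaxes from a regular hexagon to a
circle (radial blend between the hexagon's support function and the
circle, with the blend weight solved by root finding so each frame hits
its target circularity exactly) while the enclosed area contracts
linearly to 50%, as an anti-aliased band of thickness 4 px. Defaults are
a 160×160 px field with initial circumradius 60 px — a ~9 µm ring at the
0.08 µm/px confocal sampling used for embryo recordings — 15 frames at
3-minute intervals. Truth circularity is computed analytically from the
polygon vertices, never from the rendering. The ring size matters for
validation: sub-pixel contour accuracy and descriptor truncation both
leave relative errors that shrink with radius, and at radius 60 px the
full pipeline stays within the ±0.02 oracle band even for the rendered
square (the hardest case).

**Attachment tables** draw
$y \sim \Gamma(\alpha, \text{mean} = e^{X\beta + u_s + v_i})$ at the study
design scale: 13/13/14/15 flies for wild type / Filamin-closed / Drak-KO /
double mutant, 2 images per fly, 10 sites per image. Default effects:
$\beta_{closed} = 0.25$ (clearly longer), $\beta_{KO} = -0.08$ (slightly
shorter), epistasis $\delta = 0.2$, shape $\alpha = 25$ (a ~20%
coefficient of variation), random-intercept sds 0.10 (sample) and 0.05
(image) on the log scale — magnitudes chosen once to mirror the
qualitative findings (a significant lengthening, a small shortening, a
significant positive interaction) at a realistic signal-to-noise.

**What the generators do not emulate**: optical point-spread functions,
depth-dependent attenuation, photobleaching, chromatic misregistration,
nucleus shape irregularity, or spatially correlated (structured) noise.
Passing the validation suite therefore demonstrates correctness of the
*statistics and algorithms* under a controlled image model, not
robustness to every artifact of real microscopy; on real data the
control-calibrated thresholds and the manual-exclusion mechanism are the
main defenses against such artifacts.

## 7. Problem sizes used in validation

The test and acceptance studies run at desk scale, chosen as the smallest
sizes at which the measured quantities are stable: 128×128 px
colocalization fields (20 seeds per planted fraction), 160×160 px ring
series, 2×2/3×3 integer images for exhaustive/bit-exact oracle
comparison (the full cross product of 3×3 images over five intensity
levels is combinatorially out of reach; exhaustive enumeration runs at
2×2 over three levels), 500 replicates for the Fisher-z coverage study,
and 120–200 replicates of the full GLMM design for bias, coverage and
type-I measurement.

## 8. Known limitations

- TIFF output is 32-bit float (bit-exact at float32 precision; 64-bit
  TIFFs are not written because the reading library does not support
  them). Multi-page TIFFs carry no axis metadata; the `(t, z, c)` layout
  is the caller's responsibility.
- The rolling ball uses a flat disc structuring element, not the
  paraboloid of ImageJ's implementation; for background flatness,
  offset invariance and spot preservation the two agree, but the exact
  background estimate under a curved gradient differs.
- Huang thresholding follows the published fuzzy-entropy formulation;
  ImageJ's port differs in minor binning details, so thresholds can
  differ by a bin on identical data.
- One ring per recording is assumed (as measured in the source study);
  there is no multi-ring tracking.
- The gamma GLMM assumes a common shape across observations and
  log-normal random intercepts; neither is tested against alternatives
  (model selection is out of scope).
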