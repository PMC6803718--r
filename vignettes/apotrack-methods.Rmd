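---
title: "Methods: shape-constrained aponeurosis tracking and 1D SPM of muscle thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-constrained aponeurosis tracking and 1D SPM of muscle thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apotrack)
```

# The problem

B-mode ultrasound of the triceps surae (soleus SO, medial/lateral
gastrocnemius MG/LG) shows the muscles' aponeuroses as three bright,
gently curved bands: superficial, middle and deep. Muscle thickness — the
vertical distance between the two aponeuroses bounding a muscle belly —
changes systematically through the stride cycle, and whether a single
mid-image thickness measurement represents the whole imaged region is an
empirical question that requires (i) segmenting all three boundaries in
every frame of long image sequences, (ii) converting boundary fits into
thickness at many sites time-normalised to the stride, and (iii) testing
region and condition effects over the whole stride continuum rather than
at hand-picked instants. `apotrack` implements that full chain, plus a
synthetic phantom world in which every stage can be validated against
known truth.

# Segmentation model

## Point distribution model

Each frame's segmentation is a single configuration of 57 landmarks: 19
per boundary, laterally spaced 32 px (about 2.75 mm at the default pixel
pitch of 2.75/32 mm/px), ordered superficial, middle, deep. Training
shapes (hand labels in the real protocol; subsampled phantom truth here)
are stacked as 114-vectors and summarised by their mean and the
eigendecomposition of the sample covariance (n−1 denominator). The
smallest number of leading modes whose cumulative eigenvalue fraction
reaches the variance target (default 0.985) is retained.

Shapes are modelled in **raw image coordinates** — no Procrustes
alignment. The transducer is fixed to the limb, so absolute image position
carries information; removing pose would discard the depth changes that
are the measurement of interest. This is a deliberate design choice, not a
claim about how the original analysis was configured.

A candidate shape is made *plausible* by projecting onto the retained
modes and clipping every coefficient to ±3 standard deviations
(`sd_limit * sqrt(lambda_i)`); the operation is idempotent and never
increases a coefficient magnitude.

## Appearance model and search

At each landmark, image appearance is summarised by the normalised
intensity gradient along the boundary normal: intensities are sampled by
bilinear interpolation at 2k+3 unit-spaced positions (k = 2), central
differences give 2k+1 gradient values, and the vector is normalised by its
L1 norm (the Cootes–Taylor convention; the gradient estimator and the norm
are design choices, since only "normalised" is specified upstream).
Profiles collected over training frames are modelled per landmark and per
resolution level as a Gaussian; covariance is regularised by adding
1e-6 × mean diagonal (at least 1e-10) so Mahalanobis scoring never
pseudo-inverts a singular matrix silently.

The search is multiresolution: pyramids are built by Gaussian smoothing
(sigma 1 px) and factor-2 decimation, so coordinates divide by 2 per
level. At each level, coarsest first, every landmark moves to the integer
offset in ±5 px (per level) minimising its Mahalanobis distance — ties
break toward smaller |offset|, then the negative offset — and the whole
configuration is re-projected into the plausible space. A level stops when
90% of landmarks move less than one level-pixel, or after 10 iterations.
The search range, iteration cap and convergence fraction are not specified
upstream; these values let a coarse level traverse ±40 full-resolution
pixels while keeping each level cheap.

Tracking uses 4 levels; the first frame of a trial, which has no
predecessor to inherit from, uses 5 levels and two independent starts (the
mean shape of each training trial), keeping the result whose Mahalanobis
distance summed over all landmarks *and all levels* is smallest. The
"4 track / 5 init" split is one reading of an internally inconsistent
level count in the source description (full resolution + "three lower"
= 4, yet "five resolution levels" for initialisation); both counts are
configurable.

# Thickness pipeline

Fitted boundaries are interpolated with monotone piecewise-cubic
(Fritsch–Carlson) splines — exact at landmarks, non-overshooting, and
within 0.1 px of a gently curved analytic boundary (5 px amplitude at
32 px landmark spacing). Thickness is the **vertical** (depth-axis)
distance between the deep and superficial boundary of each muscle — the
literal reading, not perpendicular distance — evaluated at 20 equally
spaced x-positions over the common span, converted to mm, with the
arithmetic mean appended as a 21st series. In the gastrocnemius view the
muscle lies between boundaries 1–2 and the soleus between 2–3.

Strides are segmented from the vertical GRF by upward crossings of a 20 N
threshold with a 50 ms debounce (both invented, as no event rule is given
upstream); each of 4 consecutive strides is linearly resampled onto 200
nodes spanning the half-open strike-to-strike interval (node i at
i/200 of the stride, so 1 node = 0.5% stride). The quiet-standing
baseline — the per-site mean over a static trial — is subtracted to give
thickness change. The mean-site series stays the mean of the 20 site
series through every linear stage; tests assert this to 1e-10.

# Statistical model

At every node independently, a balanced within-subject two-way ANOVA is
computed with subject as the random block. Strides are treated as
within-cell replicates and averaged into subject × region × condition
cell means before the ANOVA; each effect is tested against its
interaction with subject (region: MS_region / MS_region×subject, etc.).
The alternative reading — strides as an explicit repeat dimension — is
deliberately not the default: averaging replicates before a
subject-blocked ANOVA is the standard within-subject SPM construction.
No sphericity correction is applied by default. Whether the mean series
belongs in the omnibus region factor is questionable (it is a linear
combination of the other 20); it is included as described upstream, and
callers can simply drop it from the design.

Field smoothness is estimated from the model residuals: pointwise
unit-variance normalisation, forward differences along nodes, and
FWHM = sqrt(4 ln 2) / RMS(gradient). Convolving white noise with a
Gaussian kernel of FWHM f yields fields whose estimated smoothness is f,
which the generator tests confirm within 10%.

The critical threshold solves expected Euler characteristic = alpha by
bisection (tolerance 1e-6 in the statistic), with
EC(u) = P0(stat > u) + resels × rho1(u), resels = (n_nodes − 1)/FWHM, and
Worsley's 1D EC densities. Two identities pin the F density down: at
FWHM → ∞ the threshold equals the 0D quantile, and at k = 1 the F(1, v)
threshold equals the square of the two-sided t(v) threshold. (An early
draft used a 1/(2π) prefactor in the F density; the k = 1 identity and a
simulated type-I error of 0.10 exposed it, and the corrected 1/sqrt(2π)
form brings the simulated field-wise false-positive rate to 0.04–0.05 at
alpha 0.05.) Clusters are maximal runs of nodes strictly above threshold,
reported as half-open intervals in % stride at node resolution; two-sided
t fields are thresholded on |t|. Post-hoc families divide alpha by the
number of comparisons (Bonferroni).

Degenerate inputs are reported, not patched: zero difference variance at
a node gives a signed-infinite flagged t; identical effect and error mean
squares of exactly zero give F = 0; all-zero residuals in a
self-comparison fall back to the 0D threshold (infinitely smooth field)
rather than erroring inside a family.

# The phantom world

The generator renders each boundary as a Gaussian-profiled bright ridge
(sigma 3 px) on the true curve — polynomial-plus-sinusoid in x, sinusoid
in time — over a 0.15 background, with multiplicative gamma speckle and
additive Gaussian noise, clamped to [0, 1]. `noise_snr10()` (speckle
variance 0.005, additive sd 0.02 against band brightness 0.8) gives a
ridge-to-noise ratio near 10. Image size (300 × 608), frame rates, stance
peak (1600 N) and duty factor (0.35, running-like) are not specified by
the source protocol and were fixed once at values a musculoskeletal
ultrasound/gait lab would call unremarkable. GRF stance phases are
half-sine bumps; truth foot-strike times are recorded on the sampling
grid. Hand-labelling every 20th frame of two trials is emulated by
subsampling phantom truth shapes at a configurable stride (tests use
every 3rd or 5th frame of shorter trials to keep 10–20 training shapes,
the stated range).

What the phantom does **not** emulate: acoustic scattering and
attenuation, probe motion and out-of-plane fascicle motion, intensity
inhomogeneity, and real inter-subject anatomy. A green phantom test
therefore establishes that the algorithms are implemented correctly — not
that the method reaches any particular accuracy on clinical images.

Smooth null fields for statistics validation are white Gaussian noise
convolved with a Gaussian kernel of the requested FWHM, rescaled to exact
unit pointwise variance; effect fields add subject intercepts and
region/condition offset curves over a fully crossed balanced design. One
stated example constant was found wrong when computed honestly:
FWHM = 10 × n_nodes does *not* make fields near-constant to 0.05 — the
increment sd over the span is ~0.14 at that smoothness — so the
near-constant limit is asserted at FWHM = 200 × n_nodes, where the
derivation genuinely gives range < 0.05.

# Numerical and I/O choices

- 0-based pixel coordinates, x = column, y = row (depth increases
  downward); bilinear sampling clamps to the image edge.
- Integer-offset landmark search with deterministic tie-breaks makes
  fits reproducible bit-for-bit under a fixed seed; the whole pipeline
  derives per-stage seeds from one root seed and stamps an MD5 config
  hash into the run manifest.
- Image sequences are stored as PGM stacks (P2/P5, 8/16-bit) with a JSON
  sidecar, because the deployment environment has no TIFF reader for R;
  16-bit quantisation (≈1.5e-5 intensity) is below every tolerance used.
- Thickness tables are long-format CSV
  (trial, muscle, stride, site ∈ {1..20, mean}, node ∈ {0..199},
  thickness_mm, change_mm); models and fits are JSON archives.

# Worked example

```{r example, eval = FALSE}
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
print(res$spm$SO)
geometry_example()
```

The geometry table reproduces the planar worked example: a soleus with
44 mm fascicles and a 15 mm belly has pennation asin(15/44) ≈ 19.9° (~20°);
a 15% thicker belly gives ≈ 23.1° (~23°) at fixed fascicle length, or
≈ 50.6 mm (~51 mm) fascicles at fixed pennation.

# Known limitations

- The RM-ANOVA supports balanced designs only; missing strides must be
  handled upstream.
- Cluster inference is existence-only (no cluster-level p-values), and
  endpoints are reported at node resolution without interpolation.
- The ASM has no temporal smoothing or motion prediction beyond copying
  the previous frame's fit; very fast motion (> search range per frame at
  the coarsest tracking level) will lose lock and be flagged rather than
  recovered.
- Real-data headline statistics (critical F values, mm differences,
  cluster intervals of the source study) depend on a human dataset and
  manual labels and are intentionally out of scope.
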