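---
title: "Methods: wide-field optical imaging functional connectivity"
author: "woifc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-field optical imaging functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woifc)
```

## The measurement and its model

Wide-field optical intrinsic signal (OIS) imaging records diffuse skull
reflectance of sequentially fired LEDs (530, 590 and 625 nm here) with a
camera, at 16 frames/s per channel after light separation. Fluctuations in
oxy- and deoxy-hemoglobin concentration modulate absorption differently at
each wavelength; the modified Beer–Lambert law linearizes this around the
temporal mean:

$$\Delta A_\lambda(p, t) \;=\; L_\lambda\,\big[\varepsilon_{HbO_2,\lambda}\,
\Delta c_{HbO_2}(p, t) + \varepsilon_{HbR,\lambda}\, \Delta c_{HbR}(p, t)\big],$$

where $\Delta A_\lambda = -\log\!\big(R_\lambda / \langle R_\lambda\rangle_t\big)$
is the differential absorption from the log-mean transform, $L_\lambda$ a
wavelength-dependent differential pathlength factor and $\varepsilon$ the
extinction coefficients. With three wavelengths and two chromophores the
system is overdetermined; `invert_spectroscopy()` solves it per pixel and
frame by least squares (the pseudoinverse solution). The shipped
$\varepsilon$ and $L$ values are approximate constants rounded from
standard hemoglobin absorption compilations — adequate for the relative
(contrast) units used throughout and for simulation, and replaceable via
`spectroscopy_model()` when calibrated tables are available. Only the
conditioning of the $3\times 2$ system affects the pipeline's behavior.

Downstream analysis uses the HbO$_2$ contrast only.

## The preprocessing chain

`preprocess_stack()` applies, in a fixed and provenance-recorded order:

1. **Downsampling** — spatial block means (75×100 px from 1200×1600 in the
   full acquisition geometry) and pairwise temporal averaging 16→8 frames/s.
   Block means rather than interpolation preserve photon statistics and
   round-trip integer counts predictably.
2. **Masking** — a user-supplied brain mask with left/right hemisphere
   labels (the hemisphere split is a column convention; rows run
   anterior→posterior, 1-based, column-major).
3. **Second-order detrending** — per-pixel quadratic-in-time least squares,
   with the temporal mean re-added so the log-mean step stays well defined.
   A per-frame quadratic *spatial* surface fit is implemented
   (`detrend_series(..., spatial = TRUE)`) but not part of the default
   chain: its constant term is exactly per-frame global signal regression,
   which this pipeline deliberately replaces with per-hemisphere regression
   later, and its quadratic terms project out genuine large-scale signal
   when functional regions span the field of view. Static spatial variation
   (vignetting) is multiplicative and cancels exactly in the log-mean
   ratio; spatially varying slow drift is handled by the per-pixel temporal
   fit.
4. **Log-mean transform and spectroscopy inversion** (above).
5. **Masked Gaussian smoothing** — 5×5 kernel, σ = 1.3 px, with weights
   renormalized over the in-mask support of each pixel
   (`make_smoothing_operator()` builds the sparse operator once). Plain
   convolution would bleed masked-out values (vein, off-brain) inward.
6. **Hemispheric signal regression** — each hemisphere's in-mask mean trace
   is regressed (with intercept) out of every pixel of that hemisphere, in
   lieu of global signal regression. Note the known artifact: removing a
   mean that contains a share of the regional signals both induces
   anticorrelations between regions and slightly inflates homotopic
   correlations (see *Recovery accuracy* below).
7. **Band-pass 0.02–0.167 Hz** — order-5 Butterworth low-pass and
   high-pass sections in cascade, each applied forward–backward (zero
   phase) after removing the per-pixel mean, with odd-reflection padding of
   three periods of the low cutoff. The cascade is used instead of the
   single 10th-order band-pass polynomial because the band lies far below
   Nyquist, where the direct transfer-function form is numerically fragile
   (measured ~10% passband error versus <0.1% for the cascade). Measured
   response at 8 frames/s: gain 1.001 at 0.08 Hz, attenuation ≥ 99.9% at
   0.5 Hz, DC removed exactly.
8. **Censoring** — frames whose in-mask spatial *mean* of squared HbO$_2$
   contrast exceeds 1 are dropped and recorded. The mean (not the raw sum)
   makes the threshold comparable across masks of different sizes;
   censoring is idempotent. Runs from one individual are concatenated
   (`concatenate_runs()`) with censored indices re-offset.

## Parcellation

`pixel_correlation_matrix()` builds the Pearson matrix over in-mask
pixels. `svd_initial_parcels()` takes the leading
$\lceil n_{parcels}/2 \rceil$ singular vectors (15 for the standard 30
parcels); each vector seeds a positive and a negative candidate parcel and
every pixel joins the candidate with its largest signed loading. Loadings
are compared *unweighted*: the unit-norm vectors make them commensurable,
whereas weighting by the singular values lets the two or three leading
global patterns absorb nearly every pixel and collapses the seeding (the
weighted variant remains available as `weight = "singular"`).

`iterate_parcels()` then alternates parcel-mean traces, pixel–parcel
correlations and argmax reassignment until a fixed point. Ties keep the
current parcel, else the lowest parcel id; emptied parcels are dropped
between passes; a recurring non-fixed state (oscillation) terminates with
`converged = FALSE` and a warning — the iteration has no general
convergence guarantee, though all benchmark runs converge. A converged map
satisfies the per-pixel argmax audit exactly
(`audit_parcel_fixed_point()`), and on ≤ 50-pixel instances the
implementation matches a from-scratch loop reference exactly.

**Vein exclusion.** The midline venous sinus carries a strong vascular
signal. After a first full-field pass, parcels concentrated in the midline
band are flagged and their pixels excluded before the second, definitive
pass. The flag requires both the parcel centroid inside the band *and* at
least half its pixels there: a centroid-only rule misflags bilaterally
symmetric parcels, whose centroid also sits on the midline although their
pixels do not. A manual parcel-id override is available.

**Cluster cutting.** Parcels are grouped by average-linkage hierarchical
clustering on $1 - r$ of their mean traces and cut at the largest merge
height whose partition has at least 8 clusters (the shallowest qualifying
level; cuts are nested, so raising the minimum only refines the
partition). Average linkage on correlation distance matches grouping by
"average trace similarity"; other linkages can be passed through.

**Hemisphere division.** Strong homotopic coupling can produce parcels and
clusters spanning both hemispheres. `split_clusters_by_hemisphere()`
assigns each parcel its majority hemisphere (exact ties go left, with a
warning) and derives a canonical, geometry-only ordering — left block
first, clusters by mean anterior–posterior centroid, parcels by centroid
within cluster — so the ordering is invariant to input parcel numbering.
`hemi_cluster_map()` additionally divides the *map* by hemisphere at pixel
level, which separates bilateral clusters into hemisphere-specific groups
even when single parcels straddle the midline; that pixel-level division
is what recovery scoring uses.

## Connectivity and statistics

Region/cluster traces are means over member-pixel HbO$_2$ traces (not
means of pairwise correlations), then correlated. Correlation matrices can
be reordered by hemisphere and cluster, with the within-left,
within-right, and cross-hemisphere quadrants addressable; the diagonal of
the cross quadrant holds the homotopic correlations. `extract_homotopic()`
splits unique region pairs into homotopic pairs and the remaining
non-homotopic pairs, the latter tagged as within- or cross-hemisphere.
Pooled bookkeeping over a cohort with heterogeneous window placements
counts one homotopic pair per bilaterally seen region name and the
within-hemisphere distinct-name pairs ($m(m-1)$ for $m$ names) as the
non-homotopic pool.

**Randomization tests.** Matrix dissimilarity is the mean absolute
difference over unique off-diagonal entries ("matrix delta") — absolute,
because a signed mean difference of correlations cancels.
`shuffle_matrix()` permutes the off-diagonal entries symmetrically,
preserving the value multiset, so the null destroys structure only. The
between-individual test compares the group-mean observed delta against a
null pooled over pairs, with *both* matrices of a pair shuffled per draw;
the ECDF quantile of the observed delta within the pooled null is the
reported probability. For a cohort of two (including the split-half test,
which applies the same machinery to the first and second halves of one
recording) the quantile is exactly calibrated under exchangeability; for
larger cohorts the group mean is less dispersed than the pooled marginal
null, so the test is *conservative* (measured rejection ≈ 1% at nominal
5% with three individuals) — an acceptable direction for a consistency
claim.

**Contrasts.** Correlation pools are screened with a one-sample KS test
against a standard normal after standardization (rank-based testing is
used regardless). The Wilcoxon rank-sum test reports the rank sum of the
first sample, a tie-corrected, continuity-corrected normal z, and a
two-sided p by full enumeration of rank arrangements when
$n_1 + n_2 \le 10$ (valid under ties via midranks) and by the normal
approximation otherwise; swapping samples negates z and preserves p.

## The synthetic-data generator

No public recordings of this kind are deposited, so validation rests on a
generator whose defaults define the package's benchmark conditions:

* **Geometry** — a 36×40 px field with 5 mirrored elliptical region pairs
  (10 regions, the number of anatomical regions expected in such a
  window), a 2-px midline vein stripe, and a brain mask equal to the union
  of regions and vein. The benchmark is run at this reduced scale, rather
  than the full 75×100 acquisition geometry, to keep the pixel-pixel
  correlation and SVD stages fast; all operations are
  resolution-independent.
* **Dynamics** — 4800 frames at 8 frames/s (two concatenated 5-minute
  runs). Latent region traces are filtered Gaussian noise band-limited to
  0.03–0.12 Hz (inside the analysis band, so the analysis filter is
  near-unity over their support). Homotopic pairs correlate at 0.6,
  within-hemisphere neighbours at 0.2, others at 0 — bracketing reported
  region-level homotopic strengths (~0.5–0.8) so that recovery is neither
  trivial nor impossible. The target correlation is imposed *exactly* at
  the realized sample size (empirical whitening, then coloring by a PSD
  square root of the target): band-limiting shrinks the effective sample
  size enough that approximate coloring would leave ±0.05 calibration
  marginal even at 4800 frames. All latent, nuisance and sub-component
  traces come from one block-diagonal draw, so nuisance components are
  exactly uncorrelated with the region latents.
* **Within-region structure** — two independent sub-component traces per
  region, weighted by smooth row/column gradients that are exactly
  zero-mean over the region (relative amplitude 0.4). Perfectly
  homogeneous regions would make bilaterally merged parcels a global
  attractor and collapse the 30 seeded parcels to one per region pair;
  real recordings show parcels persisting and varying within regions. The
  zero-mean weights leave region-mean traces untouched.
* **Optics and artifacts** — forward Beer–Lambert rendering with
  HbR = −0.7·HbO$_2$ plus noise (HbR realism is secondary since analysis
  uses HbO$_2$ only, but the coupling keeps the spectroscopy well posed);
  a smooth quadratic vignette; second-order multiplicative drift (1%/1.5%
  coefficients); per-hemisphere nuisance traces of the same amplitude as
  the signal; a strong independent vein trace (amplitude 3× signal);
  per-pixel Gaussian concentration noise with sd equal to the signal
  amplitude (0.3 µM) — chosen, in the absence of a published SNR estimate,
  so that recovery succeeds with roughly 2× margin, and documented as an
  assumption; and 16-bit quantization with clipping warnings. Quantization
  alone injects ~10⁻³ relative error, so the exact (10⁻⁸) forward/inverse
  consistency check runs with `bit_depth = NULL`.
* **Reproducibility** — identical seeds give bit-identical stacks; all
  internal draws derive deterministically from the scenario seed.

What passing the benchmark does *not* show about real data: the generator
has piecewise-constant region supports with clean gaps, Gaussian noise
without photon (shot) statistics, heart-beat or respiratory physiology, no
motion, and an exactly known homotopic pairing. Results on it validate the
algorithmic machinery, not biological effect sizes.

## Recovery accuracy and numerical choices

On benchmark conditions the hemisphere-divided cluster partition matches
the true regions at adjusted Rand index ≈ 1.0 (≥ 0.8 required; with noise
switched off the index is exactly 1), the vein stripe is fully excluded,
and recovered region-level homotopic correlations lie within ±0.1 of the
0.6 target. They sit systematically high (≈ 0.62–0.71): hemispheric-mean
regression removes a variance share common to all regions of a
hemisphere, which deflates denominators more than the homotopic
covariance. The same artifact drives the median non-homotopic correlation
to ≈ −0.17. Both effects are properties of the analysis (present in any
data processed this way), not of the generator.

Other numerical conventions: correlation matrices are computed by
standardized cross-products (BLAS) and clipped to [−1, 1]; zero-variance
traces are an error naming the offending units rather than silent NaNs; a
regressor with variance below 10⁻²⁰ of the data's mean square collapses to
mean removal with a warning; empirical whitening refuses noise
realizations whose covariance condition exceeds 10¹⁰ (short series cannot
support many latent columns — at the 0.09 Hz synthesis bandwidth the
effective dimension is roughly 0.0225·n frames); dendrogram cuts use the
largest qualifying merge height, with ties handled by scanning unique
heights. Problem sizes in the shipped tests (24×20 to 36×40 px, 300–4800
frames) were chosen as the smallest instances that still exercise every
failure mode found during development.
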