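---
title: "Quantifying elastic wing deformation and wing-shape evolution"
author: "scarabwing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elastic wing deformation and wing-shape evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarabwing)
```

## The scientific problem

Insect wings have no intrinsic musculature: their shape in flight is set by
the wing-vein skeleton and by elastic deformation under inertial and
aerodynamic loads. Scarab beetles are a natural system for asking how
evolutionary rearrangement of wing veins changes that elastic behaviour —
hovering flower chafers and fast-cruising dung beetles flap similar wings at
similar frequencies, yet deform them very differently. `scarabwing`
implements the full measurement chain needed to study this quantitatively:

1. **Free-flight deformation.** From 3D trajectories of three thorax points
   and seven wing landmarks, reconstruct the body frame, the three wing
   angles (flapping, deviation, incidence), and the signed, normalized
   deflection of four trailing-edge landmarks (RP, MP, CuA, AA) relative to
   the rigid leading-edge plane; summarize deflections at mid-stroke and
   relate them to the vertical force requirement through a power-law
   allometry.
2. **Static bending.** Invert point-load cantilever measurements into
   flexural stiffness via $\beta = F l^3 / (k\,EI)$ and compute
   dorsal–ventral and wing-support contrasts.
3. **Morphometrics.** Generalized Procrustes alignment of 25-landmark wing
   configurations, shape PCA with per-landmark variance contributions,
   thin-plate-spline warps between mean shapes, and phylogenetically
   corrected PCA under a Brownian-motion model.

Because raw flight films and specimens are not redistributable, every stage
is exercised against seeded synthetic generators with known ground truth;
all quantitative claims made by the test suite are claims about this
synthetic system.

## Angle conventions

The paper literature defers wing-angle definitions to camera-calibration
pipelines; this package fixes one convention and uses it consistently in
both the generator and the estimator:

* the **body frame** comes from three thorax points: longitudinal axis from
  point 1 to point 2, dorsoventral axis normal to the thorax triangle,
  lateral axis completing a right-handed triad;
* the **stroke plane** is inclined by $\gamma$ about the body's lateral
  axis; when unknown it is estimated as the total-least-squares plane of
  the wing-tip path in body coordinates (smallest principal axis of the
  centred path), which is rotation-equivariant and parameter-free;
* **flapping** is the azimuth of the wing base→tip axis within the stroke
  plane, **deviation** its elevation out of that plane, and **incidence**
  the rotation of the leading-edge plane about the span axis measured
  against the stroke plane.

Since estimation happens entirely in body coordinates, every output is
exactly invariant under rigid motions of the world frame (tested to
1e-8 degrees).

## The flight simulator and its design constants

`simulate_flight()` is a forward model of the videography measurement, not
of aerodynamics. Its defaults are the study conditions of the motivating
system: wing length 20 mm (observed range 14–25 mm), wingbeat 118 Hz,
stroke amplitude 120° peak-to-peak, stroke plane 34°, three flapping
cycles, body mass 0.5 g (observed range 0.198–0.908 g). The commanded
trailing-edge deflection follows $A_i\,|\sin(2\pi f t)|$ — zero at stroke
reversals, maximal at mid-stroke — directed along the leading-edge-plane
normal oriented toward the instantaneous wing motion (the pressure side),
which is the simplest profile consistent with the observed cyclical
deflection pattern. Incidence defaults to $45^\circ \sin(2\pi\,\text{phase})$,
an idealized symmetric pitching profile.

Two generator constants deserve explanation because they were chosen from
an explicit error analysis, not tuned to data:

* **Sampling at 40 samples per cycle, phase-locked.** The default frame
  rate is $40f$, so frames fall exactly on stroke reversals and
  mid-strokes. Mid-stroke deflection is read off by linear interpolation at
  the flapping-angle midpoint crossing; with generic sampling, the
  interpolation of the deflection *peak* carries an
  $O((f/\text{frame rate})^2)$ bias (about $10^{-4}$ of the amplitude at
  realistic rates), whereas phase-locked sampling makes the noise-free
  round trip exact to machine precision. Real high-speed cameras are not
  phase-locked; users emulating that simply pass any other `frame_rate`,
  and recovery is then accurate to the interpolation bias rather than
  exact.
* **Landmark layout.** The marginal joint sits at $(0.55, -0.22)R$ relative
  to the base–tip axis and the trailing-edge landmarks at chord depths
  0.14–0.28 $R$. The deflection of a trailing-edge point against a plane
  fitted through three noisy points amplifies coordinate noise by
  $\sqrt{1 + \sum_j \lambda_j^2}$, where $\lambda_j$ are the barycentric
  coordinates of the point in the leading-edge triangle. For this layout
  the worst factor (CuA) is about 2.3; averaged over the three cycles of a
  recording, the mid-stroke RMSE lands below $\sqrt{2}\,\sigma/R$, which is
  the accuracy budget the pipeline promises at $\sigma = 0.05$ mm
  digitization noise. A slimmer leading-edge triangle would break that
  budget; this is a property of the geometry, not of the estimator.

Noise is isotropic Gaussian per coordinate, applied after all geometry — a
deliberate simplification of real digitization error, which is
camera-geometry dependent and may be anisotropic and autocorrelated. Each
generator call consumes a private RNG stream seeded explicitly, restoring
the caller's RNG state, so identical seeds give bit-identical data.

## Reversal detection and mid-stroke extraction

Stroke reversals are alternating extrema of the flapping series, committed
with a hysteresis of 20% of the series range (so noise wiggles cannot
create spurious reversals) and refined to sub-frame resolution with a
parabola through the three surrounding samples. Extrema falling on the
first or last frame are refined through a shifted window and flagged: they
are kept for segmenting half-strokes but excluded from the wingbeat
frequency estimate, which they would bias through clamping. Frequency is
the number of full cycles over the elapsed time between the first and last
same-sense reversal; its resolution is limited by the frame interval and by
the number of recorded cycles.

A *half-stroke* runs between consecutive reversals; *mid-stroke* is where
the flapping angle crosses the midpoint of the two bounding refined
extremes (well-defined even for non-sinusoidal strokes, unlike a
peak-angular-velocity rule, which is offered conceptually but not needed
here). Per-landmark deflections are interpolated at that instant and
averaged over cycles, separately for down- (flapping decreasing) and
up-strokes. Near reversals the deflection magnitude vanishes and the
pressure-side orientation of the plane normal is briefly ambiguous (the
orientation is frozen from the previous frame when the trailing-edge
centroid speed drops below $10^{-6}R$ per frame); mid-stroke values are
unaffected, but users should not over-interpret deflection *signs* within
a few frames of a reversal.

## Static bending and allometry

`flexural_stiffness()` is the exact inversion $EI = F l^3/(k \beta)$ with
$k = 3$ (end-loaded uniform cantilever) by default; real wings are
non-uniform, so $k$ is exposed. Distances $l$ are supplied per measurement
point rather than hard-coded; for the leading-edge-supported (WBLE)
configuration the chord-wise distance from the support line is the
appropriate span. Forces below a configurable load-cell floor (default
$10^{-6}$ N) are flagged, never dropped. The dorsal−ventral and
WBLE−WB contrasts are simple per-point differences of cell means with
strict completeness checking; a distribution-free permutation test (add-one
corrected, two-sided) stands in for parametric group comparisons, which are
out of scope.

The deflection–force allometry $\beta = a F_v^{\,b}$ is fitted by ordinary
least squares on $\ln \beta$ vs $\ln F_v$, with a t-based 95% interval on
the exponent (the original CI method being unstated, this is the
conventional choice). Coverage is verified by simulation at the fitted
study values $a = 0.038$, $b = 0.43$.

## Morphometric choices

* **Full GPA** with translation removal, unit-centroid-size scaling and
  rotation-only (no reflection) fitting to an iteratively refined mean;
  convergence at $10^{-10}$.
* **Canonical orientation.** Plain GPA output is only defined up to a
  global rotation inherited from the initializer. After convergence the
  whole set is rotated so the mean shape's principal axes align with the
  coordinate axes, with the sign fixed by the third moment of the
  coordinates. This makes the aligned coordinates a deterministic function
  of shape alone — strictly invariant to the pose, scale and ordering of
  the input configurations.
* **Covariance PCA** of the aligned coordinates without tangent-space
  projection: all coordinates share units after scaling and shape
  variation here is small, making the projection correction negligible.
  Eigenvector signs are fixed by making each vector's largest-magnitude
  element positive. Per-landmark contributions to a component are the
  squared loadings summed over x and y, as percentages of the squared
  loading norm — a documented decomposition choice.
* **Thin-plate splines** use the standard kernel $U(r) = r^2 \ln r$ with
  affine side conditions; exact interpolation and zero bending energy for
  affine maps are tested properties, and the bending energy
  $\mathrm{tr}(W^\top K W)$ is clamped at zero against roundoff.

## Phylogenetically corrected PCA

`phylo_pca()` follows the standard Brownian-motion GLS construction in
covariance mode: tree covariance $C_{ij}$ = shared root-to-MRCA path
length, GLS root state
$a = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} X$, evolutionary covariance
$R = (X-1a)^\top C^{-1} (X-1a)/(n-1)$, eigen-decomposition of $R$, and
scores as the untransformed projection of the GLS-centred data. $C$ is
inverted through a Cholesky factor; a singular $C$ (duplicate zero-length
tips) raises an informative error rather than being silently
pseudo-inverted. Two analytic anchors pin the implementation: on a star
phylogeny with equal branch lengths it reduces *exactly* to ordinary PCA of
the species means, and rescaling all branch lengths by $s$ multiplies
eigenvalues by $1/s$ while leaving directions and scores fixed. The
installed reference implementation (`phytools::phyl.pca`) serves as an
independent cross-check in the test suite, never as the implementation.

A representational subtlety: in the `phylo` tree structure a rooted star
phylogeny is indistinguishable from an "unrooted" basal polytomy, so the
package treats the stored root as the root rather than rejecting
polytomous roots — the star tree is the method's own oracle. Missing or
negative branch lengths and duplicated tip labels are rejected.

Species means enter phylo-PCA as arithmetic means of GPA-aligned
coordinates per species — consistent with analysing species mean shapes
while leaving within-species variation to the ordinary PCA.

### Clade offsets versus phylogenetic correction

The radiation generator can superimpose a fixed displacement on all tips of
a clade. Such a signal is *maximally* phylogenetically structured, so the
phylogeny-corrected axes largely absorb it — that is the method working as
intended, not failing. The "two seeded landmarks dominate the leading
component" recovery property therefore belongs to the *uncorrected* shape
PCA, while phylo-PCA recovery is tested with what it is built to detect: a
rank-one elevation of the evolutionary *rate* along a known trait
direction, whose leading eigenvector it recovers (median cosine > 0.95 at
100 tips).

## Wing-planform geometry

Span $b$ is the outline's extent along the declared span axis (base-to-tip
convention), area $S$ the shoelace polygon area, aspect ratio $AR = b^2/S$.
The non-dimensional radius of the second moment of area is
$\hat r_2 = \sqrt{\smash{\sum_i c(r_i) r_i^2 \Delta r} / (S b^2)}$ with
midpoint-rule strips measured from the wing base (500 strips by default —
well past the 0.1% accuracy of the closed-form anchors $1/\sqrt3$ for a
rectangle and $1/\sqrt6$ for a linear taper). Both the dimensional $S_2$
and $\hat r_2$ are reported, since normalization conventions differ across
the literature.

## Synthetic-data scope: what passing tests do and do not show

The generators emulate the *measurement geometry* of the three
experiments: rigid leading-edge motion with commanded elastic deflection
and Gaussian digitization noise; Brownian shape evolution with optional
clade displacement and per-specimen digitization scatter; closed-form
cantilever forces with log-normal transducer noise. They deliberately do
**not** emulate aeroelastic coupling (deflection is commanded, not a
response to loads), camera-model distortions, non-Gaussian or correlated
digitization error, wing-wear or bilateral asymmetry, or selection-driven
(non-Brownian) shape evolution. Green tests therefore certify that the
*analysis chain* is correct and well-conditioned at realistic noise
levels — they are not evidence about any real beetle.

## Problem sizes and numerical tolerances used by the test suite

Chosen as the smallest sizes at which the Monte-Carlo tolerances below are
comfortably resolved: 100-seed noise sweeps for the deflection RMSE budget;
500 replicates for the 3-tip Brownian covariance check (tolerance three
standard errors of a variance estimate); 500 simulations for the 93–97%
CI-coverage window; 100 radiations for the ≥95% landmark-localization
rate; 50 seeded end-to-end two-species runs (8 individuals per species,
999 permutations) for the compliance contrast. Exact claims use 1e-10 to
1e-12; linear-algebra identities 1e-8. Degenerate inputs (collinear
triads, coincident landmarks, zero-length branches, monotone angle series,
self-intersecting outlines) raise errors rather than producing numbers.

## Known limitations

* Angle recovery is exact only in the noise-free limit with either a
  planar tip path or a known stroke-plane angle; with deviation present and
  the stroke plane estimated, the total-least-squares plane is a
  first-order approximation.
* Frequency resolution is limited by cycle count (three cycles by
  default), so single-recording estimates carry ~1–2% scatter at
  0.05 mm noise.
* The advance ratio uses total flight speed (the horizontal/total choice
  being unstated in the source literature) and mean tip speed
  $2\Phi f R$.
* Mid-stroke values are averaged across the recorded cycles; recordings
  with strong cycle-to-cycle drift should be segmented first.
* TPS warps are interpolants: extrapolation far outside the landmark hull
  grows quadratically and should only be used for visualization.
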