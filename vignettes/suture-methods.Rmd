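---
title: "Methods: suture shape and complexity through ontogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suture shape and complexity through ontogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures it implements, the parameters that matter, the numerical choices
behind them, and what the synthetic test bed does and does not establish
about real data.

## The analysis problem

A suture's trace across the skull roof is an ordered curve. Comparing such
curves across specimens, species and developmental stages requires (i) making
the curves geometrically commensurable — superimposition and semilandmark
sliding; (ii) reducing them to the planar form that complexity metrics are
defined on; and (iii) statistics that respect the permutation structure of
high-dimensional shape data and, for species-level traits, phylogenetic
non-independence. The package implements this chain for three cranial vault
sutures (interfrontal, sagittal, coronal) with two developmental axes:
discrete age categories (foetal, infant, subadult, adult) and a continuous
proxy, relative age, defined as a specimen's skull centroid size as a
percentage of its species' reference adult (100 by construction for that
adult; values above 100 are legal, since an unusually large subadult can
exceed the sampled adult).

## Morphometry

**Missing landmarks.** Landmarks flagged with the 9999 sentinel are completed
by a 3D thin-plate spline (kernel U(r) = −r) fitted from a reference
configuration's observed-correspondents onto the specimen's observed
landmarks and evaluated at the reference's missing-correspondents. TPS
reproduces affine maps exactly, so similarity-transformed copies of the
reference are completed exactly; this is the property the unit tests pin.
The reference is the mean of complete conspecifics when at least three
exist, else the global complete-specimen mean — the conspecific mean
minimizes extrapolation. If *no* specimen is complete the reference falls
back to per-landmark observed means with a warning; this is coarser because
raw configurations share a frame only approximately, and estimation is
always performed before mirroring and superimposition.

**Mirroring.** Half-digitized configurations are reflected across the plane
through three midline landmarks. The three must be non-collinear; collinear
triples raise a degeneracy error rather than producing an arbitrary plane.

**GPA.** Superimposition is iterative: translate to zero centroid, scale to
unit centroid size, rotate by the orthogonal least-squares rotation onto the
running consensus, with reflections forbidden (determinant +1) because all
specimens share handedness after mirroring. Convergence is declared when the
consensus moves by less than `tol` (default 1e-9) in Frobenius norm. Only
the fixed (and mirrored) landmarks enter the fit; 1500 suture semilandmarks
per specimen would otherwise dominate the alignment of one skull region.
Each specimen's translation, scale and rotation is applied passively to its
curves, so semilandmarks end up expressed in the consensus frame. The
reported consensus is the arithmetic mean of the aligned configurations, so
the mean-deviation identity holds exactly.

**Sliding.** Interior semilandmarks are displaced along local tangent
directions (central differences of flanking points) to minimize thin-plate
bending energy against the per-suture consensus; endpoints stay fixed, and
the consensus is recomputed between iterations (default 3). The sliding
amounts solve a dense k×k linear system per curve and specimen — the
bending-energy quadratic restricted to the tangent subspace — with a small
relative ridge (1e-9) for conditioning. The criterion is bending energy
rather than Procrustes distance: it is the standard choice of the curve
semilandmark literature and has a closed-form solve. Non-convergence within
the iteration budget produces a warning carrying the residual relative
energy drop, not an error, since a slowly-improving slide is still a valid
configuration.

**Resampling.** Curves are resampled to 500 points equally spaced by arc
length along the piecewise-linear input, endpoints preserved exactly.
Resampling an already equally-spaced polyline is exactly idempotent; for
smooth curves re-resampling moves points by the chord-versus-arc
discrepancy, of order (κh)²/24 for curvature κ and spacing h. At 500 points
on gently curved sutures this is below 1e-5 of curve length, which is the
tolerance the property test uses; exact 1e-9-level idempotence is only
attainable on polylines whose vertices are already at equal chord spacing,
and the suite pins that case on straight segments.

## 2D projection

The aligned frame is taken as anatomical: x anteroposterior, y mediolateral,
z dorsoventral. Midline sutures drop z, retaining the horizontal-plane
course of the curve; a `drop_axis = "y"` option retains the lateral profile
instead, because the anatomical wording of "the plane the suture lies in" is
genuinely ambiguous between the two for a curve running along the skull
roof. The default is the horizontal plane, which carries the mediolateral
interdigitation signal.

The coronal suture occupies an oblique plane. Three skull-roof landmarks
(defaults 20, 23, 27) define it; substituting the z-coordinates of the
second and third with that of the first defines the pseudo-frontal target
plane, and θ is the angle between the two unit normals, with magnitude in
[0, π/2]. The printed procedure does not fix the sign of θ, so the package
resolves it operationally: the sign is chosen so that applying the x-axis
rotation reduces the z-spread of the defining triple. A single x-rotation
can only flatten planes whose normal lies in the y–z plane; for a general
oblique plane the residual z-spread after rotation is recorded as a
per-specimen diagnostic (`coronal_residual_z`) rather than treated as an
error, quantifying the approximation instead of hiding it. Degenerate
projected curves (collinear points) remain valid downstream — they are
maximally simple sutures.

## Complexity metrics

**FD (box count).** The curve is first rotated to a canonical pose — chord
along +x, principal axis as fallback for closed curves — then translated and
isotropically scaled into the unit square. Canonical pose matters: raw box
counting is not rotation-invariant, and the package's contract is exact
similarity invariance of both scores. Dyadic grids of size 2^−k for k = 2…8
are overlaid (seven scales; finer boxes are unresolved by 500-point curves),
segments are subdivided below half the smallest box so no crossing is
missed, and FD is the least-squares slope of log N against log 1/s. The
estimator sits in [1, 2] for planar curves up to noise; the suite pins 1.0
on segments, log 4/log 3 on a Koch polyline, and 2.0 on a boustrophedon
sweep.

**PSD (STFT).** The curve is scaled to unit chord and reduced to its signed
perpendicular deviation from the chord; the signal is interpolated to 512
samples and transformed with a Hann window of 128 samples at 50% overlap.
Coefficient magnitudes are squared per frequency, averaged across the local
transforms, and summed over harmonics. A straight suture scores exactly 0,
and doubling deviation amplitude multiplies the score by 4 (the transform is
linear; the score quadratic). Window, overlap and signal length are fixed,
documented defaults; absolute PSD values are comparable only within one
configuration, which is why the package reports them per configuration
rather than claiming a universal scale.

## Statistics

Shape responses are vectorized semilandmark configurations. ANOVA uses the
trace form of sums of squares with sequential (type-I) term entry and RRPP
p-values: for each term, residuals of the reduced model are permuted, the
statistic recomputed, and the observed permutation counted, giving
resolution 1/(n_perm+1) (default 1000 permutations, seed 42). Saturated
fits (numerically zero residual SS) give infinite F; permutations can
reproduce a group-preserving relabelling, so the saturated-effect p can
legitimately land at 2–3 times the resolution rather than exactly at it.
The phylogenetic MANOVA premultiplies response and design by the inverse
square root of the Brownian-motion tip covariance and reuses the same
engine; on an equal-branch star tree it reproduces the ordinary ANOVA
exactly, which the suite checks.

Disparity is Procrustes variance — mean squared distance to the group mean
(n-divisor, so duplicating a group leaves it unchanged) divided by the
semilandmark count — with pairwise differences tested by permutation of
group labels. Allometric adjustment defaults to regression residuals of
shape on log centroid size; division of coordinates by log size is provided
as a literal alternative mode for comparison with published tables.

Trajectories are per-species multivariate slopes of shape on log centroid
size, compared pairwise by angle and by absolute length difference, each
with RRPP p-values against the common-trajectory reduced model and
Bonferroni adjustment over pairs. The count of "significant pairs" defaults
to the union of angle- and length-significant pairs, with angle-only and
length-only available, because summaries of such counts in the literature
rarely state which statistic they aggregate.

## Phylogenetic comparative methods

Ancestral states under Brownian motion are the joint ML — equivalently GLS —
estimates: they minimize the sum over edges of squared parent-child
differences weighted by inverse branch length, which is a sparse linear
solve, deterministic, polytomy-safe, and identical to the optimum a
numerical ML search would find. The rate is the ML rate given those states.
Internal estimates are convex combinations of tip values (range-bounded),
and the whole estimate is shift- and scale-equivariant; both are tested, as
is agreement with an independent ML implementation. Clade-ancestor lookups
require monophyly and name intruding tips otherwise; both the root and any
clade node can be queried, since "the ancestral value" of a paraphyletic
remainder is not well defined. The simulation-based phylogenetic ANOVA
estimates the rate by REML from phylogenetically independent contrasts,
simulates the trait on the tree, and compares the observed one-way F to the
simulated distribution with the +1 convention.

## The synthetic study

The generator is the package's test bed and defines its study conditions:
22 species, four stages per species (foetal, infant, subadult, adult at 30,
55, 80, 100% of adult centroid size, with 6% lognormal jitter off-adult), a
unit-depth pure-birth tree whose root split defines monophyletic
marsupial/placental clades plus a monotreme-like outgroup, lognormal adult
sizes (median 10, sdlog 0.4), and a 69-landmark template skull with fixed
midline (1–3) and coronal-plane (20, 23, 27) landmarks, species-specific
shape offsets, and mild ontogenetic elongation. Suture curves are bowed
arcs with sinusoidal interdigitation, per-wave phase jitter (SD 0.3 rad),
small isotropic noise (8e-4 of curve length), and an endpoint-pinning
envelope. Default amplitudes and wave counts (interfrontal 0.030/9,
sagittal 0.045/13, coronal 0.065/18) encode the complexity ordering coronal
≥ sagittal ≥ interfrontal; age profiles encode the generative regimes —
monotone decline for the midline sutures, decline-then-adult-rise for the
coronal (a logistic bump centred at 92% adult size). The clade effect on
amplitude defaults to zero, so clade-level disparity tests are calibrated
against a true null. All randomness descends from one seed through a
documented key-splitting scheme, making any sub-artifact independently
reproducible.

What the generator does *not* emulate: anatomically realistic skull
geometry, fractal (multi-scale) interdigitation, suture fusion and
obliteration, digitization error correlated along curves, or unbalanced
museum sampling. Passing tests therefore demonstrate that the pipeline
recovers known signal of the modelled kinds at realistic magnitudes — not
that any particular biological result would replicate. The generated FD
range (roughly 1.05–1.4 at defaults) is narrower than values reported for
real sutures by some implementations, whose absolute scale depends on their
box-scale conventions; within one configuration only comparisons matter.

## Problem sizes and budgets

The default study is 88 specimens (22 species × 4 stages), 500
semilandmarks per suture, 1000 permutations, 3 sliding iterations — a full
run takes well under a minute on one core. The test suite uses smaller
configurations chosen for statistical sufficiency: 50–120-point curves for
morphometric unit tests, 500 null datasets for type-I calibration, 200
replicates for slope-recovery and null-uniformity checks, 100 for the
adult-rise power check, and a 50-curve amplitude grid through the full
morphometric chain for rank-correlation recovery.

## Known limitations

- The bending-energy solve is dense; curves much beyond ~2000 points per
  suture would need a low-rank or sparse treatment.
- The 2D projection assumes the GPA consensus frame is anatomically
  oriented; datasets digitized in arbitrary frames should be roughly
  pre-oriented (the generator guarantees this by construction).
- A single x-axis rotation cannot flatten a fully general oblique coronal
  plane; the residual z-spread diagnostic should be inspected when skull
  roofs are strongly twisted.
- PSD values are configuration-relative; comparisons across window settings
  are meaningless.
- The phylogenetic ANOVA assumes Brownian motion with a single rate; no OU
  or multi-rate models are provided.
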