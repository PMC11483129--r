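---
title: "Quantifying superficial white-matter U-fibers at controlled depth and relating them to tapping synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ufiber methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short-range association fibers (U-fibers) run tangentially just beneath the
cortical mantle, connecting adjacent gyri. Diffusion MRI fixel analysis can
resolve several fiber populations per voxel, each with a direction and an
apparent fiber density (AFD, the integral of the corresponding fiber
orientation distribution lobe). The difficulty is anatomical: at a given
point of superficial white matter, tangential U-fibers coexist with radial
long-range fibers entering or exiting the cortex, and "depth below the
cortex" is not a coordinate any scanner provides. This package implements a
complete, testable pipeline that

1. defines depth geometrically, by solving the Laplace equation between the
   ventricles and the gray/white boundary and following its gradient;
2. separates the U-fiber (tangential) from the long-range (parallel) AFD
   component at controlled depths below every surface vertex; and
3. relates the resulting density maps to sensorimotor synchronization
   behavior, with vertex-wise statistics under permutation cluster
   correction and a regularized canonical correlation analysis (rCCA).

Because real diffusion data cannot validate any of these steps in isolation,
the package ships a synthetic-data module that builds phantoms with known
geometry, plants two fiber systems with known depth profiles, simulates
tapping behavior from generative models with closed-form properties, and
plants a known inter-subject brain-behavior correlation. Every downstream
stage is tested against those ground truths.

# Laminar geometry

## Laplace field

`solve_laplace()` solves $\nabla^2 \varphi = 0$ over the white-matter mask
with Dirichlet values 0 on the gray/white boundary and 1 on the ventricle
surface, by red-black successive over-relaxation (default $\omega = 1.9$,
relative update tolerance $10^{-6}$, at most 10,000 sweeps). Which boundary
carries which value only fixes the sign of the gradient; the tracer follows
$+\nabla\varphi$, i.e. toward the ventricles.

Two boundary discretizations are provided. The mask-only `"voxel"` scheme
(gray/white boundary voxels fixed at 0; the ventricle mask dilated by one
voxel fixed at 1) needs nothing but the masks, but a staircase Dirichlet
layer is first-order accurate: on the concentric-sphere phantom at 1 mm
voxels its error against the closed form
$\varphi(r) = (1/r - 1/b)/(1/a - 1/b)$ is of order $10^{-1}$. The default
`"subvoxel"` scheme instead treats every white-matter voxel as unknown and
shortens stencil arms that cross the analytic boundary to the exact crossing
distance (Shortley-Weller). This is second-order: the measured maximum error
on the $a = 10$, $b = 20$ mm sphere at 1 mm voxels is about $7\times10^{-4}$,
and the mid-shell value reproduces $\varphi(15) = 1/3$ to three decimals.
The sub-voxel scheme is available because the phantom geometry is analytic;
for arbitrary masks the voxel scheme applies.

Isolated mask components touching no boundary are filled with the nearest
boundary value and reported with a warning. A grid with no interior unknowns
returns its boundary values unchanged and is flagged converged.

## Streamlines and depth sampling

`trace_streamlines()` seeds one trajectory at every surface vertex and
integrates the trilinearly interpolated, renormalized gradient with fixed
0.1 mm Euler steps, truncating at 5 mm of arc length; trajectories also stop
on entering the ventricle mask, on genuinely leaving the white-matter mask,
or when the interpolated gradient vanishes (stalled; a seed with no usable
gradient is nudged 0.05 mm inward along the vertex normal once). Euler at
0.1 mm is well inside the tolerance of the analytic oracles: on the sphere
phantom the first segments deviate from the vertex normals by under
5 degrees for more than 99% of vertices, trajectories stay within 0.03 mm of
their seed rays, and the point 1.5 mm along each trajectory sits at radius
18.5 +/- 0.1 mm. Near the voxelized outer boundary the containing-voxel test
alone would spuriously terminate seeds, so a point counts as inside while
its interpolation stencil retains white-matter support.

`depth_points()` interpolates the polylines at requested arc lengths
(default 0, 0.5, 1, 1.5, 2 mm below the boundary; 1.5 mm is the nominal
U-fiber depth); depths beyond a truncated trajectory return missing markers,
never errors. Tangents at a depth are central differences of the bracketing
polyline points.

# Fixels and the parallel/tangential split

`fixels_to_sh()` renders fixels as a fiber orientation distribution in the
real even spherical-harmonic basis (lmax 8, 45 coefficients): each fixel
contributes an axially symmetric Gaussian-in-angle lobe scaled so its
spherical integral equals the fixel's AFD, projected by quadrature on an
icosphere tessellation (order 4, 2562 directions, triangle-area weights).
The angular SD of the lobe defaults to 25 degrees: wide enough that the
truncated expansion stays non-negative (minimum rendered value above
$-10^{-6}$), narrow enough that two orthogonal planted lobes are recovered
within 5% after segmentation. Synthesis is exactly linear in the densities.

`segment_fod()` is a discrete watershed on the tessellation: local maxima
above 10% of the global maximum become candidate directions, every
tessellation point drains to its steepest-ascent peak, each catchment's
quadrature-weighted mass is its fixel's AFD, sub-threshold catchments fold
into the angularly nearest retained peak, and antipodal lobe pairs merge
into single axial fixels. By construction the fixel AFDs sum to the full
spherical integral ($\sqrt{4\pi}\,c_{00}$) to within $10^{-6}$. A constant
FOD (no directional structure) returns a single fixel carrying all mass.

`classify_afd()` splits density against the local streamline tangent:
$\mathrm{total} = \sum_i \mathrm{afd}_i$; the parallel component is the
density of the single fixel with the smallest axial angle to the tangent,
counted only below a 45 degree cutoff (otherwise no fixel is parallel and
par = 0); and $\mathrm{tan} = \mathrm{total} - \mathrm{par}$ identically.
The single-winner rule keeps the decomposition well defined when no fixel is
remotely parallel; the cutoff is a parameter because reasonable analysts
could always assign a parallel fixel instead. Classification is invariant to
axial sign flips and fixel order.

`sample_depth_profiles()` evaluates this split at every (vertex, depth)
sample using the fixel list of the containing voxel - fixel sets do not
interpolate meaningfully, so no interpolation is attempted. Per-depth vertex
maps are then smoothed on the mesh by `smooth_surface_metric()`, an iterated
neighbor-averaging heat-kernel approximation whose iteration count is
calibrated from the mean edge length so the impulse response has the
requested full width at half maximum (verified within 15% by brute-force
geodesic measurement); missing vertices are excluded from averages and stay
missing, and constant maps are preserved exactly. Smoothing is applied to
the final per-depth maps, after sampling.

# Tapping behavior

## Metrics

From each trial's stimulus and tap streams the package computes the four
standard synchronization-continuation metrics: mean absolute asynchrony
(phase accuracy; taps paired to the nearest stimulus within half a target
interval, earlier stimulus on ties, closest tap winning a contested
stimulus), constant error (mean produced interval minus target; period
accuracy), temporal variability (sample SD of produced intervals, $n-1$
denominator; period precision), and the lag-1 autocorrelation of the
produced-interval series (mean-subtracted biased estimator per trial,
averaged arithmetically across trials - no Fisher transform, as the series
are short and the convention is a plain average). A trial epoch is valid
when every produced interval deviates from the target by less than 30%
(synchronization) or 40% (continuation) of the target; summaries use valid
trials only and retain discard counts.

## Generative simulator

The set of phenomena to emulate - anticipatory (negative) mean
asynchronies, error correction visible as negative lag-1 autocorrelation,
poorer visual than auditory synchronization, and the central-tendency bias
with zero constant error at an indifference interval - determines the two
standard models used:

* synchronization: linear phase correction on the asynchronies,
  $A_{n+1} = (1-\alpha)A_n + T_n + M_{n+1} - M_n$, stable for
  $\alpha \in (0,2)$ (default 0.7), with timekeeper noise SD 20 ms and motor
  noise SD 10 ms;
* continuation: the two-level timekeeper/motor model
  $I_n = C_n + M_{n+1} - M_n$, which has closed-form lag-1 autocorrelation
  $-\sigma_M^2 / (\sigma_T^2 + 2\sigma_M^2)$ - the test oracles $-1/2$ at
  $\sigma_T = 0$ and $-1/3$ at $\sigma_T = \sigma_M$ follow - with the
  timekeeper mean regressed toward the indifference interval with weight 0.3,
  so the constant-error-versus-target line crosses zero exactly there.

Defaults: five targets 550-950 ms, six intervals per epoch, ten trials per
target, mean absolute asynchrony level 40 ms (auditory), indifference
interval 654 ms (empirical reports for auditory pacing place it in the
650-680 ms range; it is an explicit parameter, so either convention is one
argument away), and visual-mode multipliers of 1.5 on both the asynchrony
level and the noise SDs.

One subtlety: a subject's `asynchrony_scale` is defined as their mean
*absolute* asynchrony level. Because the asynchrony distribution folds at
zero, setting the signed mean to $-s$ would produce a mean absolute
asynchrony above $s$ and, worse, a nonlinear compression at low $s$ that
attenuates any planted inter-subject correlation. The simulator therefore
inverts the folded-normal mean of the stationary asynchrony distribution to
find the offset whose expected |asynchrony| equals the requested level; in
the noise-free limit this reduces to asynchronies exactly equal to the
negative level.

## Cohorts

`generate_cohort()` draws per-subject pairs (tangential amplitude,
asynchrony level) from a bivariate normal and orthogonalizes the second
coordinate so the empirical correlation equals the planted rho exactly.
Amplitudes have mean 1 and SD 0.2; asynchrony levels have mean 40 ms and SD
12 ms with a 22 ms floor (just above the simulator's noise floor, so every
planted level is realizable; the floor is skipped in the degenerate
|rho| = 1 case, which must stay exactly affine). The planted amplitude
scales the tangential profile inside one ROI's radial sector; ROI labels are
angular sectors shared between surface vertices and the voxels radially
beneath them.

`plant_fixel_field()` gives every white-matter voxel a radial fixel (flat
0.5 profile) and a tangential fixel (azimuthal direction of the local
spherical frame; Gaussian depth profile peaking at 0.4 at 1.5 mm with SD
0.6 mm), plus a seeded multiplicative log-normal jitter of 5% relative SD.
The jitter is part of the study conditions: without it every off-ROI vertex
would have zero across-subject variance, the vertex-wise correlation would
be undefined there, and the null calibrations would be degenerate; 5% is a
conservative stand-in for scan-rescan variability of density estimates.

# Statistics

## Vertex-wise model and cluster correction

`vertexwise_correlation()` fits, per vertex, the linear model
$\mathrm{AFD}_i = \beta_0 + \beta_1\,\mathrm{behavior}$ across subjects and
reports the Pearson correlation, its square, and the two-tailed p value from
$t = r\sqrt{df/(1-r^2)}$ with $df = n - 2$. `critical_r()` inverts that
transform; at df = 29 and two-tailed alpha = 0.05 it gives 0.355, the
conventional threshold for a 31-subject sample (note that 0.355 is the
alpha = 0.05 value; alpha = 0.02 would give 0.416).

Cluster-level inference is by permutation rather than random-field theory:
random-field corrections need smoothness estimation and Gaussianity, while
the maximum-cluster-extent permutation null (behavior vector permuted, full
map recomputed, supra-threshold vertices at p < 0.001 grouped into
edge-connected components) is exact under subject exchangeability and can be
calibrated on synthetic cohorts. Cluster p values are
$(1 + \#\{\text{null max} \ge \text{observed}\})/(1 + n_{perm})$, so they
live on $[1/(n_{perm}+1), 1]$ - significance at the 0.001 cluster level
therefore needs $n_{perm} \ge 1999$. The extent statistic (vertex count) is
used because cluster sizes are the quantity reported downstream.

Calibration on null cohorts (the acceptance suite) finds the vertex test
slightly conservative - an observed type-I fraction near 0.042 at nominal
0.05 - which traces to the non-Gaussian (log-normal, floored) generator
noise; the permutation cluster test needs no distributional assumption and
its family-wise rate stays below its level.

## Regularized CCA

`fit_rcca()` solves the first canonical pair with ridge-regularized
covariances $C_{xx} + \lambda_x I$, $C_{yy} + \lambda_y I$, via a symmetric
eigenproblem on the behavior side and the Woodbury identity on the vertex
side, so the cost stays $O(n^2 q)$ with thousands of vertex columns. The
sign convention (largest-magnitude behavioral weight positive) makes fits
deterministic. With $q \ge n$ and $\lambda_y = 0$ the in-sample canonical
correlation is identically 1, so "maximize the correlation of the variates"
is operationalized as the mean out-of-fold correlation of variates computed
with training-fold weights (`grid_search_lambdas()`, default 6 log-spaced
values per regularizer spanning $10^{-3}$ to $10^{2}$ after
standardization). `permutation_loading_cis()` builds 99% null intervals for
every loading by refitting under row permutations of Y (equivalent to
permuting either side under exchangeability); a variable is flagged when its
observed loading leaves its own interval, which calibrates to about a 1%
flag rate under independence.

# What the tests do and do not show

The phantoms are concentric spheres with optional low-order harmonic
"gyrification", chosen because the Laplace problem then has a closed-form
oracle; they have no realistic folding, no partial-volume gray matter, no
curvature-dependent fiber dispersion, and the fixel fields are noiseless
two-population constructions up to the planted jitter. The tapping simulator
reproduces the stated phenomena but not, e.g., drift or lapses. Passing
tests therefore demonstrate that the machinery - field, tracer,
decomposition, metrics, statistics - is internally correct and calibrated,
not that the pipeline's assumptions hold in measured diffusion data.

Problem sizes in the shipped tests are the package's choices for a
single-CPU run: order-2/order-3 icospheres (162/642 vertices), 1 mm voxels,
cohorts of 200 subjects for recovery and calibration, 199-1999 permutations
depending on the level being tested, and a 32-subject demonstration pipeline
(order-3 mesh) that completes in well under a minute. The demonstration
config applies a 4 mm smoothing kernel: the phantom's 20 mm outer radius is
roughly a third of a human hemisphere's, and 4 mm preserves the planted
ROI's spatial scale the way a 15 mm kernel does on a full-size cortex
(`smooth_surface_metric()` itself defaults to 15 mm for full-scale meshes).

Known limitations: the sub-voxel Laplace boundary requires the analytic
phantom geometry; the tangential fixel azimuth is a deterministic
convention (any tangential direction serves the par/tan split); rCCA models
only the first canonical pair; and the permutation cluster test, while
calibrated, is conservative at small n with a 0.001 forming threshold
(clusters simply do not form at n = 32 - the planted-effect recovery runs
use n = 200).
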