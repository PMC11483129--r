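# ufiber

Superficial white matter (SWM) is where short-range association fibers —
U-fibers, which run tangentially under the cortex and connect adjacent
gyri — cross the radial long-range fibers entering and exiting the cortical
mantle. `ufiber` quantifies the density of these two fiber systems at
controlled depths below the gray/white matter interface and relates the
tangential (U-fiber) density to sensorimotor synchronization behavior. It is
aimed at diffusion-MRI methods researchers who want a fully testable,
self-contained implementation of the laminar-sampling idea: every stage runs
on synthetic phantoms with known ground truth, so no imaging data are
required to exercise, validate, or extend the pipeline.

## The method

1. **Laminar geometry.** Solve the Laplace equation
   ∇²φ = 0 between the ventricles (φ = 1) and the gray/white boundary
   (φ = 0) over the white-matter mask, then seed one streamline per surface
   vertex and integrate the normalized gradient in 0.1 mm steps, truncated
   at 5 mm. Arc length along these trajectories *is* depth below the cortex;
   metrics are sampled at 0, 0.5, 1, 1.5 and 2 mm (1.5 mm is the nominal
   U-fiber depth).
2. **Fixel decomposition.** Per voxel, fiber populations ("fixels") carry an
   apparent fiber density (AFD), the spherical integral of their fiber
   orientation distribution lobe (even spherical harmonics, lmax 8,
   segmented by a watershed on a dense tessellation). Against the local
   streamline tangent the density splits as

       total_AFD = Σᵢ afdᵢ,   par_AFD = afd of the single fixel most
       parallel to the tangent (within 45°),   tan_AFD = total − par

   so `tan_AFD` — the U-fiber proxy — is defined by exact subtraction.
3. **Behavior.** Synchronization–continuation tapping is summarized per
   subject, modality and target interval by mean absolute asynchrony,
   constant error, temporal variability and lag-1 autocorrelation, after a
   30%/40% produced-interval validity filter. The built-in simulator uses
   linear phase correction plus the two-level timekeeper/motor model
   Iₙ = Cₙ + Mₙ₊₁ − Mₙ (closed-form lag-1 = −σ²_M/(σ²_T + 2σ²_M)).
4. **Anatomo-behavioral statistics.** Vertex-wise Pearson correlation
   (AFDᵢ = β₀ + β₁·behavior) with permutation max-cluster-extent correction
   on the mesh, ROI aggregation, and a regularized CCA (ridge on both
   covariances, Woodbury solver, regularizers chosen by cross-validated
   variate correlation, 99% permutation intervals on the loadings).

## Worked example

```r
library(ufiber)

ph <- make_phantom(outer_radius = 20, inner_radius = 10, voxel_size = 1, mesh_order = 3)
ph
#> phantom: 1 hemisphere(s), outer 20 mm / inner 10 mm, voxel 1 mm
#>   grid 45x45x45 | wm voxels 29202 | ventricle voxels 4169
#>   surface: 642 vertices, 1280 faces, 8 ROI labels

field <- solve_laplace(ph)
field
#> Laplace potential field: 29202 unknowns, 140 sweeps, residual 6.42e-07 (converged)

streams <- trace_streamlines(ph, gradient_field(field))
streams
#> 642 laminar streamlines, step 0.1 mm, truncation 5 mm
#> max_length
#>        642

subj   <- subject_spec(tan_amplitude = 1.4, asynchrony_scale = 35, seed = 7)
fixels <- plant_fixel_field(ph, subject = subj, roi_id = 3)
samples <- sample_depth_profiles(fixels, streams)
median(samples[, 4, "tan"])   # tangential AFD at 1.5 mm depth
#> [1] 0.379

session <- simulate_tapping_session(subj, "auditory", seed = 1)
summarize_subject(session)[, c("target_ms", "mean_abs_asynchrony",
                               "constant_error_cont", "lag1_autocorr")]
#>   target_ms mean_abs_asynchrony constant_error_cont lag1_autocorr
#> 1       550            38.05354          32.2636798    -0.4147973
#> 2       650            35.62179          -0.3747787    -0.3467546
#> 3       750            31.49001         -29.0943112    -0.2799233
#> 4       850            40.28858         -61.7597530    -0.3860602
#> 5       950            34.45869         -89.0164629    -0.2883884
```

Reading the output: every streamline reached the full 5 mm truncation; the
tangential AFD at 1.5 mm sits near the planted profile peak (0.4, here
scaled by the subject's amplitude inside ROI 3 and damped by voxel
averaging); asynchronies are negative-mean with magnitude near the subject's
35 ms level; the continuation constant error crosses zero near the 654 ms
indifference interval (over-production at 550 ms, under-production at
950 ms); and the lag-1 autocorrelations are negative, the signature of error
correction.

A full cohort analysis — phantom, cohort simulation, field, streamlines,
depth sampling with smoothing, behavioral summaries, vertex-wise cluster
statistics and rCCA, with all intermediates, a JSON manifest and a log
written to disk — is one call:

```r
run_pipeline(pipeline_config(), "out_demo")
```

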