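# ddtvpat

Model-based 2-D photoacoustic tomography (PAT) reconstruction in R, with a
directional total-variation prior whose directivity adapts to the image.

In PAT, pulsed-laser absorption launches ultrasound that is recorded by
detectors around the tissue; after time integration, each sample of the
measured signal is a circular mean of the absorption map `A`,

    g(r_l, t) = ∮_{|r − r_l| = ct} A(r) dr .

`ddtvpat` discretizes this model into a sparse system matrix `W` (triangular
arc interpolation across time bins) and reconstructs `A` from sparse-view,
limited-view or linear scans by solving

    A* = argmin_A ‖W A′ − g‖² + λ · DDTV(A) ,

where DDTV replaces the isotropic unit ball of the TV dual with per-pixel
ellipses: the major axis (length `α ∈ [1, α_m]`) follows the local texture
direction `θ`, estimated block-wise from gradient moments with doubled-angle
smoothing, and its length is set by the gradient coherence `C ∈ [0, 1]`:

    DDTV(A) = Σ_ij ‖ Λ_α R_θᵀ ∇A_ij ‖₂ ,   α_ij = (α_m − 1) C_ij + 1 .

With `α ≡ 1` the prior is exactly classical TV. The regularized problem is
solved by a projected-gradient iteration on the per-pixel dual field
(`‖Γ_ij‖ ≤ 1`, step `1/(8 α² λ²)`), interleaved with normalized data steps,
with the orientation field re-estimated at each of 10 outer iterations.
Classical TV and filtered back-projection (FBP) baselines, phantom
generators (Shepp–Logan, stripe and ring textures, gratings, disks), an
inverse-crime-free arc-quadrature signal simulator, calibrated Gaussian
noise, and PSNR / normalized-distance metrics are included.

## Worked example: a 30-view sparse scan

```r
library(ddtvpat)

grid    <- make_grid(128, 128, 76.8)        # 0.6 mm pixels
phantom <- shepp_logan(128)
geom    <- circular_scan(30, 36)            # 30 detectors, 36 mm radius
samp    <- sampling_for(geom, grid)         # c = 1500 m/s, one-pixel bins

g  <- simulate_spherical_means(phantom, geom, samp, grid, upsample = 8)
W  <- build_weight_matrix(geom, grid, samp)
cfg <- recon_config()                       # lambda = 0.01, alpha_max = 2.5

ddtv <- reconstruct_ddtv(g, W, cfg, reference = phantom)
tv   <- reconstruct_tv(g, W, cfg, reference = phantom)
fbp  <- reconstruct_fbp(differentiate_to_pressure(g), geom, grid, samp)

rbind(ddtv = metric_report(ddtv, phantom),
      tv   = metric_report(tv, phantom),
      fbp  = metric_report(fbp, phantom))
```

Output on this machine:

```
      psnr_db distance_d
ddtv 19.94039  0.4057081
tv   16.32052  0.6163130
fbp  14.67456  0.7432742
```

The directional prior buys about 3.6 dB over classical TV and 5.3 dB over
FBP at 30 views: with identical data, DDTV preserves the phantom's edges
that isotropic TV smears and that FBP buries in streak artifacts. The
per-iteration error distance `d = ‖A − r‖/‖r‖` is recorded in
`recon_trace(ddtv)$d` and decreases across the 10 iterations. Because the
detector signals are generated by continuum arc quadrature — deliberately
*not* by the reconstruction's own matrix — absolute PSNRs sit in the
sparse-data regime of honest simulation; see the methods vignette
(`vignettes/ddtv-pat-methods.Rmd`) for the discretization analysis behind
this and for every parameter default.

A full experiment (phantom → simulate → noise → all methods → metrics) is
one call:

```r
out <- run_experiment(experiment_spec(
  phantom  = list(type = "shepp_logan", n = 128),
  geometry = list(mode = "circular", n_views = 30, radius_mm = 36),
  noise    = list(snr_db = 10),
  seed     = 1L
))
out$metrics
```

A thin command-line front end with `phantom`, `simulate`, `reconstruct`,
`evaluate` and `run` subcommands lives at `inst/cli/ddtv-pat.R`.

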