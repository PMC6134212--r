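# plsbeam

Source localization for magnetoencephalography (MEG) with a minimum-variance
beamformer, optionally aided by supervised partial-least-squares (PLS)
denoising of the sensor array.

## What it does, and for whom

Localizing a focal cortical current source — an epileptiform spike, an
evoked transient — from a few hundred MEG channels is an ill-posed inverse
problem.  The linearly constrained minimum variance (LCMV) beamformer
resolves it by scanning a volumetric grid: at each candidate location `r`
with lead-field gain matrix `L(r)`, it forms the spatial filter

    W'(r) = [L' C⁻¹ L]⁻¹ L' C⁻¹        (unit gain:  W' L = I)

and evaluates the minimum output variance `tr{[L' C⁻¹ L]⁻¹}`; the map's
maximum (reported as the neural activity index, i.e. normalized by the
white-noise variance `tr{[L' L]⁻¹}`) is the estimated source.  LCMV is
noise-sensitive because `C` is estimated directly from the raw array.  The
PLS-aided variant (pLCMV) first partitions the sensors into eight anatomical
regions, builds a one-hot class matrix `Y`, extracts NIPALS-PLS components
maximizing the covariance between projections of the channels-by-time
matrix `X` and of `Y`, reconstructs a denoised `X̂` from those components,
and estimates `C` from `X̂` (diagonal loading handles the resulting low
rank).

The package is for methodologists who want a self-contained, tested
implementation of both estimators plus the simulation/evaluation scaffolding
around them: a deterministic 306-channel helmet builder, an analytic
conducting-sphere forward model with planar gradiometers, a sinc-dipole
simulator with a 12-level calibrated Gaussian noise ladder, and sweep
harnesses reporting localization error in mm.

## Worked example

```r
library(plsbeam)

sphere  <- head_sphere()                                  # 75 mm sphere, center (0, 0, 40) mm
helmet  <- build_helmet_array(102, sphere)                # 102 sites x {mag, grad1, grad2}
regions <- partition_regions(helmet)                      # eight-region PLS classes
grid    <- build_source_grid(sphere, spacing = 10, interior_margin = 10)
lead    <- compute_leadfield(grid, helmet, sphere, channels = "grads")

# simulate a 100 nAm tangential sinc dipole on a grid point, then add noise
truth <- grid$points[which.min(colSums((t(grid$points) - c(40, 20, 60))^2)), ]
spec  <- source_spec(truth, tangential_orientation(truth, sphere),
                     amplitude = 100, sphere = sphere)
clean <- project_dipole(spec, lead)
ds    <- add_noise(clean, sigma_for_snr(clean, 3), seed = 42)   # ~3 dB SNR

fit <- pls_lcmv_localize(ds$observed, regions, lead)
location_error(truth, fit$location)
```

Printed objects and results from this exact session:

```
<sensor_array> 102 sites, 306 channels (102 mag, 204 grad)
<region_partition> 306 channels in 8 regions
  frontal-L   frontal-R  temporal-L  temporal-R  parietal-L  parietal-R
         33          36          48          48          39          30
occipital-L occipital-R
         33          39
<source_grid> 1189 points, 10 mm spacing
truth: 40 20 60   snr: 2.979 dB
plcmv location: 40 20 60   K: 30   error: 0 mm
lcmv  location: 40 20 60   error: 0 mm
```

The realized SNR (2.979 dB) is the Frobenius-norm ratio of the clean and
noise matrices; `K = 30` is the number of PLS components extracted before
the residual-norm stopping rule's hard cap; both methods recover the exact
grid point here.  `six_source_experiment()` and
`subsampled_grid_experiment()` run the same cell over six benchmark
locations (deep and shallow) or every 12th grid point, across the full
noise ladder, and `compare_methods()` summarizes per-level mean errors with
paired bootstrap intervals.

A thin CLI over the same functions lives at `inst/cli/plsbeam.R`
(`simulate`, `localize`, `sweep` subcommands).

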