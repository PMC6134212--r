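---
title: "PLS-aided minimum-variance beamforming for MEG source localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-aided minimum-variance beamforming for MEG source localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Magnetoencephalography (MEG) records, outside the head, the femtotesla-scale
magnetic fields produced by synchronous cortical currents.  Estimating the
position of a focal generator — an epileptiform spike, an evoked response —
from the sensor array is an ill-posed inverse problem: a few hundred channels
against a continuum of possible current distributions.  Beamforming resolves
it pointwise: for every candidate location $r$ in a volumetric grid, a
spatial filter $W(r)$ is built that passes activity from $r$ with unit gain
while minimizing total output power, and the location where the filtered
output power peaks is taken as the source.

`plsbeam` implements the linearly constrained minimum variance (LCMV)
beamformer and a PLS-aided variant, pLCMV, in which the channels-by-time
data matrix is first denoised by supervised partial least squares against a
sensor-region class matrix.  The package also contains everything needed to
validate the two methods end to end: a deterministic helmet-array builder,
an analytic spherical forward model, a dipole simulator with a calibrated
noise ladder, and a sweep harness that measures localization error.

## The model

**Forward model.**  Data are modeled as $X = L D + \varepsilon$, with $X$
the $M \times N$ sensor matrix ($M$ channels, $N$ time samples), $L$ the
lead-field (gain) matrix of the active sources, $D$ their moment time
courses, and $\varepsilon$ sensor noise.  Lead fields come from the
classical closed-form solution for a current dipole in a homogeneous
conducting sphere, with volume currents included.  Planar gradiometers are
modeled as two-point finite differences of the normal field component along
a tangential 17 mm baseline, which reproduces their spatial high-pass
character.  Units are fixed throughout: positions in mm, moments in nAm,
fields in fT (fT/mm for gradiometers).

**Minimum-variance filter.**  For a location $r_0$ with gain matrix $L_0$,
the filter solves

$$\min_W \operatorname{tr}\{W^{\top} C W\} \quad \text{s.t.}\; W^{\top} L_0 = I,$$

with $C$ the channel covariance of the data, giving
$W^{\top} = (L_0^{\top} C^{-1} L_0)^{-1} L_0^{\top} C^{-1}$ and minimum
output variance $\operatorname{tr}\{(L_0^{\top} C^{-1} L_0)^{-1}\}$, the
source-strength value scanned over the grid.

**Rank-2 scanning.**  In a spherical conductor a radial dipole produces no
external magnetic field, so every $M \times 3$ gain block has rank 2 and the
$3 \times 3$ matrix $L_0^{\top} C^{-1} L_0$ is singular at every grid point.
The scan therefore runs on the two leading principal moment directions of
each block (precomputed when the lead field is assembled), exactly the
rank-reduction convention MEG analysis toolboxes apply for spherical and
quasi-spherical models.  The generic 3-column scan remains available
(`rank = 3`) for non-degenerate lead fields, and the unit-gain property is
tested in both forms.

**Depth normalization.**  The raw minimum variance grows without bound as
gains shrink with depth, so on noisy data its argmax sits at the deepest
grid point regardless of the source.  By default the map reports the neural
activity index — the output variance divided by its value under unit white
sensor noise, $\operatorname{tr}\{(L^{\top}C^{-1}L)^{-1}\} /
\operatorname{tr}\{(L^{\top}L)^{-1}\}$ — the normalization introduced with
the original LCMV formulation.  `normalize = "none"` gives the literal
variance map; its $c^2$ homogeneity in the data scale is kept under test.

**PLS denoising.**  pLCMV interposes a supervised denoising step.  Sensors
are partitioned into eight regions (frontal/temporal/parietal/occipital,
left/right); the $M \times 8$ one-hot class matrix $Y$ encodes membership.
Both $X$ and $Y$ are column-standardized, and two-block NIPALS PLS extracts
weight/score/loading sets $(w_k, t_k, p_k)$ maximizing the squared
covariance between $Xw$ and $Yv$, deflating both blocks after each
component.  The reconstruction $\hat X = T P^{\top}$, de-standardized back
to field units, keeps the covariance structure that is consistent with the
regional organization of the array and sheds unstructured noise; its
covariance replaces $C$ in the filter.

## Numerical choices

- **Inner PLS solver.**  The per-component maximizer is the leading
  singular pair of the deflated $X^{\top}Y$.  The classical alternating
  power iteration stalls when the leading covariance directions are nearly
  tied (its rate is the squared singular-value ratio), which happens
  routinely on noise-dominated data, so the default solver computes the
  fixed point exactly from the eigendecomposition of the $8 \times 8$
  matrix $(X^{\top}Y)^{\top}(X^{\top}Y)$.  The classical iteration is kept
  as `inner = "power"` (with a 500-iteration cap and an error on
  non-convergence) and doubles as an independent cross-check in the tests.
- **Stopping rule.**  Extraction stops when the spectral norm of the
  deflated $X$ falls below 5% of its initial value, or at
  $K = \min(M, N, 30)$ components.  Residual norms are tracked exactly:
  deflation is rank-one, so the $M \times M$ Gram matrix is maintained by
  rank-2 updates and its top eigenvalue read off per step.
- **Sign convention.**  Each $w_k$ is flipped so its largest-magnitude
  entry is positive, making the fit fully deterministic.
- **Diagonal loading.**  $\hat X$ has rank at most $K + 1 \ll M$, so its
  covariance is singular; the filter uses
  $(C + \lambda \operatorname{tr}(C)/M \cdot I)^{-1}$ with
  $\lambda = 10^{-4}$ by default (config-exposed).  The loaded inverse of
  the low-rank covariance is applied through the Woodbury identity, so a
  pLCMV scan costs $O(MK)$ per grid point instead of $O(M^2)$; tests pin
  the fast route to the dense one at $3 \times 10^{-13}$.
- **Degenerate grid points.**  Points whose reduced Gram matrix is
  numerically singular (the sphere center is magnetically silent) are
  marked missing and excluded from the argmax rather than failing the scan.
- **Tie-breaks.**  The argmax takes the lowest grid index on exact ties;
  region assignment sends boundary sites to the anterior/left side.

## The synthetic data generator

The simulator emulates the acquisition setting the methods are meant for:

- a 306-channel helmet of 102 triplet sites (one magnetometer, two
  orthogonal planar gradiometers), sites placed deterministically by a
  Fibonacci lattice on a spherical cap extending 30° below the equator of a
  sphere 20 mm outside the scalp sphere (center (0, 0, 40) mm, radius
  75 mm, a typical adult head);
- localization uses the 204 planar gradiometers, the channel set named for
  that purpose in the protocol this package follows; the 306-channel and
  magnetometer-only selections are config switches;
- a source grid of 10 mm spacing clipped 10 mm inside the sphere
  (≈1,150 points), the desk-scale analogue of a 3,704-point
  millimeter-resolution patient grid;
- a sinc moment waveform $s(t) = \sin(\pi(t+\tau))/(\pi(t+\tau))$, 600
  samples at 1,000 Hz, time axis scaled so the main lobe spans ~100 ms —
  the shape of an epileptiform transient; $\tau = 0$ by default;
- a tangential dipole of 100 nAm placed exactly on a grid point (off-grid
  placement is supported for robustness experiments);
- 12 Gaussian noise levels, geometric in $\sigma$, calibrated analytically
  (via $E\|B\|_F^2 = MN\sigma^2$ in
  $\mathrm{SNR_{dB}} = 10\log_{10}(\|A\|_F^2/\|B\|_F^2)$) so the expected
  SNR runs from 6.990 dB at level 1 to 0.043 dB at level 12; 50
  realizations per level, shared across methods at each cell (a paired
  design).

What the generator deliberately does not emulate: physiological noise
(cardiac, ocular, muscular), spatially correlated sensor noise, realistic
skull/CSF conduction, multi-source activity, or real spike morphology
variability.  Passing the sweep therefore shows correctness of the
machinery and the methods' relative ordering under i.i.d. Gaussian noise on
a spherical conductor — not clinical-grade accuracy figures.  Under these
idealized conditions both beamformers localize grid-point sources
essentially exactly across the whole ladder; the comparison harness
reports per-level means, paired bootstrap intervals, and trend tests so
that harder conditions (deeper sources, fewer samples, correlated noise)
can be explored by changing the configuration, not the code.

## Experiment harness

`run_noise_sweep()` is a pure function of its configuration (all seeds
derive from `seed`); `six_source_experiment()` runs the six benchmark
locations spanning deep and shallow cortex — given in another head's
coordinates and snapped to the nearest grid point, with the snap distance
recorded — and `subsampled_grid_experiment()` covers every 12th grid point.
Problem sizes default to the desk scale above: the full six-source ladder
(6 sources × 12 levels × 50 repetitions × 2 methods) runs in roughly ten
minutes on one core; the acceptance script uses 15 repetitions per level to
keep a complete reproduction under five minutes.

## Known limitations

- The spherical forward model and geometric region partition are stand-ins
  for subject anatomy; absolute error magnitudes do not transfer to
  realistic head models.
- Only single-source argmax localization is provided; multi-source scenes
  need thresholded-map post-processing outside the package.
- The mapping of region labels to helmet sites is geometric, not the
  manufacturer's channel grouping; the class matrix machinery accepts any
  alternative labeling.
- The PLS response-weight matrix follows the extraction/reconstruction use
  of PLS; regression-mode prediction of $Y$ is out of scope.
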