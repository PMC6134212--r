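#' Sinc source waveform
#'
#' The moment time course used for simulated focal activity:
#' `s(t) = sin(pi (t + tau)) / (pi (t + tau))` on a centered, scaled time
#' axis `t_i = (i - N/2) / fs * time_scale` (i = 0..N-1, dimensionless after
#' scaling).  The removable singularity at `t + tau = 0` evaluates to exactly
#' 1.  The default `time_scale = 20` makes the main lobe span about 100 ms of
#' a 600 ms window at 1000 Hz, the shape of an epileptiform transient.
#'
#' @param n_samples Number of samples N (default 600).
#' @param fs Sampling rate, Hz (default 1000).
#' @param tau Translation of the sinc peak, in scaled time units.
#' @param time_scale Dimensionless stretch applied to the time axis.
#' @return Numeric vector of length `n_samples`.
#' @examples
#' s <- sinc_waveform()
#' max(s)  # 1 at the center sample
#' @export
sinc_waveform <- function(n_samples = 600, fs = 1000, tau = 0, time_scale = 20) {
  if (n_samples < 1 || fs <= 0) stop("need n_samples >= 1 and fs > 0")
  t <- (seq_len(n_samples) - 1 - n_samples / 2) / fs * time_scale
  u <- t + tau
  out <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  as.numeric(out)
}

#' Dipole source specification
#'
#' @param location 3-vector, mm (inside the head sphere).
#' @param orientation 3-vector; normalized internally.
#' @param amplitude Peak moment, nAm.
#' @param waveform Moment time course (default [sinc_waveform()]).
#' @param sphere Head sphere for the containment check.
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(location, orientation = c(0, 1, 0), amplitude = 100,
                        waveform = sinc_waveform(), sphere = NULL) {
  orientation <- orientation / sqrt(sum(orientation^2))
  if (!is.null(sphere) &&
      sqrt(sum((location - sphere$center)^2)) >= sphere$radius)
    stop("source location lies outside the head sphere")
  structure(list(location = as.numeric(location), orientation = orientation,
                 amplitude = amplitude, waveform = as.numeric(waveform)),
            class = "source_spec")
}

#' Tangential unit orientation at a location
#'
#' MEG is blind to radial dipoles in a sphere; the default simulated source
#' is therefore tangential.  Returns a deterministic unit vector orthogonal
#' to the radial direction at `location`.
#'
#' @param location 3-vector, mm.
#' @param sphere A [head_sphere()].
#' @return Unit 3-vector.
#' @export
tangential_orientation <- function(location, sphere) {
  r <- location - sphere$center
  rn <- sqrt(sum(r^2))
  if (rn < 1e-9) return(c(0, 1, 0))   # center: any direction is tangential
  tangent_frame(r / rn)$e1
}

#' Project a dipole source through the lead field
#'
#' Clean sensor data `A = L(gamma) (amplitude * orientation) s'`, a rank-1
#' channels-by-time matrix.  The source location is snapped to the nearest
#' grid point (the default simulation protocol places sources exactly on
#' grid points).
#'
#' @param spec A [source_spec()].
#' @param lead A [compute_leadfield()] result.
#' @param snap_warn_mm Warn if the snap moved the source by more than this.
#' @return M x N clean data matrix; attributes `"grid_index"` and
#'   `"snap_mm"` record the snapped point and distance.
#' @export
project_dipole <- function(spec, lead, snap_warn_mm = Inf) {
  d2 <- colSums((t(lead$grid$points) - spec$location)^2)
  gi <- which.min(d2)
  snap <- sqrt(d2[gi])
  if (snap > snap_warn_mm)
    warning(sprintf("source snapped %.1f mm to grid point %d", snap, gi))
  L <- leadfield_at(lead, gi)
  m <- spec$amplitude * spec$orientation
  A <- (L %*% m) %*% t(spec$waveform)
  attr(A, "grid_index") <- gi
  attr(A, "snap_mm") <- snap
  A
}

#' Add seeded Gaussian sensor noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every entry of the clean matrix and
#' records the realized signal-to-noise ratio
#' `SNR_dB = 10 log10(||A||_F^2 / ||B||_F^2)`.
#'
#' @param clean M x N clean data matrix A.
#' @param sigma Noise standard deviation, same units as `clean`.
#' @param seed Integer RNG seed for this realization.
#' @return Object of class `sim_dataset`: `clean`, `noise`, `observed`
#'   (= clean + noise, exactly), `snr_db`, `sigma`, `seed`.
#' @export
add_noise <- function(clean, sigma, seed) {
  if (sigma <= 0) stop("'sigma' must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  B <- matrix(stats::rnorm(length(clean), sd = sigma), nrow(clean), ncol(clean))
  structure(list(clean = clean, noise = B, observed = clean + B,
                 snr_db = snr_db(clean, B), sigma = sigma, seed = seed),
            class = "sim_dataset")
}

#' Signal-to-noise ratio of a signal/noise pair, in dB
#' @param A Clean signal matrix.
#' @param B Noise matrix.
#' @return `10 log10(||A||_F^2 / ||B||_F^2)`.
#' @export
snr_db <- function(A, B) 10 * log10(sum(A^2) / sum(B^2))

#' Noise standard deviation achieving a target expected SNR
#'
#' Inverts the SNR definition in expectation: i.i.d. noise of standard
#' deviation sigma has `E||B||_F^2 = M N sigma^2`, so the sigma whose
#' expected SNR is `target_db` is `||A||_F / sqrt(M N) * 10^(-target_db/20)`.
#'
#' @param clean Clean data matrix A.
#' @param target_db Target mean SNR, dB.
#' @return Scalar sigma.
#' @export
sigma_for_snr <- function(clean, target_db) {
  sqrt(sum(clean^2) / length(clean)) * 10^(-target_db / 20)
}

#' Calibrated Gaussian noise ladder
#'
#' Generates `n_levels` noise intensities from weak to strong, geometric in
#' sigma, calibrated so the expected SNR runs from `snr_top_db` at level 1
#' down to `snr_bottom_db` at the last level (defaults 6.990 and 0.043 dB,
#' the mean-SNR span of the 12-level protocol).  Each level draws `n_reps`
#' independent seeded realizations.
#'
#' @param clean Clean data matrix A.
#' @param n_levels Number of noise levels (>= 2, default 12).
#' @param n_reps Realizations per level (default 50).
#' @param seed Base seed; realization (level, rep) uses
#'   `seed + 1000 * level + rep`.
#' @param snr_top_db,snr_bottom_db Calibration endpoints, dB.
#' @param keep_data Keep every `sim_dataset` (memory heavy); otherwise only
#'   SNRs and sigmas are returned.
#' @return List with `sigmas` (per level), `snr_mean` (per-level mean
#'   realized SNR, dB), `snr_db` (n_levels x n_reps matrix), `datasets`
#'   (list of lists, if `keep_data`), `n_levels`, `n_reps`, `seed`.
#' @export
noise_ladder <- function(clean, n_levels = 12, n_reps = 50, seed = 1,
                         snr_top_db = 6.990, snr_bottom_db = 0.043,
                         keep_data = FALSE) {
  if (n_levels < 2) stop("'n_levels' must be >= 2")
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  s1 <- sigma_for_snr(clean, snr_top_db)
  sL <- sigma_for_snr(clean, snr_bottom_db)
  sigmas <- s1 * (sL / s1)^((seq_len(n_levels) - 1) / (n_levels - 1))
  snr <- matrix(NA_real_, n_levels, n_reps)
  datasets <- if (keep_data) vector("list", n_levels) else NULL
  for (l in seq_len(n_levels)) {
    if (keep_data) datasets[[l]] <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      ds <- add_noise(clean, sigmas[l], seed + 1000L * l + r)
      snr[l, r] <- ds$snr_db
      if (keep_data) datasets[[l]][[r]] <- ds
    }
  }
  list(sigmas = sigmas, snr_mean = rowMeans(snr), snr_db = snr,
       datasets = datasets, n_levels = n_levels, n_reps = n_reps, seed = seed)
}

#' Write a simulated dataset to a directory (CSV matrices + JSON-less manifest)
#'
#' Writes `observed.csv`, `clean.csv`, `noise.csv` and a plain-text
#' `manifest.dcf` (DCF key-value) with the ground truth.
#'
#' @param ds A `sim_dataset`.
#' @param spec The generating [source_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ds$observed, file.path(dir, "observed.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$clean, file.path(dir, "clean.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$noise, file.path(dir, "noise.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  man <- data.frame(
    location = paste(spec$location, collapse = " "),
    orientation = paste(signif(spec$orientation, 10), collapse = " "),
    amplitude = spec$amplitude,
    sigma = ds$sigma, seed = ds$seed, snr_db = ds$snr_db)
  write.dcf(man, file.path(dir, "manifest.dcf"))
  invisible(dir)
}
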