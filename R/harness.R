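#' Euclidean location error
#'
#' Distance in mm between the true and estimated source positions; smaller is
#' more accurate.
#'
#' @param true,est 3-vectors, mm.
#' @return Non-negative scalar, mm.
#' @examples
#' location_error(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
location_error <- function(true, est) {
  stopifnot(is.finite(true), is.finite(est))
  sqrt(sum((true - est)^2))
}

#' Experiment configuration for location-error sweeps
#'
#' Bundles the geometry, forward model, sources, noise ladder and methods of
#' a sweep into one validated object.  All randomness is controlled by
#' `seed`; a sweep is a pure function of its configuration.
#'
#' @param sphere A [head_sphere()].
#' @param n_sites Helmet sites (default 102).
#' @param spacing,interior_margin Source-grid parameters, mm.
#' @param channels `"grads"`, `"all"` or `"mags"` (default planar
#'   gradiometers, the localization channels).
#' @param source_locations List or matrix of source locations, mm (snapped to
#'   the grid when simulated).
#' @param amplitude Source moment amplitude, nAm.
#' @param n_levels,n_reps Noise-ladder size.
#' @param snr_top_db,snr_bottom_db Ladder calibration endpoints, dB.
#' @param methods Character subset of `c("lcmv", "plcmv")`.
#' @param lambda_rel Diagonal-loading factor for both beamformers.
#' @param pls_threshold,pls_max_k PLS stopping controls.
#' @param seed Base seed.
#' @param n_samples,fs Waveform length and sampling rate.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(sphere = head_sphere(), n_sites = 102,
                              spacing = 10, interior_margin = 10,
                              channels = "grads",
                              source_locations = six_source_locations(),
                              amplitude = 100,
                              n_levels = 12, n_reps = 50,
                              snr_top_db = 6.990, snr_bottom_db = 0.043,
                              methods = c("lcmv", "plcmv"),
                              lambda_rel = 1e-4,
                              pls_threshold = 0.05, pls_max_k = NULL,
                              seed = 1, n_samples = 600, fs = 1000) {
  methods <- match.arg(methods, c("lcmv", "plcmv"), several.ok = TRUE)
  if (is.matrix(source_locations))
    source_locations <- lapply(seq_len(nrow(source_locations)),
                               function(i) source_locations[i, ])
  stopifnot(length(source_locations) >= 1, n_levels >= 1, n_reps >= 1)
  structure(list(sphere = sphere, n_sites = n_sites, spacing = spacing,
                 interior_margin = interior_margin, channels = channels,
                 source_locations = source_locations, amplitude = amplitude,
                 n_levels = n_levels, n_reps = n_reps,
                 snr_top_db = snr_top_db, snr_bottom_db = snr_bottom_db,
                 methods = methods, lambda_rel = lambda_rel,
                 pls_threshold = pls_threshold, pls_max_k = pls_max_k,
                 seed = seed, n_samples = n_samples, fs = fs),
            class = "experiment_config")
}

#' The six benchmark source locations
#'
#' Six dipole positions spanning deep and shallow cortex in Neuromag head
#' coordinates (mm): left mesial temporal, right lateral temporal, right
#' frontal, right occipital, right parietal, right mesial temporal.  The
#' first and last are deep sources.
#'
#' @return 6 x 3 matrix with a logical `"deep"` attribute per row.
#' @export
six_source_locations <- function() {
  m <- rbind(c(-29, 11, 38), c(67, 11, 30), c(59, 43, 70),
             c(59, -53, 54), c(67, -29, 86), c(35, 11, 38))
  rownames(m) <- c("left-mesial-temporal", "right-lateral-temporal",
                   "right-frontal", "right-occipital", "right-parietal",
                   "right-mesial-temporal")
  attr(m, "deep") <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  m
}

# Shared scene construction for sweeps: helmet, partition, grid, lead field.
build_scene <- function(config) {
  arr <- build_helmet_array(config$n_sites, config$sphere)
  part <- partition_regions(arr)
  grid <- build_source_grid(config$sphere, config$spacing,
                            config$interior_margin)
  lead <- compute_leadfield(grid, arr, config$sphere, config$channels)
  list(array = arr, partition = part, grid = grid, lead = lead)
}

# Localize one dataset with one method; returns list(index, location, K).
localize_with <- function(method, X, scene, config) {
  if (method == "lcmv") {
    r <- lcmv_localize(X, scene$lead, config$lambda_rel)
    list(index = r$index, location = r$location, K = NA_integer_)
  } else {
    r <- pls_lcmv_localize(X, scene$partition, scene$lead,
                           lambda_rel = config$lambda_rel,
                           threshold = config$pls_threshold,
                           max_k = config$pls_max_k)
    list(index = r$index, location = r$location, K = r$K_used)
  }
}

#' Run a noise sweep over sources, levels and repetitions
#'
#' For every source x noise level x repetition, simulates sinc-dipole data,
#' adds the calibrated Gaussian noise, and localizes with every configured
#' method.  Noise realizations are shared across methods at each cell
#' (paired design).  Any cell failure is recorded and the sweep continues.
#'
#' @param config An [experiment_config()].
#' @param scene Optional precomputed [build_scene()] output (reused across
#'   sweeps sharing a geometry).
#' @param progress Print a line per source.
#' @return Object of class `sweep_result`: `rows` (data.frame with columns
#'   `method, source, level, rep, seed, true_x/y/z, est_x/y/z,
#'   location_error, snr_db, K_used, failed`), `config`, `sigmas`,
#'   `snap_mm` (per-source snap distances).
#' @export
run_noise_sweep <- function(config, scene = NULL, progress = FALSE) {
  if (is.null(scene)) scene <- build_scene(config)
  wav <- sinc_waveform(config$n_samples, config$fs)
  nS <- length(config$source_locations)
  rows <- vector("list", nS)
  snap_mm <- numeric(nS)
  sigmas <- NULL
  for (s in seq_len(nS)) {
    loc <- config$source_locations[[s]]
    # snap the requested location to the nearest grid point first: the
    # simulated truth lives on the grid, and requested coordinates (e.g. the
    # benchmark set, given in another head's coordinates) may fall outside
    # the configured sphere
    gi <- which.min(colSums((t(scene$grid$points) - loc)^2))
    truth <- scene$grid$points[gi, ]
    snap_mm[s] <- sqrt(sum((truth - loc)^2))
    spec <- source_spec(truth, tangential_orientation(truth, config$sphere),
                        config$amplitude, wav, config$sphere)
    A <- project_dipole(spec, scene$lead)
    s1 <- sigma_for_snr(A, config$snr_top_db)
    sL <- sigma_for_snr(A, config$snr_bottom_db)
    sigmas <- if (config$n_levels > 1)
      s1 * (sL / s1)^((seq_len(config$n_levels) - 1) / (config$n_levels - 1))
    else s1
    cells <- vector("list", config$n_levels * config$n_reps * length(config$methods))
    ci <- 0L
    for (l in seq_len(config$n_levels)) {
      for (r in seq_len(config$n_reps)) {
        cell_seed <- config$seed + 100000L * s + 1000L * l + r
        ds <- add_noise(A, sigmas[l], cell_seed)
        for (m in config$methods) {
          fit <- tryCatch(localize_with(m, ds$observed, scene, config),
                          error = function(e) e)
          ci <- ci + 1L
          if (inherits(fit, "error")) {
            cells[[ci]] <- data.frame(method = m, source = s, level = l,
                                      rep = r, seed = cell_seed,
                                      true_x = truth[1], true_y = truth[2],
                                      true_z = truth[3],
                                      est_x = NA_real_, est_y = NA_real_,
                                      est_z = NA_real_,
                                      location_error = NA_real_,
                                      snr_db = ds$snr_db,
                                      K_used = NA_integer_, failed = TRUE)
          } else {
            cells[[ci]] <- data.frame(method = m, source = s, level = l,
                                      rep = r, seed = cell_seed,
                                      true_x = truth[1], true_y = truth[2],
                                      true_z = truth[3],
                                      est_x = fit$location[1],
                                      est_y = fit$location[2],
                                      est_z = fit$location[3],
                                      location_error =
                                        location_error(truth, fit$location),
                                      snr_db = ds$snr_db,
                                      K_used = fit$K, failed = FALSE)
          }
        }
      }
    }
    rows[[s]] <- do.call(rbind, cells)
    if (progress)
      message(sprintf("source %d/%d done (snap %.1f mm)", s, nS, snap_mm[s]))
  }
  structure(list(rows = do.call(rbind, rows), config = config,
                 sigmas = sigmas, snap_mm = snap_mm),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells (%d failed); methods: %s\n",
              nrow(x$rows), sum(x$rows$failed),
              paste(unique(x$rows$method), collapse = ", ")))
  invisible(x)
}

#' The six-source benchmark sweep
#'
#' Runs the full noise ladder at the six benchmark locations (snapped to the
#' configured grid) and returns per-source error-vs-level curves alongside
#' the raw sweep rows.  Sources 1 and 6 are tagged deep, the rest shallow.
#'
#' @param config An [experiment_config()]; its `source_locations` are
#'   replaced by [six_source_locations()].
#' @param scene Optional precomputed scene.
#' @param ... Passed to [run_noise_sweep()].
#' @return A `sweep_result` with an extra `curves` element: data.frame
#'   `(source, depth, level, method, mean_error, sd_error)`.
#' @export
six_source_experiment <- function(config = experiment_config(), scene = NULL, ...) {
  locs <- six_source_locations()
  config$source_locations <- lapply(seq_len(nrow(locs)), function(i) locs[i, ])
  sw <- run_noise_sweep(config, scene, ...)
  agg <- stats::aggregate(location_error ~ source + level + method,
                          data = sw$rows[!sw$rows$failed, ],
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  curves <- data.frame(source = agg$source,
                       depth = ifelse(attr(locs, "deep")[agg$source],
                                      "deep", "shallow"),
                       level = agg$level, method = agg$method,
                       mean_error = agg$location_error[, "mean"],
                       sd_error = agg$location_error[, "sd"])
  sw$curves <- curves[order(curves$source, curves$method, curves$level), ]
  sw
}

#' Sweep with sources at every subsampled grid point
#'
#' Places the simulated source at every `step`-th grid point (starting from
#' the first) and runs the noise ladder at each, the grid-coverage analogue
#' of the six-source benchmark.
#'
#' @param config An [experiment_config()].
#' @param step Subsampling step (default 12).
#' @param scene Optional precomputed scene.
#' @param ... Passed to [run_noise_sweep()].
#' @return A `sweep_result` with extra elements `source_indices` (grid
#'   indices exercised) and `summary` (per level x method mean/sd).
#' @export
subsampled_grid_experiment <- function(config = experiment_config(),
                                       step = 12, scene = NULL, ...) {
  if (is.null(scene)) scene <- build_scene(config)
  idx <- subsample_grid(scene$grid, step)
  config$source_locations <- lapply(idx, function(i) scene$grid$points[i, ])
  sw <- run_noise_sweep(config, scene, ...)
  sw$source_indices <- idx
  agg <- stats::aggregate(location_error ~ level + method,
                          data = sw$rows[!sw$rows$failed, ],
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  sw$summary <- data.frame(level = agg$level, method = agg$method,
                           mean_error = agg$location_error[, "mean"],
                           sd_error = agg$location_error[, "sd"])
  sw
}

#' Compare beamforming methods on a sweep
#'
#' Per-level mean location error for each method, paired per-cell differences
#' with bootstrap 95 percent confidence intervals, and a monotonicity report
#' (one-sided trend test of mean error against noise level).
#'
#' @param sweep A `sweep_result` (or its `rows` data.frame).
#' @param n_boot Bootstrap resamples for the paired-difference intervals.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return List with `per_level` (level x method mean/sd table), `pairs`
#'   (per-level paired mean difference and 95 percent CI for each method
#'   pair), `trend` (per-method Spearman correlation of error with level and
#'   one-sided p-value), `n_failed`.
#' @export
compare_methods <- function(sweep, n_boot = 2000, boot_seed = 1) {
  rows <- if (inherits(sweep, "sweep_result")) sweep$rows else sweep
  ok <- rows[!rows$failed, ]
  methods <- sort(unique(ok$method))
  agg <- stats::aggregate(location_error ~ level + method, data = ok,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  per_level <- data.frame(level = agg$level, method = agg$method,
                          mean_error = agg$location_error[, "mean"],
                          sd_error = agg$location_error[, "sd"])
  per_level <- per_level[order(per_level$method, per_level$level), ]
  rownames(per_level) <- NULL

  trend <- do.call(rbind, lapply(methods, function(m) {
    sub <- ok[ok$method == m, ]
    if (length(unique(sub$level)) < 2)
      return(data.frame(method = m, rho = NA_real_, p_increasing = NA_real_))
    ct <- suppressWarnings(stats::cor.test(sub$level, sub$location_error,
                                           method = "spearman",
                                           alternative = "greater"))
    data.frame(method = m, rho = unname(ct$estimate),
               p_increasing = ct$p.value)
  }))

  pairs <- NULL
  if (length(methods) >= 2) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(boot_seed)
    combos <- utils::combn(methods, 2, simplify = FALSE)
    pairs <- do.call(rbind, lapply(combos, function(pr) {
      a <- ok[ok$method == pr[1], c("source", "level", "rep", "location_error")]
      b <- ok[ok$method == pr[2], c("source", "level", "rep", "location_error")]
      mg <- merge(a, b, by = c("source", "level", "rep"),
                  suffixes = c("_a", "_b"))
      do.call(rbind, lapply(sort(unique(mg$level)), function(l) {
        d <- mg$location_error_a[mg$level == l] - mg$location_error_b[mg$level == l]
        bs <- replicate(n_boot, mean(sample(d, replace = TRUE)))
        data.frame(method_a = pr[1], method_b = pr[2], level = l,
                   mean_diff = mean(d),
                   ci_lo = unname(stats::quantile(bs, 0.025)),
                   ci_hi = unname(stats::quantile(bs, 0.975)))
      }))
    }))
  }
  list(per_level = per_level, pairs = pairs, trend = trend,
       n_failed = sum(rows$failed))
}

#' Export sweep rows and summaries as CSV
#' @param sweep A `sweep_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep_result <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sweep$rows, file.path(dir, "sweep_rows.csv"),
                   row.names = FALSE)
  cmp <- compare_methods(sweep)
  utils::write.csv(cmp$per_level, file.path(dir, "per_level.csv"),
                   row.names = FALSE)
  if (!is.null(cmp$pairs))
    utils::write.csv(cmp$pairs, file.path(dir, "paired_differences.csv"),
                     row.names = FALSE)
  invisible(dir)
}
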