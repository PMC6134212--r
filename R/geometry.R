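#' Spherical head model
#'
#' A homogeneous conducting sphere standing in for the head volume conductor,
#' in Neuromag-style head coordinates (x toward the right pre-auricular point,
#' y toward the nasion, z superior), all lengths in mm.
#'
#' @param center Numeric 3-vector, sphere center in mm.
#' @param radius Positive scalar, sphere radius in mm.
#' @return An object of class `head_sphere` with elements `center` and `radius`.
#' @examples
#' sph <- head_sphere()
#' sph$radius
#' @export
head_sphere <- function(center = c(0, 0, 40), radius = 75) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, is.finite(center))
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("'radius' must be a positive finite scalar")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "head_sphere")
}

#' @export
print.head_sphere <- function(x, ...) {
  cat(sprintf("<head_sphere> center (%g, %g, %g) mm, radius %g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

# Quasi-uniform points on the upper cap of a unit sphere via a Fibonacci
# lattice, restricted to elevations above `elev_cutoff` (radians).  The
# lattice is deterministic: no randomness enters helmet construction.
fibonacci_cap <- function(n, elev_cutoff) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  # uniform in sin(elevation) over [sin(cutoff), 1]
  s <- sin(elev_cutoff) + (1 - sin(elev_cutoff)) * i / n
  elev <- asin(s)
  azim <- 2 * pi * i / golden
  cbind(cos(elev) * cos(azim), cos(elev) * sin(azim), sin(elev))
}

# Deterministic tangential frame at a radial direction u (unit 3-vector):
# e1, e2 orthonormal, both orthogonal to u.
tangent_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Build a helmet-shaped triplet sensor array
#'
#' Places `n_sites` measurement sites quasi-uniformly (Fibonacci lattice,
#' deterministic) on the upper cap of a sphere concentric with the head
#' sphere, at radius `radius + shell_offset`.  Each site carries one
#' magnetometer and two orthogonal planar gradiometers, so the full array has
#' `M = 3 * n_sites` channels.  Coil normals point radially outward;
#' gradiometer baselines lie along the two tangential frame directions.
#'
#' @param n_sites Number of sites (>= 8; default 102, a whole-head helmet).
#' @param sphere A [head_sphere()].
#' @param shell_offset Distance from scalp sphere to the sensor shell, mm (> 0).
#' @param elev_cutoff_deg Lowest site elevation in degrees relative to the
#'   horizontal plane through the sphere center; the default -30 extends the
#'   cap below the "equator" as a helmet does.
#' @param baseline_mm Planar-gradiometer baseline length, mm.
#' @return An object of class `sensor_array`: list with `site_positions`
#'   (`n_sites` x 3), `channel_positions` (M x 3), `channel_orientations`
#'   (M x 3 unit coil normals), `baseline_dirs` (M x 3; unit tangential
#'   baseline direction for gradiometers, zero rows for magnetometers),
#'   `baseline_mm` (length-M; 0 for magnetometers), `channel_types` (character:
#'   `"magnetometer"`, `"planar_grad_1"`, `"planar_grad_2"`), `site_index`
#'   (length-M), `M`, and `sphere`.
#' @examples
#' arr <- build_helmet_array(102, head_sphere(), shell_offset = 20)
#' arr$M  # 306
#' @export
build_helmet_array <- function(n_sites = 102, sphere = head_sphere(),
                               shell_offset = 20, elev_cutoff_deg = -30,
                               baseline_mm = 17) {
  stopifnot(inherits(sphere, "head_sphere"))
  if (n_sites < 8) stop("'n_sites' must be >= 8 to cover the eight regions")
  if (shell_offset <= 0) stop("'shell_offset' must be positive")
  if (baseline_mm <= 0) stop("'baseline_mm' must be positive")

  R <- sphere$radius + shell_offset
  u <- fibonacci_cap(n_sites, elev_cutoff_deg * pi / 180)   # unit directions
  sites <- sweep(u * R, 2, sphere$center, "+")

  M <- 3L * n_sites
  pos <- matrix(NA_real_, M, 3)
  ori <- matrix(NA_real_, M, 3)
  bdir <- matrix(0, M, 3)
  blen <- numeric(M)
  type <- character(M)
  sidx <- integer(M)
  for (s in seq_len(n_sites)) {
    fr <- tangent_frame(u[s, ])
    rows <- (3L * (s - 1L) + 1L):(3L * s)
    pos[rows, ] <- matrix(sites[s, ], 3, 3, byrow = TRUE)
    ori[rows, ] <- matrix(u[s, ], 3, 3, byrow = TRUE)
    type[rows] <- c("magnetometer", "planar_grad_1", "planar_grad_2")
    bdir[rows[2], ] <- fr$e1
    bdir[rows[3], ] <- fr$e2
    blen[rows[2:3]] <- baseline_mm
    sidx[rows] <- s
  }
  structure(list(site_positions = sites, channel_positions = pos,
                 channel_orientations = ori, baseline_dirs = bdir,
                 baseline_mm = blen, channel_types = type,
                 site_index = sidx, M = M, sphere = sphere),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sites, %d channels (%d mag, %d grad)\n",
              nrow(x$site_positions), x$M,
              sum(x$channel_types == "magnetometer"),
              sum(x$channel_types != "magnetometer")))
  invisible(x)
}

#' Select channels of an array by type
#'
#' @param array A [build_helmet_array()] result.
#' @param channels One of `"grads"` (planar gradiometers only, the default for
#'   localization), `"mags"`, or `"all"`.
#' @return Integer indices of the selected channels.
#' @export
channel_mask <- function(array, channels = c("grads", "all", "mags")) {
  channels <- match.arg(channels)
  switch(channels,
         all   = seq_len(array$M),
         grads = which(array$channel_types != "magnetometer"),
         mags  = which(array$channel_types == "magnetometer"))
}

.region_names <- c("frontal-L", "frontal-R", "temporal-L", "temporal-R",
                   "parietal-L", "parietal-R", "occipital-L", "occipital-R")

#' Partition helmet sites into eight anatomical regions
#'
#' Labels every channel with one of eight regions (frontal, temporal,
#' parietal, occipital; left/right), the classes of the PLS class matrix.
#' The rule is geometric on the site position relative to the sphere center:
#' hemisphere by the sign of x (ties to left); a site is temporal when it sits
#' low (elevation below `temporal_elev_deg`) and laterally (|x| exceeds
#' `lateral_ratio` times |y| in the horizontal plane); the remaining sites are
#' split frontal / parietal / occipital by the sagittal angle
#' `atan2(y, z)` with cuts at `frontal_cut_deg` and `occipital_cut_deg`
#' (ties to the anterior side).  All three channels of a site share its label.
#'
#' @param array A [build_helmet_array()] result.
#' @param sphere The [head_sphere()]; defaults to the array's own.
#' @param frontal_cut_deg Sagittal angle (deg) above which a non-temporal site
#'   is frontal.
#' @param occipital_cut_deg Sagittal angle (deg) below which a non-temporal
#'   site is occipital.
#' @param temporal_elev_deg Elevation (deg) below which a lateral site is
#'   temporal.
#' @param lateral_ratio Lateral dominance factor for the temporal rule.
#' @return Object of class `region_partition`: `labels` (length-M factor with
#'   the eight region levels), `site_labels`, `counts` (named per-region
#'   channel counts), `C = 8`, `region_names`.
#' @examples
#' arr <- build_helmet_array(102)
#' part <- partition_regions(arr)
#' part$counts
#' @export
partition_regions <- function(array, sphere = array$sphere,
                              frontal_cut_deg = 35, occipital_cut_deg = -35,
                              temporal_elev_deg = 25, lateral_ratio = 1) {
  stopifnot(inherits(array, "sensor_array"))
  d <- sweep(array$site_positions, 2, sphere$center)
  x <- d[, 1]; y <- d[, 2]; z <- d[, 3]
  elev <- atan2(z, sqrt(x^2 + y^2)) * 180 / pi
  sag  <- atan2(y, z) * 180 / pi            # +90 anterior, 0 vertex, -90 posterior

  lobe <- ifelse(elev < temporal_elev_deg & abs(x) > lateral_ratio * abs(y),
                 "temporal",
          ifelse(sag >= frontal_cut_deg, "frontal",
          ifelse(sag < occipital_cut_deg, "occipital", "parietal")))
  hemi <- ifelse(x > 0, "R", "L")           # x == 0 -> left, per tie rule
  site_labels <- factor(paste(lobe, hemi, sep = "-"), levels = .region_names)

  labels <- site_labels[array$site_index]
  counts <- table(labels)
  if (any(counts == 0))
    stop("empty region(s): ", paste(names(counts)[counts == 0], collapse = ", "),
         "; the PLS class matrix would be degenerate")
  structure(list(labels = labels, site_labels = site_labels,
                 counts = c(counts), C = length(.region_names),
                 region_names = .region_names),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", sum(x$counts), "channels in", x$C, "regions\n")
  print(x$counts)
  invisible(x)
}

#' Build a regular volumetric source grid inside the head sphere
#'
#' Axis-aligned lattice with the given spacing, centered on the sphere center,
#' clipped to points with `||p - center|| <= radius - interior_margin`.
#' Points are ordered lexicographically in (x, y, z).
#'
#' @param sphere A [head_sphere()].
#' @param spacing Lattice spacing, mm (0 < spacing < 2 * radius).
#' @param interior_margin Keep-out depth from the sphere surface, mm.
#' @return Object of class `source_grid`: `points` (P x 3 mm), `spacing`, `P`,
#'   `sphere`.
#' @examples
#' g <- build_source_grid(head_sphere(), spacing = 10)
#' g$P
#' @export
build_source_grid <- function(sphere, spacing = 10, interior_margin = 10) {
  stopifnot(inherits(sphere, "head_sphere"))
  if (spacing <= 0 || spacing >= 2 * sphere$radius)
    stop("'spacing' must lie in (0, 2*radius)")
  if (interior_margin < 0) stop("'interior_margin' must be >= 0")
  reff <- sphere$radius - interior_margin
  if (reff <= 0) stop("'interior_margin' >= radius leaves an empty grid")
  n <- floor(reff / spacing)
  ax <- seq(-n, n) * spacing
  # expand.grid varies its first factor fastest; feed (z, y, x) so the row
  # order is lexicographic in (x, y, z)
  pts <- as.matrix(expand.grid(z = ax, y = ax, x = ax)[, c("x", "y", "z")])
  keep <- rowSums(pts^2) <= reff^2 + 1e-9
  pts <- sweep(pts[keep, , drop = FALSE], 2, sphere$center, "+")
  if (nrow(pts) < 1) stop("empty source grid")
  dimnames(pts) <- NULL
  structure(list(points = pts, spacing = spacing, P = nrow(pts),
                 sphere = sphere),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %g mm spacing\n", x$P, x$spacing))
  invisible(x)
}

#' Subsample a source grid by a regular step
#'
#' Returns the 1-based indices of every `step`-th grid point starting from the
#' first, i.e. positions 0, step, 2*step, ... in 0-based counting; the count
#' is `floor((P - 1) / step) + 1`.
#'
#' @param grid A [build_source_grid()] result (or anything with `P`).
#' @param step Positive integer step length.
#' @return Integer vector of 1-based grid indices.
#' @examples
#' g <- list(P = 3704)
#' length(subsample_grid(g, 12))  # 309
#' @export
subsample_grid <- function(grid, step) {
  if (!is.numeric(step) || length(step) != 1 || step < 1 || step != floor(step))
    stop("'step' must be a positive integer")
  seq.int(1L, grid$P, by = as.integer(step))
}

#' Export / import a sensor layout as CSV
#'
#' Writes one row per channel with columns `site_id, channel_id, type, x, y,
#' z, ox, oy, oz, bx, by, bz, baseline_mm, region`.
#'
#' @param array A `sensor_array`.
#' @param file Path to write.
#' @param partition Optional `region_partition` supplying the region column.
#' @return `file`, invisibly.
#' @export
write_sensor_layout <- function(array, file, partition = NULL) {
  region <- if (is.null(partition)) NA_character_ else as.character(partition$labels)
  df <- data.frame(site_id = array$site_index,
                   channel_id = seq_len(array$M),
                   type = array$channel_types,
                   x = array$channel_positions[, 1],
                   y = array$channel_positions[, 2],
                   z = array$channel_positions[, 3],
                   ox = array$channel_orientations[, 1],
                   oy = array$channel_orientations[, 2],
                   oz = array$channel_orientations[, 3],
                   bx = array$baseline_dirs[, 1],
                   by = array$baseline_dirs[, 2],
                   bz = array$baseline_dirs[, 3],
                   baseline_mm = array$baseline_mm,
                   region = region)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sensor_layout
#' @param sphere Head sphere to attach to the imported array.
#' @export
read_sensor_layout <- function(file, sphere = head_sphere()) {
  df <- utils::read.csv(file)
  sites <- as.matrix(df[df$type == "magnetometer", c("x", "y", "z")])
  dimnames(sites) <- NULL
  structure(list(site_positions = sites,
                 channel_positions = unname(as.matrix(df[, c("x", "y", "z")])),
                 channel_orientations = unname(as.matrix(df[, c("ox", "oy", "oz")])),
                 baseline_dirs = unname(as.matrix(df[, c("bx", "by", "bz")])),
                 baseline_mm = df$baseline_mm,
                 channel_types = df$type,
                 site_index = df$site_id,
                 M = nrow(df), sphere = sphere),
            class = "sensor_array")
}

#' Export a source grid as CSV (`index, x, y, z`)
#' @param grid A `source_grid`.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_source_grid <- function(grid, file) {
  utils::write.csv(data.frame(index = seq_len(grid$P),
                              x = grid$points[, 1],
                              y = grid$points[, 2],
                              z = grid$points[, 3]),
                   file, row.names = FALSE)
  invisible(file)
}
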