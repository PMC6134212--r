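# Shared fixtures, built once per test run.  The "small" scene keeps the
# default 102-site helmet (the partition needs all eight regions) but a
# coarse 20 mm grid so lead-field work stays cheap; the "desk" scene is the
# default 10 mm grid used by the slower end-to-end checks.

.scene_cache <- new.env(parent = emptyenv())

get_scene <- function(which = c("small", "desk")) {
  which <- match.arg(which)
  if (!is.null(.scene_cache[[which]])) return(.scene_cache[[which]])
  sph <- head_sphere()
  arr <- build_helmet_array(102, sph)
  part <- partition_regions(arr)
  spacing <- if (which == "small") 20 else 10
  grid <- build_source_grid(sph, spacing = spacing, interior_margin = 10)
  lead <- compute_leadfield(grid, arr, sph, "grads")
  sc <- list(sphere = sph, array = arr, partition = part, grid = grid,
             lead = lead)
  .scene_cache[[which]] <- sc
  sc
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# brute-force minimum-variance weights under the unit-gain constraint,
# solved in the null space of the constraint (independent of the Eq. 6
# closed form): W = W0 + N A with L' W0 = I and L' N = 0, minimizing
# tr(W' C W) over the free parameters A.
qp_min_variance_weights <- function(L, C) {
  M <- nrow(L); k <- ncol(L)
  W0 <- L %*% solve(crossprod(L))           # min-norm particular solution
  Nsp <- qr.Q(qr(L), complete = TRUE)[, (k + 1):M, drop = FALSE]
  A <- -solve(crossprod(Nsp, C %*% Nsp), crossprod(Nsp, C %*% W0))
  W0 + Nsp %*% A
}

# synthetic "leadfield" wrapper for generic gain arrays (tests of the scan
# machinery on non-spherical lead fields)
toy_leadfield <- function(gains, points = NULL) {
  P <- dim(gains)[1]
  if (is.null(points)) points <- cbind(seq_len(P), 0, 0)
  gains2 <- array(0, dim = c(P, dim(gains)[2], 2))
  basis2 <- array(0, dim = c(P, 3, 2))
  for (p in seq_len(P)) {
    Lp <- matrix(gains[p, , ], dim(gains)[2], 3)
    e <- eigen(crossprod(Lp), symmetric = TRUE)
    gains2[p, , ] <- Lp %*% e$vectors[, 1:2]
    basis2[p, , ] <- e$vectors[, 1:2]
  }
  structure(list(gains = gains, gains2 = gains2, basis2 = basis2,
                 channels = seq_len(dim(gains)[2]),
                 grid = list(points = points, P = P)),
            class = "leadfield")
}
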