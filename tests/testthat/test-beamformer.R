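test_that("sample covariance matches the unbiased definition", {
  # hand-computed 2x2 example (N - 1 = 1)
  X <- rbind(c(1, -1), c(2, -2))
  expect_equal(sample_covariance(X)$C, rbind(c(2, 4), c(4, 8)))
  set.seed(41)
  X <- matrix(rnorm(10 * 30), 10, 30)
  cv <- sample_covariance(X)
  expect_equal(cv$C, t(cv$C))
  ev <- eigen(cv$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * sum(diag(cv$C)))
  # direct recomputation oracle after duplicating the time axis
  X2 <- cbind(X, X)
  Xc <- X2 - rowMeans(X2)
  expect_equal(sample_covariance(X2)$C,
               tcrossprod(Xc) / (ncol(X2) - 1), tolerance = 1e-12)
  expect_error(sample_covariance(X[, 1, drop = FALSE]), "2")
})

test_that("regularized inverse converges to the exact inverse", {
  set.seed(42)
  A <- matrix(rnorm(8 * 20), 8, 20)
  C <- tcrossprod(A) / 19
  cv <- structure(list(C = C, n_samples = 20), class = "sensor_cov")
  expect_equal(regularized_inverse(cv, 0), solve(C), tolerance = 1e-8,
               ignore_attr = "lambda_abs")
  errs <- vapply(c(1e-2, 1e-4, 1e-6), function(l)
    max(abs(regularized_inverse(cv, l) - solve(C))), numeric(1))
  expect_true(all(diff(errs) < 0))
  # rank-1 covariance: loading makes it invertible, zero loading errors
  r1 <- tcrossprod(rnorm(8))
  cv1 <- structure(list(C = r1, n_samples = 2), class = "sensor_cov")
  out <- regularized_inverse(cv1, 0.01)
  expect_true(all(is.finite(out)))
  expect_equal(out, t(out))
  expect_error(regularized_inverse(cv1, 0), "loading")
})

test_that("LCMV weights satisfy unit gain and minimize output variance", {
  set.seed(43)
  # orthonormal lead field with identity covariance: W = L0
  L0 <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  W <- lcmv_weights(L0, diag(12))
  expect_equal(W, L0, tolerance = 1e-10)
  expect_equal(crossprod(W, L0), diag(3), tolerance = 1e-10)
  for (i in 1:20) {
    M <- 10
    L <- matrix(rnorm(M * 3), M, 3)
    A <- matrix(rnorm(M * (M + 5)), M)
    C <- tcrossprod(A) / (M + 4)
    Cinv <- solve(C)
    W <- lcmv_weights(L, Cinv)
    expect_equal(crossprod(W, L), diag(3), tolerance = 1e-8)
    # optimality: projected random perturbations cannot lower the variance
    v0 <- sum(diag(crossprod(W, C %*% W)))
    Nsp <- qr.Q(qr(L), complete = TRUE)[, 4:M, drop = FALSE]
    for (j in 1:5) {
      Wp <- W + Nsp %*% matrix(rnorm((M - 3) * 3), M - 3, 3) * 0.1
      expect_gte(sum(diag(crossprod(Wp, C %*% Wp))), v0 - 1e-10)
    }
  }
})

test_that("closed-form weights match the null-space quadratic program", {
  set.seed(44)
  for (M in c(4, 5, 6)) {
    for (i in 1:10) {
      L <- matrix(rnorm(M * 3), M, 3)
      A <- matrix(rnorm(M * (M + 6)), M)
      C <- tcrossprod(A) / (M + 5)
      W_eq <- lcmv_weights(L, solve(C))
      W_qp <- qp_min_variance_weights(L, C)
      expect_equal(W_eq, W_qp, tolerance = 1e-6)
      # and the variance-map trace equals the QP's objective value
      expect_equal(sum(diag(solve(crossprod(L, solve(C, L))))),
                   sum(diag(crossprod(W_qp, C %*% W_qp))),
                   tolerance = 1e-6)
    }
  }
})

test_that("variance map obeys homogeneity and the identity-covariance value", {
  set.seed(45)
  gains <- array(rnorm(5 * 12 * 3), dim = c(5, 12, 3))
  lead <- toy_leadfield(gains)
  X <- matrix(rnorm(12 * 50), 12, 50)
  m1 <- variance_map(lead, sample_covariance(X), lambda_rel = 0,
                     rank = 3, normalize = "none")
  # scaling the data by c scales the raw map by c^2
  m2 <- variance_map(lead, sample_covariance(3 * X), lambda_rel = 0,
                     rank = 3, normalize = "none")
  expect_equal(m2$values, 9 * m1$values, tolerance = 1e-8)
  # ... and leaves the noise-normalized map unchanged
  n1 <- variance_map(lead, sample_covariance(X), lambda_rel = 0, rank = 3)
  n2 <- variance_map(lead, sample_covariance(3 * X), lambda_rel = 0, rank = 3)
  expect_equal(n2$values, 9 * n1$values, tolerance = 1e-8)
  # orthonormal gains with identity covariance: raw value is exactly 3
  g2 <- array(0, dim = c(2, 12, 3))
  for (p in 1:2) g2[p, , ] <- qr.Q(qr(matrix(rnorm(36), 12, 3)))
  leadQ <- toy_leadfield(g2)
  mQ <- variance_map(leadQ, cov = NULL, Cinv = diag(12), rank = 3,
                     normalize = "none")
  expect_equal(mQ$values, c(3, 3), tolerance = 1e-10)
  # adding a constant offset to every channel/time leaves the map unchanged
  m3 <- variance_map(lead, sample_covariance(X + 5), lambda_rel = 0,
                     rank = 3, normalize = "none")
  expect_equal(m3$values, m1$values, tolerance = 1e-8)
})

test_that("localization takes the argmax with deterministic tie-break", {
  grid <- list(points = rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)), P = 3)
  mk <- function(v) structure(list(values = v, grid = grid),
                              class = "variance_map")
  expect_equal(localize(mk(c(1, 5, 2)))$index, 2)
  expect_equal(localize(mk(c(5, 5, 2)))$index, 1)
  expect_equal(localize(mk(c(NA, 1, 2)))$index, 3)
  expect_error(localize(mk(c(NA_real_, NA_real_, NA_real_))), "valid")
})

test_that("noiseless single-dipole data is localized exactly on the grid", {
  sc <- get_scene("small")
  gi <- 40
  truth <- sc$grid$points[gi, ]
  spec <- source_spec(truth, tangential_orientation(truth, sc$sphere),
                      100, sinc_waveform(), sc$sphere)
  A <- project_dipole(spec, sc$lead)
  expect_equal(attr(A, "grid_index"), gi)
  r <- lcmv_localize(A, sc$lead, lambda_rel = 1e-8)
  expect_equal(r$index, gi)
  expect_equal(location_error(truth, r$location), 0)
  rp <- pls_lcmv_localize(A, sc$partition, sc$lead)
  expect_equal(rp$index, gi)
})

test_that("low-rank covariance shortcut equals the dense pipeline", {
  sc <- get_scene("small")
  set.seed(46)
  sel <- sc$lead$channels
  gi <- 25
  truth <- sc$grid$points[gi, ]
  spec <- source_spec(truth, tangential_orientation(truth, sc$sphere),
                      100, sinc_waveform(200), sc$sphere)
  A <- project_dipole(spec, sc$lead)
  X <- A + matrix(rnorm(length(A), sd = sigma_for_snr(A, 4)), nrow(A))
  den <- pls_denoise(X, sc$partition, channels = sel, max_k = 5)
  # dense route: reconstruct, covariance, loaded inverse
  Cd <- sample_covariance(den$X_hat)
  Cinv_dense <- regularized_inverse(Cd, 1e-4)
  Cinv_fast <- plsbeam:::lowrank_loaded_inverse(den$model, den$model$K,
                                                ncol(X), 1e-4)
  expect_equal(attr(Cinv_fast, "lambda_abs"), attr(Cinv_dense, "lambda_abs"),
               tolerance = 1e-10)
  expect_equal(Cinv_fast, Cinv_dense, tolerance = 1e-6,
               ignore_attr = "lambda_abs")
})

test_that("pLCMV with exact reconstruction degenerates to plain LCMV", {
  sc <- get_scene("small")
  set.seed(47)
  # low-rank data so the PLS can reconstruct it exactly within the cap
  sel <- sc$lead$channels
  Mch <- length(sel)
  X <- matrix(rnorm(Mch * 4), Mch, 4) %*% matrix(rnorm(4 * 120), 4, 120)
  sx <- standardize_columns(X)
  r <- qr(sx$Xn)$rank
  rl <- lcmv_localize(X, sc$lead, lambda_rel = 1e-4)
  rp <- pls_lcmv_localize(X, sc$partition, sc$lead, lambda_rel = 1e-4,
                          threshold = 0, max_k = r, K_use = r)
  rel_diff <- max(abs(rp$map$values - rl$map$values), na.rm = TRUE) /
    max(abs(rl$map$values), na.rm = TRUE)
  expect_lt(rel_diff, 1e-8)
  expect_equal(rp$index, rl$index)
})
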