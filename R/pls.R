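#' Region class membership matrix
#'
#' Builds the M x C indicator matrix Y that supervises the PLS extraction:
#' `Y[i, c] = 1` iff channel i belongs to region c.  Each row has exactly one
#' 1; column sums are the per-region channel counts.
#'
#' @param partition A [partition_regions()] result.
#' @param channels Integer indices of the channels to keep (default all).
#' @return Object of class `class_matrix`: `Y` (M_sel x C 0/1 matrix with
#'   region column names), `region_names`, `counts` (column sums).
#' @examples
#' arr <- build_helmet_array(102)
#' Y <- build_class_matrix(partition_regions(arr))$Y
#' dim(Y)        # 306 x 8
#' all(rowSums(Y) == 1)
#' @export
build_class_matrix <- function(partition, channels = NULL) {
  lab <- partition$labels
  if (!is.null(channels)) lab <- lab[channels]
  if (anyNA(lab)) stop("unlabeled channel in selection")
  Y <- stats::model.matrix(~ lab - 1)
  colnames(Y) <- levels(lab)
  attributes(Y)[c("assign", "contrasts")] <- NULL
  rownames(Y) <- NULL
  counts <- colSums(Y)
  if (any(counts == 0))
    stop("empty region(s) after channel masking: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  structure(list(Y = Y, region_names = colnames(Y), counts = counts),
            class = "class_matrix")
}

#' Column standardization
#'
#' Centers and scales every column (time point) to mean 0, variance 1, and
#' keeps the statistics so the transform can be inverted.  Both the data
#' matrix X and the class matrix Y are standardized this way before the PLS
#' optimization.
#'
#' @param X Numeric matrix (rows = samples/channels, columns = variables).
#' @return List with `Xn` (standardized matrix) and `scaling` (class
#'   `column_scaling`: `means`, `sds`).
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two rows to standardize")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("constant column(s), cannot standardize: index ",
         paste(utils::head(bad, 5), collapse = ", "))
  Xn <- sweep(sweep(X, 2, means), 2, sds, "/")
  list(Xn = Xn, scaling = structure(list(means = means, sds = sds),
                                    class = "column_scaling"))
}

#' @rdname standardize_columns
#' @param Xn Standardized matrix.
#' @param scaling A `column_scaling`.
#' @export
destandardize_columns <- function(Xn, scaling) {
  sweep(sweep(Xn, 2, scaling$sds, "*"), 2, scaling$means, "+")
}

# Spectral norm ||X||_2 through the small Gram side (exact; the Gram never
# exceeds min(M, N) so the symmetric eigensolve is cheap).
spectral_norm <- function(X) {
  S <- if (nrow(X) <= ncol(X)) tcrossprod(X) else crossprod(X)
  sqrt(max(eigen(S, symmetric = TRUE, only.values = TRUE)$values[1], 0))
}

#' Fit a two-block NIPALS PLS model
#'
#' Iteratively extracts weight/score/loading sets maximizing the squared
#' covariance between projections `Xn w` and `Yn v` of the standardized data
#' and class blocks.  Per component: the inner power iteration alternates
#' `w = X'u / ||X'u||`, `t = X w`, `c = Y't / t't`, `u = Y c / c'c` until `w`
#' stabilizes; the X loading is `p = X't / t't`; both blocks are deflated
#' (`X <- X - t p'`, `Y <- Y - t c'` by default).  Extraction stops when the
#' spectral norm of the deflated X drops to `threshold` times its initial
#' value, or at `max_k` components.  Scores of different components are
#' mutually orthogonal; each weight vector has unit norm.  The sign of each
#' component is fixed by making the largest-magnitude entry of `w` positive,
#' so the fit is fully deterministic.
#'
#' @param Xn M x N standardized data block.
#' @param Yn M x C standardized class block (row-aligned with `Xn`).
#' @param threshold Relative residual spectral-norm stopping threshold.
#' @param max_k Hard cap on the number of components (default
#'   `min(M, N, 30)`).
#' @param deflate_y Deflate the Y block as well (default TRUE; the X-side
#'   reconstruction is identical either way).
#' @param inner How the per-component weight pair is computed.  `"eigen"`
#'   (default) solves the inner maximization exactly through the
#'   eigendecomposition of the small C x C matrix `(X'Y)'(X'Y)` — the fixed
#'   point the classical power iteration converges to, without its slowdown
#'   when leading covariance directions are nearly tied.  `"power"` runs the
#'   classical alternating power iteration and errors if it exceeds
#'   `inner_maxit`.
#' @param inner_tol,inner_maxit Convergence control for `inner = "power"`.
#' @return Object of class `pls_model`: `W` (N x K unit-norm weights), `V`
#'   (C x K response weights, unit norm), `T` (M x K scores, the intrinsic
#'   components), `P_load` (N x K predictor loadings), `C_load` (C x K
#'   response loadings used in deflation), `K`, `residual_norms` (spectral
#'   norm of the deflated X after each step, preceded by the initial norm),
#'   `scaling` (set by [pls_denoise()]; NULL here).
#' @export
fit_pls <- function(Xn, Yn, threshold = 0.05, max_k = NULL,
                    deflate_y = TRUE, inner = c("eigen", "power"),
                    inner_tol = 1e-10, inner_maxit = 500) {
  inner <- match.arg(inner)
  Xn <- as.matrix(Xn); Yn <- as.matrix(Yn)
  M <- nrow(Xn); N <- ncol(Xn); C <- ncol(Yn)
  if (nrow(Yn) != M) stop("Xn and Yn must be row-aligned")
  if (M < C) stop("need at least as many samples as classes")
  if (is.null(max_k)) max_k <- min(M, N, 30L)

  X <- Xn; Y <- Yn
  # the residual spectral norm is tracked on the small Gram side, updated
  # with rank-2 corrections per deflation (deflation is rank one in X)
  use_left <- M <= N
  S <- if (use_left) tcrossprod(X) else crossprod(X)
  gram_norm <- function(S)
    sqrt(max(eigen(S, symmetric = TRUE, only.values = TRUE)$values[1], 0))
  norm0 <- gram_norm(S)
  W <- matrix(0, N, 0); V <- matrix(0, C, 0)
  Tm <- matrix(0, M, 0); P <- matrix(0, N, 0); Cl <- matrix(0, C, 0)
  res <- norm0
  k <- 0L
  while (k < max_k) {
    rnorm_now <- res[length(res)]
    if (rnorm_now <= threshold * norm0) break
    if (inner == "eigen") {
      Z <- crossprod(X, Y)                         # N x C
      if (sum(Z^2) == 0) break                     # no covariance left
      ev <- eigen(crossprod(Z), symmetric = TRUE)  # C x C
      w <- as.vector(Z %*% ev$vectors[, 1])
      wn <- sqrt(sum(w^2))
      if (wn == 0) break
      w <- w / wn
      tt <- as.vector(X %*% w)
      cc <- as.vector(crossprod(Y, tt)) / sum(tt^2)
    } else {
      u <- Y[, which.max(colSums(Y^2)), drop = TRUE]
      w_old <- rep(0, N)
      converged <- FALSE
      for (it in seq_len(inner_maxit)) {
        w <- as.vector(crossprod(X, u))
        wn <- sqrt(sum(w^2))
        if (wn == 0) break
        w <- w / wn
        tt <- as.vector(X %*% w)
        cc <- as.vector(crossprod(Y, tt)) / sum(tt^2)
        u <- as.vector(Y %*% cc) / sum(cc^2)
        if (sqrt(sum((w - w_old)^2)) < inner_tol) { converged <- TRUE; break }
        w_old <- w
      }
      if (!converged && it == inner_maxit)
        stop("inner power iteration did not converge at component ", k + 1L)
      if (sqrt(sum(w^2)) == 0) break               # X fully deflated
    }
    # deterministic sign: largest |entry| of w positive
    flip <- sign(w[which.max(abs(w))])
    w <- flip * w; tt <- flip * tt; cc <- flip * cc
    p <- as.vector(crossprod(X, tt)) / sum(tt^2)
    if (use_left) {
      q <- as.vector(X %*% p)               # pre-deflation X
      S <- S - tcrossprod(q, tt) - tcrossprod(tt, q) +
        sum(p^2) * tcrossprod(tt)
    } else {
      r2 <- as.vector(crossprod(X, tt))
      S <- S - tcrossprod(r2, p) - tcrossprod(p, r2) +
        sum(tt^2) * tcrossprod(p)
    }
    X <- X - tcrossprod(tt, p)
    if (deflate_y) Y <- Y - tcrossprod(tt, cc)
    k <- k + 1L
    W <- cbind(W, w); Tm <- cbind(Tm, tt); P <- cbind(P, p); Cl <- cbind(Cl, cc)
    V <- cbind(V, cc / sqrt(sum(cc^2)))
    rk <- gram_norm(S)
    if (rk < 1e-6 * norm0) {
      # the updated Gram carries absolute rounding at the initial scale;
      # refresh it from the deflated X so small residuals are accurate
      S <- if (use_left) tcrossprod(X) else crossprod(X)
      rk <- gram_norm(S)
    }
    res <- c(res, rk)
  }
  if (k == 0L) stop("no PLS component could be extracted")
  dimnames(W) <- dimnames(V) <- dimnames(Tm) <- dimnames(P) <- dimnames(Cl) <- NULL
  structure(list(W = W, V = V, T = Tm, P_load = P, C_load = Cl, K = k,
                 residual_norms = res, threshold = threshold,
                 scaling = NULL),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> K = %d components; residual |X|_2: %.4g -> %.4g\n",
              x$K, x$residual_norms[1], x$residual_norms[length(x$residual_norms)]))
  invisible(x)
}

#' Reconstruct a denoised data matrix from a PLS model
#'
#' `X_hat = T[, 1:K_use] %*% t(P_load[, 1:K_use])`, de-standardized back to
#' the original data units when the model carries column scaling (as models
#' from [pls_denoise()] do).
#'
#' @param model A `pls_model`.
#' @param K_use Number of components to use (default all).
#' @return M x N reconstructed matrix.
#' @export
reconstruct <- function(model, K_use = model$K) {
  if (K_use < 1 || K_use > model$K)
    stop("'K_use' must be in 1..", model$K)
  Xh <- tcrossprod(model$T[, seq_len(K_use), drop = FALSE],
                   model$P_load[, seq_len(K_use), drop = FALSE])
  if (!is.null(model$scaling)) Xh <- destandardize_columns(Xh, model$scaling)
  Xh
}

#' PLS denoising of a sensor array
#'
#' End-to-end supervised denoising: build the region class matrix, column-
#' standardize both blocks, fit the NIPALS PLS model, and reconstruct the
#' sensor matrix from the intrinsic components in the original field units.
#'
#' @param X M x N sensor data (channels x time).
#' @param partition A [partition_regions()] result covering the rows of `X`.
#' @param channels Optional channel indices (rows of the full array) that `X`
#'   corresponds to, used to subset the partition labels.
#' @param threshold,max_k,... Passed to [fit_pls()].
#' @param K_use Components used in the reconstruction (default all fitted).
#' @return List with `X_hat` (denoised matrix, original units), `model`
#'   (`pls_model`, scaling attached), `Y` (the class matrix used).
#' @export
pls_denoise <- function(X, partition, channels = NULL, threshold = 0.05,
                        max_k = NULL, K_use = NULL, ...) {
  cm <- build_class_matrix(partition, channels)
  sx <- standardize_columns(X)
  sy <- standardize_columns(cm$Y)
  model <- fit_pls(sx$Xn, sy$Xn, threshold = threshold, max_k = max_k, ...)
  model$scaling <- sx$scaling
  if (is.null(K_use)) K_use <- model$K
  list(X_hat = reconstruct(model, K_use), model = model, Y = cm$Y)
}
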