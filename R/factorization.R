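#' Factorize a voxel-by-gene matrix into principal patterns
#'
#' Decomposes the non-negative matrix `X` (`v` voxels x `n` genes) into a
#' dictionary `D` (`v x K`, columns are principal patterns, PPs) and a
#' coefficient matrix `A` (`K x n`), minimizing `||X - D A||_F^2`.
#'
#' `method = "nmf"` solves the non-negatively constrained problem by
#' coordinate descent (HALS), starting from a deterministic SVD-based
#' non-negative initialization (NNDSVD with zero entries replaced by the
#' matrix mean). Because the initialization is deterministic, refits on the
#' same data are bit-identical; the `seed` argument is carried in the result
#' for provenance but randomness only enters upstream (bootstrap resampling).
#'
#' `method = "pca"` returns the top-`K` principal components of the
#' column-mean-centred matrix: `D` holds component scores mapped back to
#' voxels (may be signed), `A` the transposed loadings, and the sign of each
#' component is fixed so that its score skewness is non-negative.
#'
#' @param X numeric matrix, voxels x genes; must be non-negative for NMF.
#' @param K number of patterns, `1 <= K <= min(dim(X))`.
#' @param method `"nmf"` or `"pca"`.
#' @param seed integer recorded with the fit (used by upstream resampling).
#' @param tol relative stopping tolerance on the loss decrease.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return An object of class `pp_fit`: `D`, `A`, `method`, `K`, `loss`
#'   (`||X - D A||_F^2` at the returned factors), `loss_trace` (per-sweep,
#'   NMF only), `center` (PCA column means), `components` (PCA orthonormal
#'   loadings), `seed`, and `zero_columns` (indices of all-zero patterns,
#'   flagged but kept).
#' @export
fit_patterns <- function(X, K, method = c("nmf", "pca"), seed = 1L,
                         tol = 1e-4, max_iter = 200L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  K <- as.integer(K)
  if (K < 1L || K > min(dim(X)))
    stop(sprintf("K must be in [1, %d]", min(dim(X))))
  if (method == "nmf" && any(X < 0))
    stop("X must be non-negative for method = 'nmf'")

  if (method == "nmf") {
    init <- nndsvd_init(X, K)
    res <- nmf_hals_cpp(X, init$W, init$H, as.integer(max_iter), tol)
    D <- res$W
    A <- res$H
    loss <- res$trace[length(res$trace)]
    zero_cols <- which(colSums(D) == 0)
    if (length(zero_cols))
      warning("NMF returned all-zero pattern(s): ",
              paste(zero_cols, collapse = ", "))
    out <- list(D = D, A = A, method = "nmf", K = K, loss = loss,
                loss_trace = res$trace, center = NULL, components = NULL,
                seed = as.integer(seed), zero_columns = zero_cols)
  } else {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    sv <- svd(Xc, nu = K, nv = K)
    D <- sv$u %*% diag(sv$d[seq_len(K)], K, K)  # component scores per voxel
    V <- sv$v                                    # orthonormal loadings
    # pin the sign: score skewness non-negative
    for (k in seq_len(K)) {
      z <- D[, k] - mean(D[, k])
      sk <- mean(z^3)
      if (sk < 0) { D[, k] <- -D[, k]; V[, k] <- -V[, k] }
    }
    A <- t(V)
    loss <- sum((Xc - D %*% A)^2)
    out <- list(D = D, A = A, method = "pca", K = K, loss = loss,
                loss_trace = NULL, center = ctr, components = V,
                seed = as.integer(seed), zero_columns = integer(0))
  }
  colnames(out$A) <- colnames(X)
  class(out) <- "pp_fit"
  out
}

#' @export
print.pp_fit <- function(x, ...) {
  cat(sprintf("<pp_fit> %s, K = %d, %d voxels x %d genes, loss = %.6g\n",
              x$method, x$K, nrow(x$D), ncol(x$A), x$loss))
  invisible(x)
}

# Deterministic NNDSVD initialization (Boutsidis & Gallopoulos); zero entries
# replaced with the matrix mean ("nndsvda") so coordinate descent cannot lock
# components at zero.
nndsvd_init <- function(X, K) {
  sv <- svd(X, nu = K, nv = K)
  W <- matrix(0, nrow(X), K)
  H <- matrix(0, K, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (K >= 2L) {
    for (k in 2:K) {
      u <- sv$u[, k]; v <- sv$v[, k]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        scale <- sqrt(sv$d[k] * nup * nvp)
        if (nup > 0 && nvp > 0) {
          W[, k] <- scale * up / nup
          H[k, ] <- scale * vp / nvp
        }
      } else {
        scale <- sqrt(sv$d[k] * nun * nvn)
        if (nun > 0 && nvn > 0) {
          W[, k] <- scale * un / nun
          H[k, ] <- scale * vn / nvn
        }
      }
    }
  }
  avg <- mean(X)
  W[W == 0] <- avg
  H[H == 0] <- avg
  list(W = W, H = H)
}

#' Reconstruct the data matrix from a fit
#'
#' @param fit a `pp_fit` from [fit_patterns()].
#' @return The reconstructed `v x n` matrix `D %*% A` (plus the column means
#'   for PCA fits).
#' @export
reconstruct <- function(fit) {
  stopifnot(inherits(fit, "pp_fit"))
  R <- fit$D %*% fit$A
  if (!is.null(fit$center)) R <- sweep(R, 2L, fit$center, `+`)
  R
}

#' Per-gene reconstruction accuracy
#'
#' The Pearson correlation between each gene's original and reconstructed
#' column. Zero-variance columns (in either the data or the reconstruction)
#' yield `NA`.
#'
#' @param X the original voxel-by-gene matrix.
#' @param fit a `pp_fit` on the same matrix.
#' @return Numeric vector of length `ncol(X)`, named by gene when `X` has
#'   column names.
#' @export
reconstruction_accuracy <- function(X, fit) {
  stopifnot(inherits(fit, "pp_fit"))
  X <- as.matrix(X)
  R <- reconstruct(fit)
  if (!all(dim(X) == dim(R))) stop("fit shape does not match X")
  out <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; r <- R[, j]
    if (sd(x) == 0 || sd(r) == 0) return(undefined_sentinel())
    cor(x, r)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
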