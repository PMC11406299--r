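# Half-space neighbour offsets for a given 3D connectivity. Each row is one
# offset; using only "positive" offsets enumerates every unordered neighbour
# pair exactly once.
half_offsets <- function(connectivity = 6L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(offs != 0L)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1L, "18" = nz >= 1L & nz <= 2L, "26" = nz >= 1L)
  offs <- offs[keep, , drop = FALSE]
  # keep one representative of each +/- pair (lexicographically positive)
  pos <- offs[, 3] > 0L | (offs[, 3] == 0L & offs[, 2] > 0L) |
    (offs[, 3] == 0L & offs[, 2] == 0L & offs[, 1] > 0L)
  offs[pos, , drop = FALSE]
}

# Linear indices of all (src, dst = src + offset) voxel pairs inside a grid.
offset_index_pairs <- function(dims, off) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - off[a]); hi <- min(dims[a], dims[a] - off[a])
    if (lo > hi) integer(0) else lo:hi
  })
  if (!all(lengths(rng) > 0)) return(list(src = integer(0), dst = integer(0)))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  src <- g$x + (g$y - 1L) * dims[1] + (g$z - 1L) * dims[1] * dims[2]
  dst <- (g$x + off[1]) + (g$y + off[2] - 1L) * dims[1] +
    (g$z + off[3] - 1L) * dims[1] * dims[2]
  list(src = as.integer(src), dst = as.integer(dst))
}

#' Global Moran's I of a 3D field
#'
#' The classical global spatial autocorrelation statistic
#' `I = (v / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with `z` the
#' mean-centred in-mask values and binary symmetric weights `w_ij = 1` for
#' voxel pairs adjacent under the chosen connectivity (both in-mask), not
#' row-standardized. Values near 1 indicate spatially coherent fields; the
#' expectation under spatial randomness is `-1 / (v - 1)`.
#'
#' @param volume numeric 3D array on the mask's grid.
#' @param mask a [voxel_mask()] with at least 2 in-mask voxels.
#' @param connectivity neighbourhood: 6 (faces, default), 18 or 26.
#' @return Scalar in `[-1, 1]` (approximately); `NA` for a zero-variance
#'   field.
#' @export
morans_I <- function(volume, mask, connectivity = 6L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (mask$v == 0L) stop("empty mask")
  if (!identical(as.integer(dim(volume)), mask$grid$dims))
    stop("volume shape does not match mask grid")
  vals <- volume[mask$inside]
  if (mask$v < 2L || sd(vals) == 0) {
    warning("zero-variance field; Moran's I undefined")
    return(undefined_sentinel())
  }
  z3 <- array(0, mask$grid$dims)
  z3[mask$inside] <- vals - mean(vals)
  dims <- mask$grid$dims
  S0 <- 0; cross <- 0
  offs <- half_offsets(connectivity)
  for (i in seq_len(nrow(offs))) {
    pr <- offset_index_pairs(dims, offs[i, ])
    keep <- mask$inside[pr$src] & mask$inside[pr$dst]
    S0 <- S0 + 2 * sum(keep)
    cross <- cross + 2 * sum(z3[pr$src[keep]] * z3[pr$dst[keep]])
  }
  if (S0 == 0) {
    warning("no in-mask neighbour pairs; Moran's I undefined")
    return(undefined_sentinel())
  }
  (mask$v / S0) * cross / sum((vals - mean(vals))^2)
}

#' Dice similarity of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint masks, `NA` when both are empty.
#'
#' @param maskA,maskB logical (or 0/1 numeric) arrays of identical shape.
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
dice <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("masks have different shapes")
  a <- as.logical(maskA); b <- as.logical(maskB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(undefined_sentinel())
  2 * sum(a & b) / denom
}

#' Binarize a pattern at a quantile threshold
#'
#' Thresholds a PP at its `q`-quantile over in-mask voxels, the binarization
#' used before Dice comparisons of patterns against region masks.
#'
#' @param pp numeric 3D array or in-mask vector.
#' @param mask a [voxel_mask()].
#' @param q quantile in (0, 1), default 0.9 (top decile support).
#' @return Logical 3D array (FALSE outside the mask).
#' @export
binarize_pp <- function(pp, mask, q = 0.9) {
  vals <- pp_in_mask(pp, mask)
  thr <- quantile(vals, q, names = FALSE)
  out <- array(FALSE, mask$grid$dims)
  out[mask$voxels[vals > thr]] <- TRUE
  out
}

pp_in_mask <- function(pp, mask) {
  if (is.array(pp) && length(dim(pp)) == 3L) {
    if (!identical(as.integer(dim(pp)), mask$grid$dims))
      stop("pattern shape does not match mask grid")
    pp[mask$inside]
  } else {
    pp <- as.numeric(pp)
    if (length(pp) != mask$v)
      stop("pattern length does not match in-mask voxel count")
    pp
  }
}

#' Bootstrap comparison of spatial coherence between methods
#'
#' For each of `n_boot` bootstrap resamples of the gene columns, fits both
#' NMF and PCA at the same `K` and records the global Moran's I of every
#' resulting pattern, giving `n_boot * K` rows per method.
#'
#' @param X non-negative voxel-by-gene matrix (rows = in-mask voxels).
#' @param mask the [voxel_mask()] that flattened `X`.
#' @param K number of patterns for both methods.
#' @param n_boot bootstrap resamples (default 20).
#' @param seed integer seed.
#' @param connectivity Moran's I neighbourhood.
#' @param tol,max_iter solver controls.
#' @return A data frame with columns `method`, `pp_index`, `boot_index`,
#'   `morans_I`.
#' @export
compare_spatial_coherence <- function(X, mask, K, n_boot = 20L, seed = 1L,
                                      connectivity = 6L,
                                      tol = 1e-4, max_iter = 200L) {
  X <- as.matrix(X)
  if (nrow(X) != mask$v) stop("nrow(X) must equal in-mask voxel count")
  n <- ncol(X)
  rows <- vector("list", 2L * n_boot)
  ri <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(as.integer(seed) + b)
    Xb <- X[, sample.int(n, n, replace = TRUE), drop = FALSE]
    for (method in c("nmf", "pca")) {
      fit <- fit_patterns(Xb, K, method = method, seed = seed,
                          tol = tol, max_iter = max_iter)
      mi <- vapply(seq_len(K), function(k) {
        suppressWarnings(morans_I(unmask(fit$D[, k], mask), mask,
                                  connectivity = connectivity))
      }, numeric(1))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(method = method, pp_index = seq_len(K),
                               boot_index = b, morans_I = mi)
    }
  }
  do.call(rbind, rows)
}
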