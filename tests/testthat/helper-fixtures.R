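# Shared fixtures and independent oracles used across the suite.

# small full-grid mask
full_mask <- function(dims) voxel_mask(array(TRUE, dims), pp_grid(dims))

# deterministic ramp volume f(x, y, z) = x + 10 y + 100 z
ramp_volume <- function(dims) {
  coords <- arrayInd(seq_len(prod(dims)), dims)
  array(coords[, 1] + 10 * coords[, 2] + 100 * coords[, 3], dims)
}

# random non-negative dictionary
random_dict <- function(v, K, seed) {
  set.seed(seed)
  matrix(rgamma(v * K, shape = 2), v, K)
}

# ORACLE: dictionary dissimilarity by exhaustive search over all K!
# column permutations, minimizing the mean (1 - matched correlation).
brute_dsim <- function(D, D2) {
  C <- suppressWarnings(cor(D, D2))
  C[!is.finite(C)] <- 0
  K <- ncol(C)
  perms <- all_permutations(K)
  best <- Inf
  for (p in seq_len(nrow(perms))) {
    val <- mean(1 - C[cbind(seq_len(K), perms[p, ])])
    if (val < best) best <- val
  }
  best
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# ORACLE: direct evaluation of the Amari-type dissimilarity formula.
brute_amari <- function(D, D2) {
  C <- suppressWarnings(cor(D, D2))
  C[!is.finite(C)] <- 0
  K <- ncol(C)
  (2 * K - sum(apply(C, 2, max)) - sum(apply(C, 1, max))) / (2 * K)
}

# ORACLE: region adjacency by scanning every voxel's neighbourhood.
brute_adjacency_pairs <- function(labels, connectivity = 26L) {
  dims <- dim(labels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  nz <- rowSums(offs != 0)
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz <= 2, , drop = FALSE],
                 "26" = offs)
  idx <- which(labels > 0)
  coords <- arrayInd(idx, dims)
  acc <- list()
  for (i in seq_along(idx)) {
    li <- labels[idx[i]]
    nb <- sweep(offs, 2L, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    lj <- labels[nb]
    lj <- lj[lj > 0 & lj != li]
    if (length(lj))
      acc[[length(acc) + 1L]] <- cbind(pmin(li, lj), pmax(li, lj))
  }
  if (!length(acc)) return(matrix(integer(0), 0, 2))
  found <- unique(do.call(rbind, acc))
  found[order(found[, 1], found[, 2]), , drop = FALSE]
}

# ORACLE: dense-matrix Moran's I with explicit weight matrix.
dense_morans_I <- function(volume, inside, connectivity = 6L) {
  dims <- dim(volume)
  idx <- which(inside)
  v <- length(idx)
  coords <- arrayInd(idx, dims)
  W <- matrix(0, v, v)
  for (i in seq_len(v)) for (j in seq_len(v)) {
    d <- abs(coords[i, ] - coords[j, ])
    touch <- switch(as.character(connectivity),
                    "6" = sum(d) == 1,
                    "18" = max(d) == 1 && sum(d) <= 2,
                    "26" = max(d) == 1)
    if (i != j && touch) W[i, j] <- 1
  }
  z <- volume[idx] - mean(volume[idx])
  (v / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# small planted study shared by several tests
tiny_study <- function(seed = 3, dims = c(14, 12, 10), n_regions = 8,
                       n_genes = 60, K_true = 3, noise_sd = 0.05,
                       missing_frac = 0.1) {
  atlas <- make_atlas(dims, n_regions, seed = seed)
  sim <- make_expression(atlas, n_genes = n_genes, K_true = K_true,
                         noise_sd = noise_sd, missing_frac = missing_frac,
                         seed = seed)
  mask <- atlas_brain_mask(atlas)
  list(atlas = atlas, sim = sim, mask = mask)
}
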