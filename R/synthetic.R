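# Separable 3D Gaussian smoothing by per-axis convolution matrices
# (zero-padded boundaries). Kernel radius 3*sd.
smooth_gaussian_3d <- function(arr, sd = 1) {
  if (sd <= 0) return(arr)
  dims <- dim(arr)
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - r):pmin(n, i + r)
      M[i, j] <- k[j - i + r + 1L]
    }
    M
  }
  # axis 1
  arr <- array(conv_mat(dims[1]) %*% matrix(arr, dims[1]), dims)
  # axis 2
  p <- aperm(arr, c(2, 1, 3))
  p <- array(conv_mat(dims[2]) %*% matrix(p, dims[2]), dim(p))
  arr <- aperm(p, c(2, 1, 3))
  # axis 3
  p <- aperm(arr, c(3, 1, 2))
  p <- array(conv_mat(dims[3]) %*% matrix(p, dims[3]), dim(p))
  aperm(p, c(2, 3, 1))
}

#' Generate a blocky labeled atlas with a two-level ontology
#'
#' Partitions an ellipsoidal "brain" (leaving a background shell of zeros)
#' into `n_regions` Voronoi cells grown from randomly placed seed voxels, and
#' groups the regions into coarse parents (about one parent per four
#' regions, by k-means on the seed coordinates), giving a two-level
#' parent/child ontology like real anatomical atlases.
#'
#' @param dims grid dimensions (integer triple) or a [pp_grid()].
#' @param n_regions number of child regions (>= 2).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param voxel_size voxel edge lengths in micrometres.
#' @return A [brain_atlas()] whose child labels are `1..n_regions` (level 2)
#'   and parent labels `n_regions + 1, ...` (level 1, not present in the
#'   volume).
#' @export
make_atlas <- function(dims, n_regions, seed = 1L,
                       voxel_size = c(200, 200, 200)) {
  grid <- if (inherits(dims, "pp_grid")) dims else pp_grid(dims, voxel_size)
  dims <- grid$dims
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be >= 2")
  ctr <- (dims + 1) / 2
  semi <- pmax((dims - 2) / 2, 0.5)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  inside <- ((coords[, 1] - ctr[1]) / semi[1])^2 +
    ((coords[, 2] - ctr[2]) / semi[2])^2 +
    ((coords[, 3] - ctr[3]) / semi[3])^2 <= 1
  in_idx <- which(inside)
  if (n_regions > length(in_idx))
    stop("n_regions exceeds the number of in-brain voxels")
  set.seed(seed)
  seed_idx <- sort(sample(in_idx, n_regions))
  seed_xyz <- coords[seed_idx, , drop = FALSE]
  # nearest-seed assignment; which.min ties go to the lower region label
  d2 <- outer(rep(1, length(in_idx)), rep(0, n_regions))
  for (a in 1:3)
    d2 <- d2 + outer(coords[in_idx, a], seed_xyz[, a], `-`)^2
  assign <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dims)
  labels[in_idx] <- assign
  n_parents <- max(1L, ceiling(n_regions / 4))
  parent_of <- if (n_parents == 1L) rep(1L, n_regions) else
    kmeans(seed_xyz, centers = n_parents, nstart = 5L)$cluster
  ontology <- rbind(
    data.frame(label = seq_len(n_regions),
               name = sprintf("region_%03d", seq_len(n_regions)),
               parent_label = n_regions + as.integer(parent_of),
               level = 2L, stringsAsFactors = FALSE),
    data.frame(label = n_regions + seq_len(n_parents),
               name = sprintf("domain_%02d", seq_len(n_parents)),
               parent_label = 0L, level = 1L, stringsAsFactors = FALSE))
  brain_atlas(labels, ontology, grid)
}

#' Generate a planted-factor expression tensor over an atlas
#'
#' Emulates the structure the factorization pipeline assumes: `K_true`
#' ground-truth patterns, each the Gaussian-smoothed indicator of a
#' spatially contiguous combination of 1-3 atlas regions; sparse
#' non-negative gene loadings (per-gene Dirichlet shares over a few active
#' patterns times a gamma scale); designated marker genes loading on a
#' single pattern each; additive Gaussian noise truncated at zero (ISH
#' "expression energy" grids are continuous non-negative intensities); and
#' uniformly random missing voxels.
#'
#' @param atlas a [brain_atlas()], e.g. from [make_atlas()].
#' @param n_genes number of genes (>= `K_true`).
#' @param K_true number of planted patterns.
#' @param noise_sd standard deviation of the truncated Gaussian noise, on
#'   the scale of patterns with unit maximum (default 0.05).
#' @param missing_frac fraction of voxels masked as missing per gene, in
#'   `[0, 1)` (default 0.1, the approximate missingness of 200-um ISH
#'   grids).
#' @param markers_per_pp marker genes planted per pattern (default 3).
#' @param smooth_sd Gaussian smoothing of the indicator patterns, in voxels
#'   (default 1, soft boundaries like ISH energy data).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return A list with `tensor` (an [expression_tensor()] on the atlas
#'   grid) and `truth` (class `synthetic_truth`: `atlas`, `mask`, `D_true`
#'   (in-mask `v x K_true`), `A_true` (`K_true x n_genes`), `combo_map`
#'   (list of region-label vectors per pattern), `marker_map` (list of gene
#'   names per pattern), `noise_sd`, `missing_frac`, `seed`).
#' @export
make_expression <- function(atlas, n_genes = 200L, K_true = 5L,
                            noise_sd = 0.05, missing_frac = 0.1,
                            markers_per_pp = 3L, smooth_sd = 1,
                            seed = 1L) {
  stopifnot(inherits(atlas, "brain_atlas"))
  n_genes <- as.integer(n_genes)
  K_true <- as.integer(K_true)
  if (n_genes < K_true) stop("n_genes must be >= K_true")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  mask <- atlas_brain_mask(atlas)
  adj <- build_adjacency(atlas)
  child <- atlas$ontology$label[atlas$ontology$level ==
                                  max(atlas$ontology$level)]
  child <- intersect(child, unique(atlas$labels[atlas$labels > 0L]))

  set.seed(seed)
  # target combination sizes cycle 1,2,3; picked greedily so regions are not
  # reused across patterns (keeps the planted patterns identifiable)
  sizes <- rep_len(c(1L, 2L, 3L), K_true)
  combos <- vector("list", K_true)
  used <- integer(0)
  pool <- list(`1` = matrix(child, ncol = 1L), `2` = adj$pairs,
               `3` = adj$triples)
  for (k in seq_len(K_true)) {
    found <- FALSE
    for (sz in unique(c(sizes[k], 2L, 1L, 3L))) {
      cand <- pool[[as.character(sz)]]
      if (!nrow(cand)) next
      fresh <- which(apply(cand, 1L, function(r) !any(r %in% used)))
      rows <- if (length(fresh)) fresh else seq_len(nrow(cand))
      pick <- rows[sample.int(length(rows), 1L)]
      combos[[k]] <- as.integer(cand[pick, ])
      used <- c(used, combos[[k]])
      found <- TRUE
      break
    }
    if (!found) stop("atlas has too few contiguous combinations for K_true")
  }

  # Normalized (mask-aware) convolution: dividing by the smoothed brain
  # indicator keeps patterns from decaying at the brain boundary, where real
  # expression energy does not attenuate.
  brain_sm <- smooth_gaussian_3d(array(as.numeric(mask$inside),
                                       atlas$grid$dims), smooth_sd)
  D_true <- matrix(0, mask$v, K_true)
  for (k in seq_len(K_true)) {
    vol <- smooth_gaussian_3d(region_mask(atlas, combos[[k]]), smooth_sd) /
      pmax(brain_sm, 1e-12)
    col <- vol[mask$inside]
    D_true[, k] <- col / max(col)
  }

  n_markers <- min(markers_per_pp * K_true, n_genes)
  A_true <- matrix(0, K_true, n_genes)
  genes <- character(n_genes)
  marker_map <- vector("list", K_true)
  gi <- 0L
  for (k in seq_len(K_true)) {
    mk <- character(0)
    for (m in seq_len(markers_per_pp)) {
      if (gi >= n_markers) break
      gi <- gi + 1L
      genes[gi] <- sprintf("marker_pp%d_%d", k, m)
      A_true[k, gi] <- rgamma(1L, shape = 5, rate = 2) + 0.5
      mk <- c(mk, genes[gi])
    }
    marker_map[[k]] <- mk
  }
  # Non-marker genes load on >= 2 patterns with no share above 0.85, so
  # pattern exclusivity is what identifies the planted markers.
  for (j in seq_len(n_genes - gi) + gi) {
    genes[j] <- sprintf("gene_%04d", j)
    n_active <- if (K_true == 1L) 1L else sample(2:min(3L, K_true), 1L)
    active <- sample.int(K_true, n_active)
    repeat {
      shares <- rgamma(n_active, shape = 2, rate = 1)
      shares <- shares / sum(shares)
      if (n_active == 1L || max(shares) <= 0.85) break
    }
    A_true[active, j] <- shares * (rgamma(1L, shape = 3, rate = 2) + 0.2)
  }

  vtot <- grid_n_voxels(atlas$grid)
  vals <- array(0, dim = c(atlas$grid$dims, n_genes))
  Xin <- D_true %*% A_true
  if (noise_sd > 0)
    Xin <- pmax(Xin + matrix(rnorm(length(Xin), sd = noise_sd), nrow(Xin)), 0)
  step <- vtot
  for (j in seq_len(n_genes)) vals[mask$voxels + (j - 1L) * step] <- Xin[, j]

  missing <- array(FALSE, dim = dim(vals))
  if (missing_frac > 0) {
    n_miss <- round(missing_frac * vtot)
    for (j in seq_len(n_genes)) {
      mi <- sample.int(vtot, n_miss)
      missing[mi + (j - 1L) * step] <- TRUE
    }
  }
  tensor <- expression_tensor(vals, genes, atlas$grid, missing = missing)
  truth <- structure(list(atlas = atlas, mask = mask, D_true = D_true,
                          A_true = A_true, combo_map = combos,
                          marker_map = marker_map, noise_sd = noise_sd,
                          missing_frac = missing_frac,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(tensor = tensor, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted patterns over %d regions (noise_sd = %g, missing = %g)\n",
              ncol(x$D_true), length(unique(x$atlas$labels[x$atlas$labels > 0])),
              x$noise_sd, x$missing_frac))
  invisible(x)
}
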