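#' Morphological region adjacency of an atlas
#'
#' Two regions are spatially contiguous when the one-step binary dilation of
#' one overlaps the other, which for a single dilation step is exactly voxel
#' contact under the structuring element's connectivity (default: the full
#' 3x3x3 cube, 26-connectivity). Triples extend pairs: `{i, j, l}` is listed
#' when `{i, j}` is a contiguous pair and the dilated third region `l`
#' overlaps at least one of `i` or `j` (i.e. `{i, l}` or `{j, l}` is itself a
#' pair).
#'
#' @param atlas a [brain_atlas()].
#' @param connectivity structuring element: 26 (3x3x3 cube, default), 18, 6.
#' @param max_combo_size 2 to skip triple enumeration, 3 (default) for both.
#' @return An object of class `adjacency_list` with `pairs` (m x 2 integer
#'   matrix, each row sorted ascending) and `triples` (t x 3, sorted rows),
#'   both ordered lexicographically.
#' @export
build_adjacency <- function(atlas, connectivity = 26L, max_combo_size = 3L) {
  stopifnot(inherits(atlas, "brain_atlas"))
  labels <- atlas$labels
  dims <- atlas$grid$dims
  offs <- half_offsets(connectivity)
  acc <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    pr <- offset_index_pairs(dims, offs[i, ])
    la <- labels[pr$src]; lb <- labels[pr$dst]
    sel <- la > 0L & lb > 0L & la != lb
    if (any(sel))
      acc[[i]] <- cbind(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel]))
  }
  pairs <- unique(do.call(rbind, acc))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0L, 2L)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  triples <- matrix(integer(0), 0L, 3L)
  if (max_combo_size >= 3L && nrow(pairs) > 0L) {
    nb <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
    tri <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      cand <- setdiff(unique(c(nb[[as.character(i)]], nb[[as.character(j)]])),
                      c(i, j))
      if (length(cand)) {
        trip <- cbind(i, j, cand)
        tri[[p]] <- t(apply(trip, 1L, sort))
      }
    }
    triples <- unique(do.call(rbind, tri))
    if (is.null(triples)) triples <- matrix(integer(0), 0L, 3L)
    if (nrow(triples))
      triples <- triples[order(triples[, 1], triples[, 2], triples[, 3]),
                         , drop = FALSE]
  }
  storage.mode(pairs) <- "integer"
  storage.mode(triples) <- "integer"
  colnames(pairs) <- c("label_i", "label_j")
  if (ncol(triples) == 3L) colnames(triples) <- c("label_i", "label_j", "label_l")
  structure(list(pairs = pairs, triples = triples,
                 connectivity = as.integer(connectivity)),
            class = "adjacency_list")
}

#' @export
print.adjacency_list <- function(x, ...) {
  cat(sprintf("<adjacency_list> %d contiguous pairs, %d contiguous triples (%d-connectivity)\n",
              nrow(x$pairs), nrow(x$triples), x$connectivity))
  invisible(x)
}

# Pearson correlation between a fixed in-mask vector y and the indicator of
# a region combination, from precomputed per-combination union size m and
# union-sum t = sum(y over union). Closed form for a binary regressor:
#   corr = (t - m * mean(y)) / sqrt(m (1 - m/v) * sum((y - mean(y))^2))
binary_pcc <- function(m, t, v, Sy, Szz) {
  num <- t - m * Sy / v
  den <- sqrt(m * (1 - m / v) * Szz)
  out <- num / den
  out[!is.finite(out)] <- undefined_sentinel()
  out
}

#' Link a pattern to its best region combination
#'
#' Exhaustively searches all single regions, all spatially contiguous pairs,
#' and all spatially contiguous triples for the combination whose normalized
#' (0/1) union mask has maximal Pearson correlation with the pattern,
#' evaluated over in-mask voxels. Region masks within an atlas are disjoint,
#' so union statistics are sums of per-region statistics and the search is
#' linear in the adjacency-list size.
#'
#' @param pp numeric 3D array on the atlas grid, or a length-`v` in-mask
#'   vector.
#' @param atlas a [brain_atlas()].
#' @param adj an [build_adjacency()] result for the atlas.
#' @param mask evaluation [voxel_mask()]; defaults to all labeled voxels.
#' @param max_combo_size search singles only (1), up to pairs (2) or up to
#'   triples (3, default).
#' @return An object of class `link_result`: `best` (list with `labels`,
#'   `names`, `size`, `pcc`) and `per_size` (same, for each combination
#'   size searched). Zero-variance patterns give an `NA` result with a
#'   warning.
#' @export
link_pp <- function(pp, atlas, adj, mask = atlas_brain_mask(atlas),
                    max_combo_size = 3L) {
  stopifnot(inherits(atlas, "brain_atlas"), inherits(adj, "adjacency_list"))
  y <- pp_in_mask(pp, mask)
  v <- mask$v
  if (sd(y) == 0) {
    warning("zero-variance pattern; link undefined")
    empty <- list(labels = integer(0), names = character(0), size = NA_integer_,
                  pcc = undefined_sentinel())
    return(structure(list(best = empty, per_size = list()),
                     class = "link_result"))
  }
  Sy <- sum(y)
  Szz <- sum((y - mean(y))^2)
  lab_in <- atlas$labels[mask$inside]
  keep <- lab_in > 0L
  counts <- tapply(rep(1L, sum(keep)), lab_in[keep], sum)
  sums <- tapply(y[keep], lab_in[keep], sum)
  labs <- as.integer(names(counts))
  n_r <- as.numeric(counts)
  s_r <- as.numeric(sums)
  idx_of <- integer(max(labs))
  idx_of[labs] <- seq_along(labs)

  per_size <- list()
  # singles
  pcc1 <- binary_pcc(n_r, s_r, v, Sy, Szz)
  b1 <- which.max(pcc1)
  per_size[["1"]] <- combo_entry(labs[b1], pcc1[b1], atlas)
  # pairs
  if (max_combo_size >= 2L && nrow(adj$pairs)) {
    i <- idx_of[adj$pairs[, 1]]; j <- idx_of[adj$pairs[, 2]]
    ok <- i > 0L & j > 0L
    if (any(ok)) {
      m <- n_r[i[ok]] + n_r[j[ok]]
      t2 <- s_r[i[ok]] + s_r[j[ok]]
      pcc2 <- binary_pcc(m, t2, v, Sy, Szz)
      b2 <- which.max(pcc2)
      per_size[["2"]] <- combo_entry(adj$pairs[which(ok)[b2], ], pcc2[b2], atlas)
    }
  }
  # triples
  if (max_combo_size >= 3L && nrow(adj$triples)) {
    i <- idx_of[adj$triples[, 1]]; j <- idx_of[adj$triples[, 2]]
    l <- idx_of[adj$triples[, 3]]
    ok <- i > 0L & j > 0L & l > 0L
    if (any(ok)) {
      m <- n_r[i[ok]] + n_r[j[ok]] + n_r[l[ok]]
      t3 <- s_r[i[ok]] + s_r[j[ok]] + s_r[l[ok]]
      pcc3 <- binary_pcc(m, t3, v, Sy, Szz)
      b3 <- which.max(pcc3)
      per_size[["3"]] <- combo_entry(adj$triples[which(ok)[b3], ], pcc3[b3], atlas)
    }
  }
  pccs <- vapply(per_size, function(e) e$pcc, numeric(1))
  best <- per_size[[which.max(pccs)]]
  structure(list(best = best, per_size = per_size), class = "link_result")
}

combo_entry <- function(labels, pcc, atlas) {
  labels <- sort(as.integer(labels))
  nm <- atlas$ontology$name[match(labels, atlas$ontology$label)]
  list(labels = labels, names = nm, size = length(labels), pcc = as.numeric(pcc))
}

#' @export
print.link_result <- function(x, ...) {
  if (!length(x$best$labels)) {
    cat("<link_result> undefined (zero-variance pattern)\n")
    return(invisible(x))
  }
  cat(sprintf("<link_result> best: {%s} (PCC = %.3f)\n",
              paste(x$best$names, collapse = ", "), x$best$pcc))
  invisible(x)
}

#' Pattern-by-region correlation table
#'
#' Pearson correlation between every dictionary column and the normalized
#' (0/1) mask of each requested region, over in-mask voxels.
#'
#' @param D `v x K` dictionary (or `pp_fit`), rows = in-mask voxels.
#' @param atlas a [brain_atlas()].
#' @param region_subset labels to include (default: all labels present in
#'   the volume). Unknown labels are an error.
#' @param mask evaluation [voxel_mask()]; defaults to all labeled voxels.
#' @return `K x length(region_subset)` matrix, columns named by region name.
#' @export
correlation_table <- function(D, atlas, region_subset = NULL,
                              mask = atlas_brain_mask(atlas)) {
  stopifnot(inherits(atlas, "brain_atlas"))
  D <- dict_matrix(D)
  if (nrow(D) != mask$v) stop("dictionary rows must match in-mask voxels")
  present <- sort(unique(atlas$labels[atlas$labels > 0L]))
  if (is.null(region_subset)) region_subset <- present
  region_subset <- as.integer(region_subset)
  unknown <- setdiff(region_subset, atlas$ontology$label)
  if (length(unknown))
    stop("unknown region labels: ", paste(unknown, collapse = ", "))
  lab_in <- atlas$labels[mask$inside]
  v <- mask$v
  out <- matrix(NA_real_, ncol(D), length(region_subset))
  for (ri in seq_along(region_subset)) {
    ind <- as.numeric(lab_in == region_subset[ri])
    m <- sum(ind)
    for (k in seq_len(ncol(D))) {
      y <- D[, k]
      Szz <- sum((y - mean(y))^2)
      out[k, ri] <- binary_pcc(m, sum(y[ind == 1]), v, sum(y), Szz)
    }
  }
  dimnames(out) <- list(paste0("PP", seq_len(ncol(D))),
                        atlas$ontology$name[match(region_subset,
                                                  atlas$ontology$label)])
  out
}

#' Expression-defined ontology report from link results
#'
#' Collates one [link_pp()] result per pattern into a hierarchical report
#' (pattern -> member regions, with the combination PCC and each member's
#' single-region PCC), ordered by descending combination PCC.
#'
#' @param links list of `link_result`s, one per pattern, in pattern order.
#' @param atlas the [brain_atlas()] that was linked against.
#' @param D optional dictionary used to add per-member single-region PCCs.
#' @param mask evaluation mask (used with `D`).
#' @return A list (class `pp_ontology`) of entries `pp_index`, `pcc`,
#'   `regions` (label, name, member_pcc), serializable with
#'   [write_ontology_json()].
#' @export
export_ontology <- function(links, atlas, D = NULL,
                            mask = atlas_brain_mask(atlas)) {
  stopifnot(is.list(links))
  if (!is.null(D)) D <- dict_matrix(D)
  entries <- lapply(seq_along(links), function(k) {
    b <- links[[k]]$best
    member_pcc <- rep(NA_real_, length(b$labels))
    if (!is.null(D) && length(b$labels)) {
      ct <- correlation_table(D[, k, drop = FALSE], atlas, b$labels, mask)
      member_pcc <- as.numeric(ct[1L, ])
    }
    list(pp_index = k, pcc = b$pcc,
         regions = data.frame(label = b$labels, name = b$names,
                              member_pcc = member_pcc,
                              stringsAsFactors = FALSE))
  })
  ord <- order(vapply(entries, function(e) e$pcc, numeric(1)),
               decreasing = TRUE)
  structure(entries[ord], class = "pp_ontology")
}

#' @rdname export_ontology
#' @param ontology a `pp_ontology` from [export_ontology()].
#' @param path output JSON file.
#' @export
write_ontology_json <- function(ontology, path) {
  stopifnot(inherits(ontology, "pp_ontology"))
  jsonlite::write_json(unclass(ontology), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
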