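#' Assign genes to patterns and score their importance
#'
#' Each gene is assigned to the pattern with the highest coefficient (ties
#' go to the lowest pattern index). The importance score of gene `j` is the
#' share of its total coefficient mass carried by the assigned pattern,
#' `r_j = a[assigned, j] / sum_k a[k, j]`, a value in `[0, 1]`. Genes whose
#' coefficients are all zero are assigned to no pattern and get `NA`.
#'
#' @param A non-negative `K x n` coefficient matrix (or a `pp_fit`).
#' @param genes optional gene identifiers (defaults to `colnames(A)` or
#'   `gene_<j>`).
#' @return A `marker_table` data frame with columns `gene`, `assigned_pp`,
#'   `coefficient`, `importance`, `rank` (rank by descending importance
#'   within the assigned pattern; ties broken by gene identifier).
#' @export
assign_and_score <- function(A, genes = NULL) {
  if (inherits(A, "pp_fit")) A <- A$A
  A <- as.matrix(A)
  if (any(A < 0)) stop("coefficients must be non-negative")
  n <- ncol(A)
  if (is.null(genes)) genes <- colnames(A) %||% sprintf("gene_%04d", seq_len(n))
  totals <- colSums(A)
  assigned <- apply(A, 2L, which.max)     # which.max takes the lowest on ties
  coefficient <- A[cbind(assigned, seq_len(n))]
  importance <- ifelse(totals > 0, coefficient / totals, NA_real_)
  assigned[totals == 0] <- NA_integer_
  coefficient[totals == 0] <- NA_real_
  tbl <- data.frame(gene = genes, assigned_pp = as.integer(assigned),
                    coefficient = coefficient, importance = importance,
                    stringsAsFactors = FALSE)
  tbl$rank <- NA_integer_
  for (k in unique(stats::na.omit(tbl$assigned_pp))) {
    idx <- which(tbl$assigned_pp == k)
    ord <- order(-tbl$importance[idx], tbl$gene[idx])
    tbl$rank[idx[ord]] <- seq_along(idx)
  }
  class(tbl) <- c("marker_table", "data.frame")
  tbl
}

#' Number of patterns represented in each gene
#'
#' Counts, per gene, the patterns whose share of the gene's total
#' coefficient mass exceeds `rel_threshold`. All-zero genes count 0.
#'
#' @param A non-negative `K x n` coefficient matrix (or `pp_fit`).
#' @param rel_threshold minimal share for a pattern to count (default 0.01).
#' @return Integer vector of length `n`.
#' @export
pp_count_per_gene <- function(A, rel_threshold = 0.01) {
  if (inherits(A, "pp_fit")) A <- A$A
  A <- as.matrix(A)
  if (any(A < 0)) stop("coefficients must be non-negative")
  totals <- colSums(A)
  shares <- sweep(A, 2L, ifelse(totals > 0, totals, 1), `/`)
  counts <- colSums(shares > rel_threshold)
  counts[totals == 0] <- 0L
  as.integer(counts)
}

#' Top marker genes of a pattern
#'
#' @param table a `marker_table` from [assign_and_score()].
#' @param pp pattern index.
#' @param n how many markers (default 3); truncated to the number assigned.
#' @return Character vector of gene identifiers in descending importance
#'   (ties broken by identifier); empty with a warning when no gene is
#'   assigned to the pattern.
#' @export
top_markers <- function(table, pp, n = 3L) {
  stopifnot(inherits(table, "marker_table"))
  idx <- which(table$assigned_pp == pp)
  if (!length(idx)) {
    warning("no genes assigned to pattern ", pp)
    return(character(0))
  }
  ord <- idx[order(-table$importance[idx], table$gene[idx])]
  table$gene[utils::head(ord, n)]
}

#' Spatial gene coexpression network of a pattern
#'
#' Nodes are the genes assigned to the pattern whose importance scores fall
#' in the top `node_quantile` fraction of the importance distribution over
#' all scored genes (a global cutoff, so the node count per pattern scales
#' with the gene universe). Edges connect node pairs whose reconstructed
#' volumes (columns of `D A`) have a pairwise Pearson correlation in the top
#' `edge_quantile` of all node-pair correlations; the edge count is
#' `ceiling(edge_quantile * n_pairs)`, ties and ordering resolved on sorted
#' gene names so the result is independent of input order.
#'
#' @param fit a `pp_fit` (for the reconstructed volumes).
#' @param table a `marker_table` from [assign_and_score()] on the same fit.
#' @param pp pattern index.
#' @param node_quantile top fraction of importance scores kept as nodes
#'   (default 0.0025, i.e. 0.25%).
#' @param edge_quantile top fraction of pairwise correlations drawn as edges
#'   (default 0.05).
#' @return An object of class `sgcn`: `pp_index`, `nodes` (gene,
#'   selectivity = importance), `edges` (gene_a, gene_b, pcc).
#' @export
build_sgcn <- function(fit, table, pp, node_quantile = 0.0025,
                       edge_quantile = 0.05) {
  stopifnot(inherits(fit, "pp_fit"), inherits(table, "marker_table"))
  scored <- table$importance[!is.na(table$importance)]
  cutoff <- quantile(scored, 1 - node_quantile, names = FALSE)
  sel <- which(table$assigned_pp == pp & !is.na(table$importance) &
                 table$importance >= cutoff)
  if (length(sel) < 2L)
    stop(sprintf("pattern %d has %d node(s) above the importance cutoff; need >= 2",
                 pp, length(sel)))
  sel <- sel[order(table$gene[sel])]
  genes <- table$gene[sel]
  R <- reconstruct(fit)[, sel, drop = FALSE]
  C <- suppressWarnings(cor(R))
  C[!is.finite(C)] <- 0
  np <- length(genes)
  pr <- combn(np, 2L)
  pcc <- C[cbind(pr[1, ], pr[2, ])]
  n_edges <- ceiling(edge_quantile * ncol(pr))
  ord <- order(-pcc, genes[pr[1, ]], genes[pr[2, ]])
  take <- ord[seq_len(n_edges)]
  edges <- data.frame(gene_a = genes[pr[1, take]], gene_b = genes[pr[2, take]],
                      pcc = pcc[take], stringsAsFactors = FALSE)
  nodes <- data.frame(gene = genes, selectivity = table$importance[sel],
                      stringsAsFactors = FALSE)
  structure(list(pp_index = as.integer(pp), nodes = nodes, edges = edges),
            class = "sgcn")
}

#' @export
print.sgcn <- function(x, ...) {
  cat(sprintf("<sgcn> pattern %d: %d nodes, %d edges\n",
              x$pp_index, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a coexpression network as GraphML (plus TSV edge list)
#'
#' @param net an `sgcn` from [build_sgcn()].
#' @param graphml_path output GraphML file (via igraph).
#' @param tsv_path optional TSV edge list (gene_a, gene_b, pcc).
#' @return `graphml_path`, invisibly.
#' @export
write_sgcn_graphml <- function(net, graphml_path, tsv_path = NULL) {
  stopifnot(inherits(net, "sgcn"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path))
    write.table(net$edges, tsv_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  invisible(graphml_path)
}

# Area under the ROC curve by the Mann-Whitney rank statistic.
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' How well a pattern subset predicts a region
#'
#' Fits an L2-regularized logistic regression of region membership (voxels
#' as samples, standardized pattern values as features) and reports the
#' training AUC by the Mann-Whitney rank statistic, together with a null
#' distribution of AUCs from `n_null` uniformly random pattern subsets of
#' the same size (the tested subset excluded).
#'
#' @param D `v x K` dictionary (or `pp_fit`), rows = in-mask voxels.
#' @param region_mask logical length-`v` vector (or 3D array with `mask`)
#'   of region membership; both classes must be present.
#' @param pp_subset pattern indices used as features.
#' @param n_null size of the random-subset null (default 1000).
#' @param seed integer seed for the null draws.
#' @param mask optional [voxel_mask()] when `region_mask` is a 3D array.
#' @param lambda ridge penalty passed to glmnet (fixed, default 0.01).
#' @return A list with `auc` and `null_aucs` (length `n_null`).
#' @export
region_predictability <- function(D, region_mask, pp_subset, n_null = 1000L,
                                  seed = 1L, mask = NULL, lambda = 0.01) {
  D <- dict_matrix(D)
  if (is.array(region_mask) && length(dim(region_mask)) == 3L) {
    if (is.null(mask)) stop("supply mask when region_mask is a 3D array")
    region_mask <- region_mask[mask$inside]
  }
  y <- as.logical(region_mask)
  if (length(y) != nrow(D)) stop("region_mask length must match dictionary rows")
  if (sum(y) == 0L || sum(!y) == 0L)
    stop("region mask must contain both classes")
  K <- ncol(D)
  pp_subset <- sort(unique(as.integer(pp_subset)))
  if (any(pp_subset < 1L | pp_subset > K)) stop("pp_subset out of range")
  fit_auc <- function(subset) {
    x <- D[, subset, drop = FALSE]
    keep <- apply(x, 2L, sd) > 0
    if (!any(keep)) return(0.5)
    x <- scale(x[, keep, drop = FALSE])
    if (ncol(x) == 1L) x <- cbind(x, x)  # glmnet needs >= 2 columns; a
                                         # duplicated feature leaves the
                                         # fitted score (and AUC) unchanged
    fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    score <- as.numeric(stats::predict(fit, newx = x, s = lambda))
    auc_rank(score, y)
  }
  auc <- fit_auc(pp_subset)
  set.seed(seed)
  size <- length(pp_subset)
  null_aucs <- numeric(n_null)
  for (i in seq_len(n_null)) {
    repeat {
      subset <- sort(sample.int(K, size))
      if (!identical(subset, pp_subset)) break
    }
    null_aucs[i] <- fit_auc(subset)
  }
  list(auc = auc, null_aucs = null_aucs)
}
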