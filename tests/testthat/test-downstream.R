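test_that("gene assignment and importance follow the coefficient shares", {
  A <- rbind(c(0, 2, 1 / 11, 0),
             c(0, 6, 1 / 11, 0),
             c(3, 2, 1 / 11, 0))
  A <- rbind(A, matrix(1 / 11, 8, 4))  # K = 11 with a uniform gene
  A[4:11, 1:2] <- 0; A[4:11, 4] <- 0
  colnames(A) <- c("only3", "mixed", "uniform", "allzero")
  tbl <- assign_and_score(A)
  expect_equal(tbl$assigned_pp[tbl$gene == "only3"], 3L)
  expect_equal(tbl$importance[tbl$gene == "only3"], 1.0)
  expect_equal(tbl$assigned_pp[tbl$gene == "mixed"], 2L)
  expect_equal(tbl$importance[tbl$gene == "mixed"], 0.6)
  # uniform coefficients: tie broken to PP 1, share = 1/11
  expect_equal(tbl$assigned_pp[tbl$gene == "uniform"], 1L)
  expect_equal(tbl$importance[tbl$gene == "uniform"], 1 / 11)
  expect_true(is.na(tbl$assigned_pp[tbl$gene == "allzero"]))
  expect_true(is.na(tbl$importance[tbl$gene == "allzero"]))
})

test_that("importance shares sum to one for genes with nonzero coefficients", {
  set.seed(21)
  A <- matrix(rgamma(5 * 30, 0.5), 5, 30)
  A[, 7] <- 0
  totals <- colSums(A)
  shares <- sweep(A, 2, ifelse(totals > 0, totals, 1), "/")
  expect_equal(colSums(shares)[totals > 0], rep(1, sum(totals > 0)),
               ignore_attr = TRUE)
  tbl <- assign_and_score(A)
  expect_true(all(tbl$importance[!is.na(tbl$importance)] >= 1 / 5 - 1e-12))
})

test_that("pattern counts per gene respect the share threshold", {
  A <- cbind(c(0.5, 0.3, 0.15, 0.05, 0),    # 4 shares above 1%
             c(1, 0, 0, 0, 0),
             rep(0, 5),
             c(0.989, 0.005, 0.002, 0.002, 0.002))
  expect_equal(pp_count_per_gene(A, rel_threshold = 0.01), c(4L, 1L, 0L, 1L))
  expect_equal(pp_count_per_gene(A, rel_threshold = 0.001), c(4L, 1L, 0L, 5L))
})

test_that("top markers are ordered by importance with identifier tie-breaks", {
  A <- matrix(0, 2, 5)
  A[1, ] <- c(1, 0.8, 0.8, 0.2, 0)
  A[2, ] <- c(0, 0.2, 0.2, 0.8, 1)
  colnames(A) <- c("a", "zz", "bb", "c", "d")
  tbl <- assign_and_score(A)
  expect_equal(top_markers(tbl, 1, 3), c("a", "bb", "zz"))
  expect_equal(top_markers(tbl, 2, 10), c("d", "c"))  # truncation to assigned
  expect_warning(mk <- top_markers(assign_and_score(matrix(c(1, 0), 2, 1)), 2),
                 "no genes")
  expect_equal(mk, character(0))
})

test_that("planted markers are recovered with precision 1", {
  st <- tiny_study(seed = 22, n_genes = 80, noise_sd = 0.02)
  X <- assemble_matrix(impute_knn(st$sim$tensor), st$mask)
  fit <- fit_patterns(X, 3)
  tbl <- assign_and_score(fit$A, colnames(X))
  # map fitted patterns to planted ones by matched correlation
  C <- cross_correlation(fit$D, st$sim$truth$D_true)
  for (k_fit in seq_len(3)) {
    k_true <- which.max(C[k_fit, ])
    planted <- st$sim$truth$marker_map[[k_true]]
    found <- top_markers(tbl, k_fit, length(planted))
    expect_setequal(found, planted)
  }
})

test_that("sGCN node and edge rules follow the quantile arithmetic", {
  st <- tiny_study(seed = 23, n_genes = 60)
  X <- assemble_matrix(impute_knn(st$sim$tensor), st$mask)
  fit <- fit_patterns(X, 3)
  tbl <- assign_and_score(fit$A, colnames(X))
  # permissive node quantile so each pattern keeps its assigned genes
  net <- build_sgcn(fit, tbl, 1, node_quantile = 0.9, edge_quantile = 0.05)
  np <- nrow(net$nodes)
  expect_gte(np, 2)
  expect_equal(nrow(net$edges), ceiling(0.05 * choose(np, 2)))
  expect_true(all(net$edges$pcc >= -1 & net$edges$pcc <= 1))
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  expect_true(all(c(net$edges$gene_a, net$edges$gene_b) %in% net$nodes$gene))
  # 11 nodes -> 55 pairs -> ceil(0.05 * 55) = 3 edges
  expect_equal(ceiling(0.05 * choose(11, 2)), 3)
  # edge set invariant to gene input order
  perm <- sample(ncol(X))
  fit2 <- fit
  fit2$D <- fit$D; fit2$A <- fit$A[, perm]
  tbl2 <- assign_and_score(fit2$A, colnames(X)[perm])
  net2 <- build_sgcn(fit2, tbl2, 1, node_quantile = 0.9, edge_quantile = 0.05)
  expect_equal(net$edges, net2$edges)
  expect_error(build_sgcn(fit, tbl, 1, node_quantile = 1e-6), "need >= 2")
})

test_that("identical reconstructions always share an edge", {
  v <- 40
  D <- random_dict(v, 2, seed = 30)
  A <- cbind(g1 = c(1, 0), g2 = c(1, 0), g3 = c(0.2, 0.8), g4 = c(0.3, 0.7),
             g5 = c(0.25, 0.75))
  fit <- structure(list(D = D, A = A, method = "nmf", K = 2, loss = 0,
                        center = NULL, components = NULL, seed = 1L,
                        loss_trace = 0, zero_columns = integer(0)),
                   class = "pp_fit")
  tbl <- assign_and_score(A)
  net <- build_sgcn(fit, tbl, 1, node_quantile = 1, edge_quantile = 0.05)
  expect_true(any(net$edges$gene_a == "g1" & net$edges$gene_b == "g2"))
  expect_equal(net$edges$pcc[net$edges$gene_a == "g1" &
                               net$edges$gene_b == "g2"], 1)
})

test_that("graphml export writes a parseable graph", {
  st <- tiny_study(seed = 24, n_genes = 40)
  X <- assemble_matrix(impute_knn(st$sim$tensor), st$mask)
  fit <- fit_patterns(X, 3)
  tbl <- assign_and_score(fit$A, colnames(X))
  net <- build_sgcn(fit, tbl, 2, node_quantile = 0.9)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sgcn_graphml(net, tmp, tsv)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(nrow(read.table(tsv, header = TRUE)), nrow(net$edges))
})

test_that("region predictability separates a region its pattern defines", {
  st <- tiny_study(seed = 25, dims = c(16, 13, 11), n_regions = 10,
                   n_genes = 10, K_true = 4, noise_sd = 0, missing_frac = 0)
  D <- st$sim$truth$D_true
  region <- st$atlas$labels[st$mask$inside] %in% st$sim$truth$combo_map[[1]]
  # a feature equal to the region indicator predicts it perfectly
  res <- region_predictability(cbind(as.numeric(region), D[, 2]), region,
                               pp_subset = 1, n_null = 5, seed = 1)
  expect_equal(res$auc, 1.0)
  # the pattern supported on the region beats most random other patterns
  res2 <- region_predictability(D, region, pp_subset = 1, n_null = 20, seed = 2)
  expect_gt(res2$auc, 0.9)
  expect_equal(length(res2$null_aucs), 20)
  expect_gte(res2$auc, max(res2$null_aucs) - 0.05)
  # adding features never materially degrades the training ROC
  res_all <- region_predictability(D, region, pp_subset = 1:3, n_null = 2,
                                   seed = 3)
  singles <- vapply(1:3, function(k)
    region_predictability(D, region, pp_subset = k, n_null = 2,
                          seed = 3)$auc, numeric(1))
  expect_gte(res_all$auc, max(singles) - 0.02)
  expect_error(region_predictability(D, rep(TRUE, st$mask$v), 1), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  score <- rnorm(200)
  label <- rbinom(200, 1, plogis(score))
  ours <- stapp:::auc_rank(score, label)
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
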