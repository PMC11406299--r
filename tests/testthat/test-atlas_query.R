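two_cube_atlas <- function(gap = 0) {
  labels <- array(0L, c(10, 6, 6))
  labels[2:4, 2:5, 2:5] <- 1L
  labels[(5 + gap):(7 + gap), 2:5, 2:5] <- 2L
  brain_atlas(labels)
}

test_that("face-touching cubes are adjacent; a 2-voxel gap is not", {
  adj <- build_adjacency(two_cube_atlas(gap = 0))
  expect_equal(nrow(adj$pairs), 1L)
  expect_equal(as.integer(adj$pairs[1, ]), c(1L, 2L))
  adj_gap <- build_adjacency(two_cube_atlas(gap = 2))
  expect_equal(nrow(adj_gap$pairs), 0L)
  expect_equal(nrow(adj_gap$triples), 0L)
})

test_that("a chain A-B-C yields pairs {A,B},{B,C} and triple {A,B,C}", {
  labels <- array(0L, c(12, 5, 5))
  labels[1:3, 2:4, 2:4] <- 1L
  labels[5:7, 2:4, 2:4] <- 2L   # touches neither under 26-conn (gap 1)?
  labels[4, 2:4, 2:4] <- 1L     # extend A to touch B
  labels[8:10, 2:4, 2:4] <- 3L  # C touches B
  atlas <- brain_atlas(labels)
  adj <- build_adjacency(atlas)
  expect_equal(unname(adj$pairs), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(unname(adj$triples), matrix(c(1L, 2L, 3L), 1))
})

test_that("adjacency agrees with the brute-force voxel-contact oracle", {
  set.seed(99)
  for (i in 1:12) {
    n_lab <- sample(3:10, 1)
    atlas <- make_atlas(c(10, 9, 8), n_lab, seed = 600 + i)
    for (conn in c(6, 26)) {
      adj <- build_adjacency(atlas, connectivity = conn)
      oracle <- brute_adjacency_pairs(atlas$labels, connectivity = conn)
      expect_equal(unname(adj$pairs), unname(oracle))
    }
  }
})

test_that("every triple contains at least one listed pair", {
  atlas <- make_atlas(c(12, 10, 9), 10, seed = 4)
  adj <- build_adjacency(atlas)
  pair_key <- paste(adj$pairs[, 1], adj$pairs[, 2])
  for (t in seq_len(nrow(adj$triples))) {
    tr <- adj$triples[t, ]
    keys <- c(paste(tr[1], tr[2]), paste(tr[1], tr[3]), paste(tr[2], tr[3]))
    expect_true(any(keys %in% pair_key))
  }
})

test_that("a pattern equal to a region mask links to that region with PCC 1", {
  st <- tiny_study(seed = 16, n_genes = 5)
  adj <- build_adjacency(st$atlas)
  lab <- st$atlas$ontology$label[st$atlas$ontology$level == 2][1]
  pp <- region_mask(st$atlas, lab)
  res <- link_pp(pp, st$atlas, adj, st$mask)
  expect_equal(res$best$labels, lab)
  expect_equal(res$best$pcc, 1, tolerance = 1e-12)
  # singles-only maximum can never beat the full superset
  res1 <- link_pp(pp, st$atlas, adj, st$mask, max_combo_size = 1)
  expect_lte(res1$best$pcc, res$best$pcc + 1e-12)
})

test_that("planted combinations are recovered by exhaustive search", {
  st <- tiny_study(seed = 17, dims = c(16, 13, 11), n_regions = 10,
                   n_genes = 10, K_true = 4, noise_sd = 0, missing_frac = 0)
  adj <- build_adjacency(st$atlas)
  for (k in seq_along(st$sim$truth$combo_map)) {
    res <- link_pp(st$sim$truth$D_true[, k], st$atlas, adj, st$mask)
    expect_equal(sort(res$best$labels), sort(st$sim$truth$combo_map[[k]]))
    expect_lte(res$per_size[["1"]]$pcc, res$best$pcc + 1e-12)
  }
})

test_that("zero-variance patterns give an NA link with warning", {
  st <- tiny_study(seed = 18, n_genes = 5)
  adj <- build_adjacency(st$atlas)
  expect_warning(res <- link_pp(rep(1, st$mask$v), st$atlas, adj, st$mask),
                 "zero-variance")
  expect_true(is.na(res$best$pcc))
})

test_that("correlation table matches direct Pearson computation", {
  st <- tiny_study(seed = 19, n_genes = 5)
  D <- st$sim$truth$D_true
  labs <- sort(unique(st$atlas$labels[st$atlas$labels > 0]))
  ct <- correlation_table(D, st$atlas, labs, st$mask)
  lab_in <- st$atlas$labels[st$mask$inside]
  for (k in seq_len(ncol(D))) for (r in seq_along(labs)) {
    expect_equal(ct[k, r], cor(D[, k], as.numeric(lab_in == labs[r])),
                 tolerance = 1e-12)
  }
  expect_error(correlation_table(D, st$atlas, c(labs, 999L), st$mask), "999")
  # a pattern equal to one region's indicator correlates 1 with it and
  # negatively with any disjoint region
  pp_ind <- as.numeric(lab_in == labs[1])
  ct1 <- correlation_table(matrix(pp_ind), st$atlas, labs[1:2], st$mask)
  expect_equal(ct1[1, 1], 1, tolerance = 1e-12)
  expect_lt(ct1[1, 2], 0)
})

test_that("ontology export orders patterns by descending link PCC", {
  st <- tiny_study(seed = 20, dims = c(16, 13, 11), n_regions = 10,
                   n_genes = 10, K_true = 4, noise_sd = 0, missing_frac = 0)
  adj <- build_adjacency(st$atlas)
  links <- lapply(seq_len(4), function(k)
    link_pp(st$sim$truth$D_true[, k], st$atlas, adj, st$mask))
  ont <- export_ontology(links, st$atlas, st$sim$truth$D_true, st$mask)
  pccs <- vapply(ont, function(e) e$pcc, numeric(1))
  expect_true(all(diff(pccs) <= 0))
  # planted membership is reproduced exactly
  for (e in ont)
    expect_equal(sort(e$regions$label),
                 sort(st$sim$truth$combo_map[[e$pp_index]]))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_ontology_json(ont, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  expect_equal(length(back), 4)
})
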