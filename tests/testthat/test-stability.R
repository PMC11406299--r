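test_that("cross-correlation matches the Pearson formula and its invariances", {
  D <- random_dict(30, 4, seed = 1)
  C <- cross_correlation(D, D)
  expect_equal(diag(C), rep(1, 4))
  # hand-computed entry on 4-vectors
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  C2 <- cross_correlation(cbind(e1, e2), cbind(e1, e2))
  expect_equal(C2[1, 2], -1 / 3)
  # positive column scaling leaves C unchanged
  D2 <- D; D2[, 2] <- 5 * D2[, 2]
  expect_equal(cross_correlation(D, D2), C)
  # zero-variance column warns and gives 0
  Dz <- D; Dz[, 3] <- 2
  expect_warning(Cz <- cross_correlation(D, Dz), "zero-variance")
  expect_true(all(Cz[, 3] == 0))
  expect_error(cross_correlation(D, D[, 1:2]), "different K")
})

test_that("dsim_hungarian solves the assignment exactly", {
  # worked 2x3 example: best assignment pairs the identical columns
  D <- cbind(c(1, 0, 0), c(0, 1, 0))
  D2 <- cbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(dsim_hungarian(D, D2), 0.75)
  # identity and permutation invariance
  D <- random_dict(25, 5, seed = 2)
  expect_equal(dsim_hungarian(D, D), 0)
  P <- sample(5)
  expect_lt(dsim_hungarian(D, D[, P]), 1e-12)
  scaled <- sweep(D[, P], 2, runif(5, 0.5, 4), `*`)
  expect_lt(dsim_hungarian(D, scaled), 1e-12)
})

test_that("hungarian dsim equals brute-force permutation search", {
  set.seed(33)
  for (i in 1:40) {
    K <- sample(2:6, 1)
    D <- random_dict(15, K, seed = 100 + i)
    D2 <- random_dict(15, K, seed = 200 + i)
    expect_equal(dsim_hungarian(D, D2), brute_dsim(D, D2), tolerance = 1e-12)
  }
})

test_that("dsim_amari matches its formula, is symmetric, zero at matchings", {
  D <- random_dict(20, 3, seed = 3)
  expect_equal(dsim_amari(D, D), 0)
  expect_lt(dsim_amari(D, D[, c(3, 1, 2)]), 1e-12)
  D2 <- random_dict(20, 3, seed = 4)
  expect_equal(dsim_amari(D, D2), brute_amari(D, D2))
  expect_equal(dsim_amari(D, D2), dsim_amari(D2, D))
  # forced row/column maxima 1 and 0 -> (1/4)(4 - 1 - 1) = 0.5
  b1 <- c(1, 0, 1, 0); b2 <- c(0, 1, 0, 1)   # cor(b1, b2) = -1
  n1 <- c(1, 1, 0, 0)                        # cor(n1, b1) = cor(n1, b2) = 0
  C <- cross_correlation(cbind(b1, n1), cbind(b1, b2))
  expect_equal(C, rbind(c(1, -1), c(0, 0)), tolerance = 1e-12)
  expect_equal(dsim_amari(cbind(b1, n1), cbind(b1, b2)), 0.5)
})

test_that("amari dissimilarity is bounded by the best-permutation value", {
  set.seed(44)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    D <- random_dict(12, K, seed = 300 + i)
    D2 <- random_dict(12, K, seed = 400 + i)
    expect_lte(dsim_amari(D, D2), brute_dsim(D, D2) + 1e-12)
  }
})

test_that("instability averages all unordered pairs", {
  D <- random_dict(20, 3, seed = 5)
  g <- instability(list(D, D, D))
  expect_equal(g$gamma, 0)
  expect_equal(g$n_pairs, 3)
  expect_error(instability(list(D)), "at least 2")
  # three dictionaries with known pairwise dsims average correctly
  set.seed(6)
  dicts <- lapply(1:3, function(i) random_dict(20, 3, seed = 500 + i))
  d12 <- dsim_hungarian(dicts[[1]], dicts[[2]])
  d13 <- dsim_hungarian(dicts[[1]], dicts[[3]])
  d23 <- dsim_hungarian(dicts[[2]], dicts[[3]])
  g3 <- instability(dicts)
  expect_equal(g3$gamma, mean(c(d12, d13, d23)))
  expect_equal(g3$sd, sd(c(d12, d13, d23)))
})

test_that("stability scan recovers the planted number of patterns", {
  st <- tiny_study(seed = 21, dims = c(14, 12, 10), n_regions = 8,
                   n_genes = 60, K_true = 3)
  X <- assemble_matrix(impute_knn(st$sim$tensor), st$mask)
  prof <- stability_scan(X, 2:7, n_runs = 12, seed = 21)
  expect_s3_class(prof, "stability_profile")
  expect_equal(select_K(prof), 3L)
  expect_true(all(prof$gamma_mean >= 0 & prof$gamma_mean <= 1))
  expect_true(all(is.finite(prof$gamma_mean)))
})

test_that("two runs give gamma equal to the single pairwise dsim", {
  X <- random_dict(60, 3, seed = 7) %*% t(random_dict(20, 3, seed = 8))
  prof <- stability_scan(X, K_range = 3, n_runs = 2, seed = 1)
  set.seed(1 + 1); b1 <- sample.int(ncol(X), ncol(X), replace = TRUE)
  set.seed(1 + 2); b2 <- sample.int(ncol(X), ncol(X), replace = TRUE)
  d1 <- fit_patterns(X[, b1], 3)$D
  d2 <- fit_patterns(X[, b2], 3)$D
  expect_equal(prof$gamma_mean, dsim_hungarian(d1, d2))
  expect_equal(prof$gamma_sd, 0)
})

test_that("without bootstrap, instability vanishes (deterministic refits)", {
  st <- tiny_study(seed = 8, n_genes = 30)
  X <- assemble_matrix(impute_knn(st$sim$tensor), st$mask)
  prof <- stability_scan(X, K_range = 3, n_runs = 5, seed = 2,
                         bootstrap = FALSE)
  expect_lte(prof$gamma_mean, 1e-9)
})

test_that("select_K takes the argmin with ties to the smaller K", {
  prof <- structure(list(K_values = c(8L, 9L, 10L),
                         gamma_mean = c(0.5, 0.1, 0.4),
                         gamma_sd = c(0, 0, 0), metric = "hungarian",
                         method = "nmf", n_runs = 10L),
                    class = "stability_profile")
  expect_equal(select_K(prof), 9L)
  prof$gamma_mean <- c(0.1, 0.1, 0.4)
  expect_equal(select_K(prof), 8L)
})
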