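#' Cross-correlation matrix between two dictionaries
#'
#' `C[k, l]` is the Pearson correlation between column `k` of `D` and column
#' `l` of `D2`. Pearson's normalization makes the matrix invariant to
#' positive rescaling of any column, which is the scaling invariance required
#' when comparing dictionaries from independent fits. Zero-variance columns
#' correlate 0 with everything (with a warning).
#'
#' @param D,D2 `v x K` matrices (or `pp_fit` objects, whose `D` is used)
#'   with identical dimensions.
#' @param mode `"pearson"` (default) or `"cosine"` column similarity.
#' @return `K x K` numeric matrix.
#' @export
cross_correlation <- function(D, D2, mode = c("pearson", "cosine")) {
  mode <- match.arg(mode)
  D <- dict_matrix(D)
  D2 <- dict_matrix(D2)
  if (nrow(D) != nrow(D2)) stop("dictionaries have different voxel counts")
  if (ncol(D) != ncol(D2)) stop("dictionaries have different K")
  if (mode == "pearson") {
    bad1 <- apply(D, 2L, sd) == 0
    bad2 <- apply(D2, 2L, sd) == 0
    if (any(bad1) || any(bad2))
      warning("zero-variance dictionary column(s); correlations set to 0")
    C <- suppressWarnings(cor(D, D2))
    C[!is.finite(C)] <- 0
  } else {
    nf1 <- sqrt(colSums(D^2)); nf2 <- sqrt(colSums(D2^2))
    if (any(nf1 == 0) || any(nf2 == 0))
      warning("all-zero dictionary column(s); similarities set to 0")
    nf1[nf1 == 0] <- Inf; nf2[nf2 == 0] <- Inf
    C <- crossprod(D, D2) / outer(nf1, nf2)
  }
  unname(C)
}

dict_matrix <- function(D) {
  if (inherits(D, "pp_fit")) D <- D$D
  as.matrix(D)
}

#' Dictionary dissimilarity after Hungarian column matching
#'
#' Solves the one-to-one assignment between the columns of the two
#' dictionaries that maximizes the total matched correlation, then returns
#' the mean of `1 - C[k, l]` over the `K` assigned pairs. Zero for identical
#' dictionaries (up to column permutation and positive scaling); at most 2.
#'
#' @inheritParams cross_correlation
#' @return A scalar in `[0, 2]`.
#' @export
dsim_hungarian <- function(D, D2, mode = "pearson") {
  C <- cross_correlation(D, D2, mode = mode)
  assign <- hungarian_cpp(1 - C)   # minimize sum(1 - C)
  mean(1 - C[cbind(seq_len(nrow(C)), assign)])
}

#' Amari-type dictionary dissimilarity
#'
#' A permutation-invariant dissimilarity built directly from the row and
#' column maxima of the cross-correlation matrix:
#' `(1 / 2K) * (2K - sum_l max_k C[k,l] - sum_k max_l C[k,l])`.
#' Symmetric in its arguments and zero when a perfect column matching exists.
#'
#' @inheritParams cross_correlation
#' @return A scalar.
#' @export
dsim_amari <- function(D, D2, mode = "pearson") {
  C <- cross_correlation(D, D2, mode = mode)
  K <- nrow(C)
  (2 * K - sum(apply(C, 2L, max)) - sum(apply(C, 1L, max))) / (2 * K)
}

#' Instability of a set of dictionaries
#'
#' The instability score is the average dissimilarity over all
#' `N (N - 1) / 2` unordered pairs of dictionaries fitted under data
#' perturbation, with its standard deviation across pairs.
#'
#' @param dictionaries list of `N >= 2` dictionaries (matrices or `pp_fit`s)
#'   with identical dimensions.
#' @param metric `"hungarian"` or `"amari"`.
#' @param mode column similarity mode passed to [cross_correlation()].
#' @return A list with `gamma` (mean pairwise dissimilarity), `sd` (their
#'   standard deviation; 0 when only one pair), and `n_pairs`.
#' @export
instability <- function(dictionaries, metric = c("hungarian", "amari"),
                        mode = "pearson") {
  metric <- match.arg(metric)
  N <- length(dictionaries)
  if (N < 2L) stop("need at least 2 dictionaries")
  dfun <- if (metric == "hungarian") dsim_hungarian else dsim_amari
  pairs <- combn(N, 2L)
  d <- vapply(seq_len(ncol(pairs)), function(i) {
    dfun(dictionaries[[pairs[1, i]]], dictionaries[[pairs[2, i]]], mode = mode)
  }, numeric(1))
  list(gamma = mean(d), sd = if (length(d) > 1L) sd(d) else 0,
       n_pairs = length(d))
}

#' Bootstrap stability scan over candidate K
#'
#' For each `K` in `K_range`, fits the factorization `n_runs` times, each on
#' an independent bootstrap resample of the gene columns (size `n`, with
#' replacement; all voxels kept so dictionaries stay comparable in voxel
#' space), and aggregates the pairwise dictionary dissimilarities into the
#' instability score. Initialization is deterministic, so all instability
#' originates from the data perturbation. Run-level seeds are derived from
#' `seed` independently per `(K, run)`, so runs can be computed in any order
#' with identical results.
#'
#' @param X non-negative voxel-by-gene matrix.
#' @param K_range integer vector of candidate pattern counts.
#' @param n_runs bootstrap fits per K (>= 2).
#' @param method factorization method, `"nmf"` or `"pca"`.
#' @param metric dissimilarity, `"hungarian"` or `"amari"`.
#' @param seed base integer seed for the bootstrap draws.
#' @param bootstrap set `FALSE` to disable resampling (all runs identical; a
#'   sanity check that non-bootstrap instability is numerically zero).
#' @param tol,max_iter solver controls passed to [fit_patterns()].
#' @return An object of class `stability_profile`: data frame-like list with
#'   `K_values`, `gamma_mean`, `gamma_sd`, plus `metric`, `method`, `n_runs`.
#' @export
stability_scan <- function(X, K_range = 8:30, n_runs = 100L,
                           method = c("nmf", "pca"),
                           metric = c("hungarian", "amari"),
                           seed = 1L, bootstrap = TRUE,
                           tol = 1e-4, max_iter = 200L) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- ncol(X)
  K_range <- as.integer(K_range)
  if (any(K_range < 1L) || any(K_range > min(dim(X))))
    stop(sprintf("K_range must lie in [1, %d]", min(dim(X))))
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  gamma_mean <- gamma_sd <- numeric(length(K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    dicts <- vector("list", n_runs)
    for (run in seq_len(n_runs)) {
      run_seed <- as.integer(seed) + (ki - 1L) * n_runs + run
      Xb <- if (bootstrap) {
        set.seed(run_seed)
        X[, sample.int(n, n, replace = TRUE), drop = FALSE]
      } else X
      fit <- tryCatch(
        fit_patterns(Xb, K, method = method, seed = run_seed,
                     tol = tol, max_iter = max_iter),
        error = function(e) stop(sprintf("fit failed at K = %d, run %d: %s",
                                         K, run, conditionMessage(e)),
                                 call. = FALSE))
      dicts[[run]] <- fit$D
    }
    g <- instability(dicts, metric = metric)
    gamma_mean[ki] <- g$gamma
    gamma_sd[ki] <- g$sd
  }
  structure(list(K_values = K_range, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, metric = metric, method = method,
                 n_runs = n_runs, seed = as.integer(seed),
                 bootstrap = bootstrap),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("<stability_profile> %s/%s, %d runs per K\n",
              x$method, x$metric, x$n_runs))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.stability_profile <- function(x, ...) {
  data.frame(K = x$K_values, gamma_mean = x$gamma_mean,
             gamma_sd = x$gamma_sd)
}

#' Select the most stable K
#'
#' The candidate with minimal mean instability; ties go to the smaller K.
#'
#' @param profile a `stability_profile` from [stability_scan()].
#' @return A single integer K.
#' @export
select_K <- function(profile) {
  stopifnot(inherits(profile, "stability_profile"))
  if (!length(profile$K_values)) stop("empty stability profile")
  ord <- order(profile$gamma_mean, profile$K_values)
  profile$K_values[ord[1L]]
}
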