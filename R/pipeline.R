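#' Default pipeline configuration
#'
#' Returns the full configuration skeleton accepted by [run_pipeline()],
#' with every tunable threshold exposed (so analyses can be re-parameterized
#' without code changes). Stage blocks set `enabled = FALSE` are skipped.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "stapp_run",
    input = list(tensor_prefix = NULL, atlas_volume = NULL,
                 atlas_ontology = NULL),
    simulate = list(enabled = FALSE, dims = c(20L, 16L, 14L),
                    n_regions = 12L, n_genes = 200L, k_true = 5L,
                    noise_sd = 0.05, missing_frac = 0.1),
    impute = list(enabled = TRUE, k = 6L),
    stability = list(enabled = TRUE, k_min = 8L, k_max = 30L,
                     n_runs = 100L, metric = "hungarian", method = "nmf"),
    fit = list(k = NULL, method = "nmf", tol = 1e-4, max_iter = 200L),
    coherence = list(enabled = FALSE, n_boot = 20L, connectivity = 6L),
    link = list(enabled = TRUE, max_combo_size = 3L, connectivity = 26L),
    markers = list(enabled = TRUE, rel_threshold = 0.01, top_n = 3L),
    sgcn = list(enabled = FALSE, node_quantile = 0.0025,
                edge_quantile = 0.05, pps = "all")
  )
}

validate_config <- function(config) {
  base <- default_config()
  problems <- character(0)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    problems <- c(problems, paste0("unknown config section(s): ",
                                   paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(base))) {
    if (!is.list(base[[sec]])) next
    bad <- setdiff(names(config[[sec]]), names(base[[sec]]))
    if (length(bad))
      problems <- c(problems, paste0("unknown key(s) in '", sec, "': ",
                                     paste(bad, collapse = ", ")))
  }
  merged <- utils::modifyList(base, config)
  if (!isTRUE(merged$simulate$enabled) &&
      is.null(merged$input$tensor_prefix))
    problems <- c(problems,
                  "either simulate.enabled or input.tensor_prefix is required")
  if (!merged$stability$enabled && is.null(merged$fit$k))
    problems <- c(problems, "fit.k is required when stability is disabled")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  merged
}

#' Run the end-to-end pattern-discovery pipeline
#'
#' Orchestrates the stages impute -> stability scan / fit -> spatial
#' coherence -> atlas linking -> marker ranking -> coexpression networks on
#' a configuration (see [default_config()]), writing all artifacts plus a
#' manifest (config hash and every derived seed) into the output directory.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config nested list, or path to a JSON configuration file.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[stapp %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  seeds <- list(base = as.integer(cfg$seed))
  results <- list(config = cfg)

  # --- inputs ---
  if (isTRUE(cfg$simulate$enabled)) {
    log_stage("simulate: %d genes, %d regions, K_true = %d",
              cfg$simulate$n_genes, cfg$simulate$n_regions, cfg$simulate$k_true)
    seeds$simulate <- seeds$base
    atlas <- make_atlas(as.integer(cfg$simulate$dims), cfg$simulate$n_regions,
                        seed = seeds$simulate)
    sim <- make_expression(atlas, n_genes = cfg$simulate$n_genes,
                           K_true = cfg$simulate$k_true,
                           noise_sd = cfg$simulate$noise_sd,
                           missing_frac = cfg$simulate$missing_frac,
                           seed = seeds$simulate)
    tensor <- sim$tensor
    results$truth <- sim$truth
    write_atlas(atlas, file.path(out, "atlas.nrrd"),
                file.path(out, "atlas_ontology.tsv"))
  } else {
    tensor <- read_expression_tensor(cfg$input$tensor_prefix)
    atlas <- if (!is.null(cfg$input$atlas_volume))
      read_atlas(cfg$input$atlas_volume, cfg$input$atlas_ontology) else NULL
  }
  mask <- if (!is.null(atlas)) atlas_brain_mask(atlas) else
    voxel_mask(array(TRUE, tensor$grid$dims), tensor$grid)

  # --- impute ---
  if (isTRUE(cfg$impute$enabled) && any(tensor$missing)) {
    log_stage("impute: k = %d", cfg$impute$k)
    tensor <- impute_knn(tensor, k = cfg$impute$k)
    write_expression_tensor(tensor, file.path(out, "imputed"))
  }
  X <- assemble_matrix(tensor, mask)
  results$X <- X

  # --- stability / model selection ---
  if (isTRUE(cfg$stability$enabled)) {
    k_range <- cfg$stability$k_min:cfg$stability$k_max
    log_stage("stability scan: K in [%d, %d], %d runs",
              min(k_range), max(k_range), cfg$stability$n_runs)
    seeds$stability <- seeds$base + 1000L
    profile <- stability_scan(X, K_range = k_range,
                              n_runs = cfg$stability$n_runs,
                              method = cfg$stability$method,
                              metric = cfg$stability$metric,
                              seed = seeds$stability,
                              tol = cfg$fit$tol, max_iter = cfg$fit$max_iter)
    K <- select_K(profile)
    results$profile <- profile
    write.table(as.data.frame(profile),
                file.path(out, "stability_profile.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(selected_K = K, metric = profile$metric,
                              n_runs = profile$n_runs),
                         file.path(out, "stability_summary.json"),
                         auto_unbox = TRUE)
  } else {
    K <- as.integer(cfg$fit$k)
  }
  results$selected_K <- K

  # --- final fit ---
  log_stage("fit: method = %s, K = %d", cfg$fit$method, K)
  seeds$fit <- seeds$base + 2000L
  fit <- fit_patterns(X, K, method = cfg$fit$method, seed = seeds$fit,
                      tol = cfg$fit$tol, max_iter = cfg$fit$max_iter)
  results$fit <- fit
  for (k in seq_len(K))
    write_volume(unmask(fit$D[, k], mask),
                 file.path(out, sprintf("pp_%02d.nrrd", k)),
                 voxel_size = tensor$grid$voxel_size)
  coef_tab <- data.frame(gene = tensor$genes, t(fit$A))
  names(coef_tab)[-1] <- paste0("PP", seq_len(K))
  write.table(coef_tab, file.path(out, "coefficients.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  # --- spatial coherence comparison ---
  if (isTRUE(cfg$coherence$enabled)) {
    log_stage("coherence: %d bootstrap resamples", cfg$coherence$n_boot)
    seeds$coherence <- seeds$base + 3000L
    coh <- compare_spatial_coherence(X, mask, K,
                                     n_boot = cfg$coherence$n_boot,
                                     seed = seeds$coherence,
                                     connectivity = cfg$coherence$connectivity)
    results$coherence <- coh
    write.table(coh, file.path(out, "coherence.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  # --- entity linking ---
  if (isTRUE(cfg$link$enabled) && !is.null(atlas)) {
    log_stage("link: combinations up to size %d", cfg$link$max_combo_size)
    adj <- build_adjacency(atlas, connectivity = cfg$link$connectivity,
                           max_combo_size = cfg$link$max_combo_size)
    links <- lapply(seq_len(K), function(k)
      link_pp(fit$D[, k], atlas, adj, mask,
              max_combo_size = cfg$link$max_combo_size))
    results$adjacency <- adj
    results$links <- links
    link_tab <- do.call(rbind, lapply(seq_len(K), function(k) {
      b <- links[[k]]$best
      data.frame(pp_index = k,
                 labels = paste(b$labels, collapse = ","),
                 names = paste(b$names, collapse = ","),
                 size = b$size, pcc = b$pcc, stringsAsFactors = FALSE)
    }))
    write.table(link_tab, file.path(out, "links.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(adj$pairs, file.path(out, "adjacent_pairs.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(adj$triples, file.path(out, "adjacent_triples.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_ontology_json(export_ontology(links, atlas, fit$D, mask),
                        file.path(out, "ontology.json"))
  }

  # --- markers ---
  if (isTRUE(cfg$markers$enabled)) {
    log_stage("markers: ranking %d genes", length(tensor$genes))
    table <- assign_and_score(fit$A, tensor$genes)
    table$pp_count <- pp_count_per_gene(fit$A, cfg$markers$rel_threshold)
    results$markers <- table
    write.table(table, file.path(out, "markers.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  # --- coexpression networks ---
  if (isTRUE(cfg$sgcn$enabled)) {
    if (is.null(results$markers))
      results$markers <- assign_and_score(fit$A, tensor$genes)
    pps <- if (identical(cfg$sgcn$pps, "all")) seq_len(K) else
      as.integer(cfg$sgcn$pps)
    nets <- list()
    for (p in pps) {
      net <- tryCatch(
        build_sgcn(fit, results$markers, p,
                   node_quantile = cfg$sgcn$node_quantile,
                   edge_quantile = cfg$sgcn$edge_quantile),
        error = function(e) NULL)
      if (is.null(net)) next
      nets[[as.character(p)]] <- net
      write_sgcn_graphml(net, file.path(out, sprintf("sgcn_pp%02d.graphml", p)),
                         file.path(out, sprintf("sgcn_pp%02d_edges.tsv", p)))
    }
    results$sgcn <- nets
  }

  # --- manifest ---
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seeds = seeds, selected_K = K,
                   n_genes = length(tensor$genes),
                   n_voxels_in_mask = mask$v)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  log_stage("done: artifacts in %s", out)
  invisible(results)
}
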