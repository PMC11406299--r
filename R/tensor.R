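#' Stack of per-gene 3D expression volumes
#'
#' Holds one non-negative volume per gene on a shared grid, plus a logical
#' mask of unobserved (missing) voxels. Missing entries may be encoded as
#' `NA` in `values`; they are moved into `missing` and zero-filled in the
#' stored array so that downstream arithmetic never meets `NA`.
#'
#' @param values numeric 4D array `(nx, ny, nz, n_genes)`; non-negative
#'   wherever observed; `NA` allowed for unobserved voxels.
#' @param genes character vector of unique gene identifiers, length =
#'   `dim(values)[4]`.
#' @param grid optional [pp_grid()]; defaults to the array's spatial dims.
#' @param missing optional logical array of the same shape marking
#'   unobserved voxels (combined with `NA`s found in `values`).
#' @return An object of class `expression_tensor` with elements `grid`,
#'   `genes`, `values` (NA-free), `missing`.
#' @export
expression_tensor <- function(values, genes, grid = NULL, missing = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("values must be a 4D array (nx, ny, nz, n_genes)")
  genes <- as.character(genes)
  if (length(genes) != dim(values)[4])
    stop("length(genes) must equal dim(values)[4]")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (is.null(grid)) grid <- pp_grid(dim(values)[1:3])
  if (!identical(as.integer(dim(values)[1:3]), grid$dims))
    stop("values shape does not match grid dims")
  if (is.null(missing)) {
    missing <- array(FALSE, dim = dim(values))
  } else {
    if (!identical(dim(missing), dim(values)))
      stop("missing mask shape must match values")
    missing <- array(as.logical(missing), dim = dim(values))
  }
  missing <- missing | is.na(values)
  observed <- values[!missing]
  if (length(observed) && any(observed < 0))
    stop("observed expression values must be non-negative")
  values[missing] <- 0
  structure(list(grid = grid, genes = genes, values = values,
                 missing = missing),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat(sprintf("<expression_tensor> %d genes on %d x %d x %d grid (%.1f%% missing)\n",
              length(x$genes), x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              100 * mean(x$missing)))
  invisible(x)
}

#' Extract one gene's volume from a tensor
#' @param tensor an [expression_tensor()].
#' @param gene gene identifier or column index.
#' @param na_missing replace unobserved voxels with `NA`?
#' @return 3D numeric array.
#' @export
tensor_gene <- function(tensor, gene, na_missing = FALSE) {
  stopifnot(inherits(tensor, "expression_tensor"))
  j <- if (is.character(gene)) match(gene, tensor$genes) else as.integer(gene)
  if (is.na(j) || j < 1L || j > length(tensor$genes))
    stop("unknown gene: ", gene)
  vol <- tensor$values[, , , j, drop = TRUE]
  dim(vol) <- tensor$grid$dims
  if (na_missing) {
    m <- tensor$missing[, , , j, drop = TRUE]
    vol[m] <- NA_real_
  }
  vol
}
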