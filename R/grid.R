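#' Voxel grid geometry
#'
#' A grid describes the shape of the common 3D lattice that all volumes in a
#' study share: integer dimensions `(nx, ny, nz)` and the physical edge length
#' of a voxel in micrometres. All arrays in the package are indexed
#' `(x, y, z)`, 0-offset-free (R's native 1-based indexing), column-major.
#'
#' @param dims integer vector of length 3, all entries >= 1.
#' @param voxel_size numeric length-3 voxel edge lengths in micrometres.
#' @return An object of class `pp_grid` with elements `dims` and `voxel_size`.
#' @examples
#' g <- pp_grid(c(67, 41, 58))
#' grid_n_voxels(g)  # 159326
#' @export
pp_grid <- function(dims, voxel_size = c(200, 200, 200)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("dims must be three integers >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive")
  structure(list(dims = dims, voxel_size = voxel_size), class = "pp_grid")
}

#' Total number of voxels of a grid
#' @param grid a [pp_grid()].
#' @return integer-valued double, `prod(dims)`.
#' @export
grid_n_voxels <- function(grid) {
  stopifnot(inherits(grid, "pp_grid"))
  prod(as.numeric(grid$dims))
}

#' @export
print.pp_grid <- function(x, ...) {
  cat(sprintf("<pp_grid> %d x %d x %d voxels (%g x %g x %g um)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

grids_equal <- function(a, b) identical(a$dims, b$dims)

#' In-mask voxel set with a fixed flattening order
#'
#' A voxel mask selects the subset of grid voxels that enter the analysis
#' (e.g. the brain) and fixes a bijection between those voxels and the rows of
#' the flattened voxel-by-gene matrix: row `i` of the matrix is the `i`-th
#' in-mask voxel in column-major (linear index) order.
#'
#' @param inside logical 3D array, `TRUE` for in-mask voxels.
#' @param grid a [pp_grid()] matching `dim(inside)`; defaults to a grid of the
#'   array's dimensions.
#' @return An object of class `voxel_mask` with elements `grid`, `inside`,
#'   `voxels` (linear indices of in-mask voxels, ascending), `index_map`
#'   (integer array: row number inside the mask, 0 outside), and `v` (count).
#' @export
voxel_mask <- function(inside, grid = NULL) {
  if (!is.array(inside) || length(dim(inside)) != 3L || !is.logical(inside))
    stop("inside must be a logical 3D array")
  if (is.null(grid)) grid <- pp_grid(dim(inside))
  if (!identical(as.integer(dim(inside)), grid$dims))
    stop("mask shape does not match grid dims")
  inside[is.na(inside)] <- FALSE
  voxels <- which(inside)
  index_map <- array(0L, dim = grid$dims)
  index_map[voxels] <- seq_along(voxels)
  structure(list(grid = grid, inside = inside, voxels = voxels,
                 index_map = index_map, v = length(voxels)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d / %g voxels inside\n", x$v,
              grid_n_voxels(x$grid)))
  invisible(x)
}

#' Flatten an expression tensor to the voxel-by-gene matrix
#'
#' Rows follow the mask's index map (in-mask voxels in linear-index order),
#' columns follow the tensor's gene manifest. The tensor must be fully
#' imputed inside the mask.
#'
#' @param tensor an [expression_tensor()].
#' @param mask a [voxel_mask()] on the same grid.
#' @return A `v x n` numeric matrix with genes as column names.
#' @seealso [unmask()] for the inverse mapping back to volumes.
#' @export
assemble_matrix <- function(tensor, mask) {
  stopifnot(inherits(tensor, "expression_tensor"), inherits(mask, "voxel_mask"))
  if (!grids_equal(tensor$grid, mask$grid))
    stop("tensor and mask are on different grids")
  n <- length(tensor$genes)
  miss_flat <- matrix(tensor$missing, nrow = grid_n_voxels(tensor$grid))
  if (any(miss_flat[mask$voxels, , drop = FALSE]))
    stop("tensor has missing values inside the mask; impute first")
  vals <- matrix(tensor$values, nrow = grid_n_voxels(tensor$grid))
  X <- vals[mask$voxels, , drop = FALSE]
  colnames(X) <- tensor$genes
  X
}

#' Map in-mask values back onto the 3D grid
#'
#' The inverse of [assemble_matrix()]: writes each in-mask value back to its
#' voxel and fills voxels outside the mask with `fill`.
#'
#' @param x a length-`v` vector (one volume) or a `v x k` matrix (stack).
#' @param mask the [voxel_mask()] that produced the flattening.
#' @param fill value for out-of-mask voxels (default 0).
#' @return A 3D array for vector input, a 4D array `(dims, k)` for a matrix.
#' @export
unmask <- function(x, mask, fill = 0) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (is.matrix(x)) {
    if (nrow(x) != mask$v) stop("nrow(x) != number of in-mask voxels")
    out <- array(fill, dim = c(mask$grid$dims, ncol(x)))
    step <- grid_n_voxels(mask$grid)
    for (j in seq_len(ncol(x))) out[mask$voxels + (j - 1L) * step] <- x[, j]
    dimnames(out) <- NULL
    out
  } else {
    x <- as.numeric(x)
    if (length(x) != mask$v) stop("length(x) != number of in-mask voxels")
    out <- array(fill, dim = mask$grid$dims)
    out[mask$voxels] <- x
    out
  }
}
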