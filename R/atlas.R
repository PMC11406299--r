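#' Labeled anatomical atlas with ontology
#'
#' An atlas is an integer-labeled 3D volume (0 = background, never a region)
#' plus an ontology table relating labels to names and parents. Every
#' nonzero label occurring in the volume must appear in the ontology; parent
#' links must form a forest (no cycles). Region masks are "normalized":
#' [region_mask()] returns 0/1 indicators regardless of the label value
#' stored in the volume.
#'
#' @param labels integer 3D array of region labels (0 = background).
#' @param ontology data frame with columns `label`, `name`, `parent_label`
#'   (0 or `NA` for roots) and `level`; if `NULL`, a flat one-level ontology
#'   is generated from the labels present.
#' @param grid optional [pp_grid()].
#' @return An object of class `brain_atlas`.
#' @export
brain_atlas <- function(labels, ontology = NULL, grid = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers (0 = background)")
  if (is.null(grid)) grid <- pp_grid(dim(labels))
  if (!identical(as.integer(dim(labels)), grid$dims))
    stop("labels shape does not match grid dims")
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(ontology)) {
    ontology <- data.frame(label = present,
                           name = sprintf("region_%03d", present),
                           parent_label = 0L,
                           level = 1L,
                           stringsAsFactors = FALSE)
  }
  need <- c("label", "name", "parent_label", "level")
  if (!all(need %in% names(ontology)))
    stop("ontology must have columns: ", paste(need, collapse = ", "))
  ontology$label <- as.integer(ontology$label)
  ontology$parent_label <- as.integer(ontology$parent_label)
  ontology$parent_label[is.na(ontology$parent_label)] <- 0L
  if (anyDuplicated(ontology$label)) stop("duplicated labels in ontology")
  missing_lab <- setdiff(present, ontology$label)
  if (length(missing_lab))
    stop("labels present in volume but absent from ontology: ",
         paste(missing_lab, collapse = ", "))
  # forest check: following parents must terminate at 0 without revisits
  parent_of <- stats::setNames(ontology$parent_label, ontology$label)
  for (l in ontology$label) {
    seen <- integer(0)
    cur <- l
    while (cur != 0L) {
      if (cur %in% seen) stop("ontology parent links contain a cycle at label ", l)
      seen <- c(seen, cur)
      cur <- if (as.character(cur) %in% names(parent_of))
        parent_of[[as.character(cur)]] else 0L
    }
  }
  structure(list(grid = grid, labels = labels, ontology = ontology),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d labeled regions on %d x %d x %d grid\n",
              length(unique(x$labels[x$labels > 0L])),
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Normalized (0/1) mask for one or more regions
#'
#' @param atlas a [brain_atlas()].
#' @param labels one or more region labels; the union indicator is returned.
#' @return Numeric 3D array valued 1 inside the union, 0 outside.
#' @export
region_mask <- function(atlas, labels) {
  stopifnot(inherits(atlas, "brain_atlas"))
  labels <- as.integer(labels)
  unknown <- setdiff(labels, atlas$ontology$label)
  if (length(unknown))
    stop("unknown region labels: ", paste(unknown, collapse = ", "))
  out <- array(0, dim = atlas$grid$dims)
  out[atlas$labels %in% labels] <- 1
  out
}

#' Brain mask of an atlas (all labeled voxels)
#' @param atlas a [brain_atlas()].
#' @return A [voxel_mask()] covering every voxel with a nonzero label.
#' @export
atlas_brain_mask <- function(atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  voxel_mask(atlas$labels > 0L, atlas$grid)
}
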