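#' Read a 3D volume from disk
#'
#' Supported containers: NRRD (`.nrrd`, raw or gzip encodings, little-endian),
#' NIfTI-1 (`.nii`, `.nii.gz`, via RNifti), and raw float binaries with a JSON
#' sidecar (`.raw`/`.bin` + `<path>.json` with keys `dims`, `dtype`, `order`).
#' The pipeline is grid-native: only the header dimensions (and, when present,
#' voxel spacings) are honoured; orientation/affine information is ignored.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"nrrd"`, `"nifti"`, `"raw"`; `"auto"`
#'   dispatches on the file extension.
#' @return A list with elements `grid` (a [pp_grid()]) and `values`
#'   (numeric 3D array).
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
         nrrd = read_nrrd(path),
         nifti = read_nifti_volume(path),
         raw = read_raw_volume(path))
}

#' Write a 3D volume to disk
#'
#' @param values numeric 3D array.
#' @param path output file; extension should match `format`.
#' @param format `"auto"` (from extension), `"nrrd"`, `"nifti"` or `"raw"`.
#' @param voxel_size voxel edge lengths in micrometres (recorded in headers).
#' @param dtype on-disk element type, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path,
                         format = c("auto", "nrrd", "nifti", "raw"),
                         voxel_size = c(200, 200, 200),
                         dtype = c("float32", "float64")) {
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
         nrrd = write_nrrd(values, path, voxel_size, dtype),
         nifti = write_nifti_volume(values, path, voxel_size),
         raw = write_raw_volume(values, path, dtype))
  invisible(path)
}

guess_volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", low)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(raw|bin)$", low)) return("raw")
  stop("cannot infer volume format from extension: ", path)
}

# ---- NRRD (minimal NRRD0004 subset: 3D, raw/gzip encoding, little endian) ----

nrrd_type_map <- list(
  "float"  = list(what = "numeric", size = 4L, signed = TRUE),
  "double" = list(what = "numeric", size = 8L, signed = TRUE),
  "int"    = list(what = "integer", size = 4L, signed = TRUE),
  "short"  = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE),
  "uint"   = list(what = "integer", size = 4L, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!length(magic) || !grepl("^NRRD000[1-5]$", magic))
    stop("not an NRRD file (bad magic): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("malformed NRRD header line: ", line)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("NRRD header missing fields: ", paste(miss, collapse = ", "))
  if (as.integer(fields$dimension) != 3L)
    stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L || anyNA(sizes)) stop("bad NRRD sizes field")
  type <- sub("^unsigned char$", "uchar", fields$type)
  spec <- nrrd_type_map[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", fields$type)
  endian <- fields[["endian"]] %||% "little"
  if (!identical(endian, "little")) stop("only little-endian NRRD supported")
  n <- prod(sizes)
  raw_rest <- readBin(con, "raw", n = file.size(path))
  enc <- fields$encoding
  if (enc == "gzip" || enc == "gz") {
    raw_rest <- memDecompress(raw_rest, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  expect_bytes <- n * spec$size
  if (length(raw_rest) < expect_bytes)
    stop(sprintf("NRRD data too short: header promises %d values (%d bytes), found %d bytes",
                 n, expect_bytes, length(raw_rest)))
  vals <- readBin(raw_rest, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n) stop("NRRD data length does not match header sizes")
  voxel_size <- c(200, 200, 200)
  if (!is.null(fields[["spacings"]])) {
    sp <- suppressWarnings(as.numeric(strsplit(fields$spacings, "\\s+")[[1]]))
    if (length(sp) == 3L && all(is.finite(sp)) && all(sp > 0)) voxel_size <- sp
  }
  list(grid = pp_grid(sizes, voxel_size),
       values = array(as.numeric(vals), dim = sizes))
}

write_nrrd <- function(values, path, voxel_size, dtype) {
  type <- if (dtype == "float32") "float" else "double"
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(values), collapse = " ")),
           paste0("spacings: ", paste(format(voxel_size, trim = TRUE), collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(values), con, size = size, endian = "little")
  invisible(path)
}

# ---- NIfTI via RNifti ----

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
    vals <- array(vals, dim = dim(vals)[1:3])
  if (length(dim(vals)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  pd <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) NULL)
  voxel_size <- if (!is.null(pd) && all(is.finite(pd)) && all(pd > 0))
    pd else c(200, 200, 200)
  list(grid = pp_grid(dim(vals), voxel_size),
       values = array(as.numeric(vals), dim = dim(vals)))
}

write_nifti_volume <- function(values, path, voxel_size) {
  img <- RNifti::asNifti(array(as.numeric(values), dim = dim(values)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- raw float binary + JSON sidecar ----

raw_sidecar_path <- function(path) paste0(path, ".json")

read_raw_volume <- function(path) {
  side <- raw_sidecar_path(path)
  if (!file.exists(side))
    stop("raw volume requires a JSON sidecar at ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$dims) || is.null(meta$dtype))
    stop("raw sidecar must contain 'dims' and 'dtype'")
  dims <- as.integer(meta$dims)
  size <- switch(meta$dtype, float32 = 4L, float64 = 8L,
                 stop("unsupported raw dtype: ", meta$dtype))
  n <- prod(dims)
  vals <- readBin(path, "numeric", n = n + 1L, size = size, endian = "little")
  if (length(vals) != n)
    stop(sprintf("raw data length %d does not match sidecar dims (%d values)",
                 length(vals), n))
  voxel_size <- if (!is.null(meta$voxel_size)) as.numeric(meta$voxel_size)
                else c(200, 200, 200)
  list(grid = pp_grid(dims[1:3], voxel_size),
       values = array(vals, dim = dims))
}

write_raw_volume <- function(values, path, dtype, voxel_size = c(200, 200, 200)) {
  size <- if (dtype == "float32") 4L else 8L
  writeBin(as.numeric(values), path, size = size, endian = "little")
  jsonlite::write_json(list(dims = dim(values), dtype = dtype, order = "F",
                            voxel_size = voxel_size),
                       raw_sidecar_path(path), auto_unbox = FALSE)
  invisible(path)
}

# ---- gene manifests and tensors ----

#' Read / write a gene manifest
#'
#' A manifest is a flat text file with one gene identifier per line, in the
#' same order as the volumes of the tensor it accompanies. Duplicated
#' identifiers are rejected.
#'
#' @param path text file path.
#' @return `read_gene_manifest`: character vector of identifiers.
#' @export
read_gene_manifest <- function(path) {
  genes <- readLines(path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers in manifest: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  genes
}

#' @rdname read_gene_manifest
#' @param genes character vector of unique identifiers.
#' @export
write_gene_manifest <- function(genes, path) {
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write an expression tensor as raw binary + sidecar + manifest
#'
#' The tensor is stored as a 4D little-endian float binary (`<prefix>.bin`),
#' a JSON sidecar (`<prefix>.bin.json`), and a gene manifest
#' (`<prefix>.genes.tsv`). Unobserved voxels are stored as `NaN`.
#'
#' @param tensor an [expression_tensor()].
#' @param prefix path prefix for the three files.
#' @return `read_expression_tensor`: an [expression_tensor()].
#' @export
write_expression_tensor <- function(tensor, prefix) {
  stopifnot(inherits(tensor, "expression_tensor"))
  vals <- tensor$values
  vals[tensor$missing] <- NaN
  bin <- paste0(prefix, ".bin")
  writeBin(as.numeric(vals), bin, size = 8L, endian = "little")
  jsonlite::write_json(list(dims = dim(vals), dtype = "float64", order = "F",
                            voxel_size = tensor$grid$voxel_size),
                       raw_sidecar_path(bin), auto_unbox = FALSE)
  write_gene_manifest(tensor$genes, paste0(prefix, ".genes.tsv"))
  invisible(prefix)
}

#' @rdname write_expression_tensor
#' @export
read_expression_tensor <- function(prefix) {
  bin <- paste0(prefix, ".bin")
  meta <- jsonlite::read_json(raw_sidecar_path(bin), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  if (length(dims) != 4L) stop("tensor sidecar must describe a 4D array")
  n <- prod(dims)
  vals <- readBin(bin, "numeric", n = n + 1L, size = 8L, endian = "little")
  if (length(vals) != n) stop("tensor data length does not match sidecar dims")
  vals <- array(vals, dim = dims)
  vals[is.nan(vals)] <- NA_real_
  genes <- read_gene_manifest(paste0(prefix, ".genes.tsv"))
  grid <- pp_grid(dims[1:3], as.numeric(meta$voxel_size %||% c(200, 200, 200)))
  expression_tensor(vals, genes, grid)
}

#' Read / write an atlas (label volume + ontology table)
#'
#' The label volume uses any supported volume container; the ontology is a
#' TSV with columns `label`, `name`, `parent_label`, `level`.
#'
#' @param volume_path label volume file.
#' @param ontology_path ontology TSV path (`NULL` for a flat auto-ontology).
#' @return `read_atlas`: a [brain_atlas()].
#' @export
read_atlas <- function(volume_path, ontology_path = NULL) {
  vol <- read_volume(volume_path)
  labels <- array(as.integer(round(vol$values)), dim = vol$grid$dims)
  ontology <- if (is.null(ontology_path)) NULL else
    read.table(ontology_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, quote = "")
  brain_atlas(labels, ontology, vol$grid)
}

#' @rdname read_atlas
#' @param atlas a [brain_atlas()].
#' @export
write_atlas <- function(atlas, volume_path, ontology_path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  write_volume(array(as.numeric(atlas$labels), dim = atlas$grid$dims),
               volume_path, voxel_size = atlas$grid$voxel_size,
               dtype = "float64")
  write.table(atlas$ontology, ontology_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(volume_path)
}
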