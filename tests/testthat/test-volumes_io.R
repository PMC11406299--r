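test_that("grid arithmetic and invariants hold", {
  g <- pp_grid(c(67, 41, 58))
  expect_equal(grid_n_voxels(g), 159326)
  expect_error(pp_grid(c(0, 2, 3)), "dims")
  expect_error(pp_grid(c(2, 2)), "dims")
})

test_that("volume round-trips are the identity for all supported formats", {
  dims <- c(3, 4, 5)
  vol <- ramp_volume(dims)
  tmp <- withr::local_tempdir()
  for (ext in c("nrrd", "nii", "raw")) {
    path <- file.path(tmp, paste0("vol.", ext))
    write_volume(vol, path, dtype = "float64")
    back <- read_volume(path)
    expect_identical(back$grid$dims, as.integer(dims))
    expect_equal(back$values, vol, tolerance = 0, ignore_attr = TRUE)
  }
  # float32 storage round-trips bit-exactly for float32-representable input
  f32 <- array(as.numeric(seq_len(prod(dims))), dims)  # small integers
  path <- file.path(tmp, "vol32.nrrd")
  write_volume(f32, path, dtype = "float32")
  expect_equal(read_volume(path)$values, f32, ignore_attr = TRUE)
})

test_that("gzip-encoded NRRD volumes are read", {
  dims <- c(4, 3, 2)
  vol <- ramp_volume(dims)
  tmp <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(tmp, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               paste("sizes:", paste(dims, collapse = " ")),
               "endian: little", "encoding: gzip", ""), con)
  writeBin(memCompress(writeBin(as.numeric(vol), raw(), size = 8,
                                endian = "little"), "gzip"), con)
  close(con)
  expect_equal(read_volume(tmp)$values, vol, ignore_attr = TRUE)
})

test_that("malformed volumes raise shape/format errors", {
  tmp <- withr::local_tempdir()
  # header promises 2x2x2 but fewer values present
  bad <- file.path(tmp, "bad.nrrd")
  con <- file(bad, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 2 2",
               "encoding: raw", ""), con)
  writeBin(as.numeric(1:5), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(bad), "too short")
  # raw with sidecar disagreeing on length
  rawp <- file.path(tmp, "bad.raw")
  writeBin(as.numeric(1:9), rawp, size = 8, endian = "little")
  jsonlite::write_json(list(dims = c(2, 2, 2), dtype = "float64"),
                       paste0(rawp, ".json"))
  expect_error(read_volume(rawp), "does not match")
  # not a volume at all
  txt <- file.path(tmp, "junk.nrrd")
  writeLines("hello", txt)
  expect_error(read_volume(txt), "magic")
  expect_error(read_volume(file.path(tmp, "nope.nrrd")), "not found")
})

test_that("gene manifests reject duplicates and preserve order", {
  tmp <- withr::local_tempfile()
  write_gene_manifest(c("Prox1", "Gabra6", "Gpr6"), tmp)
  expect_identical(read_gene_manifest(tmp), c("Prox1", "Gabra6", "Gpr6"))
  writeLines(c("a", "b", "a"), tmp)
  expect_error(read_gene_manifest(tmp), "duplicated")
})

test_that("assemble_matrix honours mask order and round-trips with unmask", {
  dims <- c(5, 4, 3)
  set.seed(42)
  vals <- array(rgamma(prod(dims) * 3, 1), c(dims, 3))
  tensor <- expression_tensor(vals, c("g1", "g2", "g3"))
  inside <- array(FALSE, dims)
  inside[2:4, 2:3, 1:2] <- TRUE
  mask <- voxel_mask(inside)
  X <- assemble_matrix(tensor, mask)
  expect_equal(dim(X), c(sum(inside), 3L))
  expect_identical(colnames(X), c("g1", "g2", "g3"))
  # row order = linear-index order of in-mask voxels
  expect_equal(X[, 2], vals[, , , 2][inside])
  # unmask inverts inside the mask, zero outside
  back <- unmask(X, mask)
  expect_equal(back[, , , 1][inside], X[, 1])
  expect_true(all(back[, , , 1][!inside] == 0))
  # idempotence of assemble o unmask o assemble
  tensor2 <- expression_tensor(back, tensor$genes)
  expect_equal(assemble_matrix(tensor2, mask), X)
  # full grid on the study dims gives one row per voxel
  expect_equal(nrow(assemble_matrix(tensor, full_mask(dims))), prod(dims))
})

test_that("assemble_matrix refuses residual missing values inside the mask", {
  dims <- c(4, 4, 4)
  vals <- array(1, c(dims, 2))
  vals[2, 2, 2, 1] <- NA
  tensor <- expression_tensor(vals, c("a", "b"))
  expect_error(assemble_matrix(tensor, full_mask(dims)), "missing")
})

test_that("expression tensors validate genes and non-negativity", {
  vals <- array(1, c(2, 2, 2, 2))
  expect_error(expression_tensor(vals, c("a", "a")), "unique")
  vals2 <- vals; vals2[1] <- -1
  expect_error(expression_tensor(vals2, c("a", "b")), "non-negative")
  t <- expression_tensor(vals, c("a", "b"))
  expect_equal(tensor_gene(t, "b"), array(1, c(2, 2, 2)))
})

test_that("tensor and atlas files round-trip", {
  tmp <- withr::local_tempdir()
  st <- tiny_study(seed = 11, dims = c(8, 7, 6), n_regions = 4, n_genes = 5,
                   K_true = 2)
  prefix <- file.path(tmp, "tensor")
  write_expression_tensor(st$sim$tensor, prefix)
  back <- read_expression_tensor(prefix)
  expect_equal(back$values, st$sim$tensor$values)
  expect_identical(back$missing, st$sim$tensor$missing)
  expect_identical(back$genes, st$sim$tensor$genes)
  write_atlas(st$atlas, file.path(tmp, "atlas.nrrd"),
              file.path(tmp, "ont.tsv"))
  atlas2 <- read_atlas(file.path(tmp, "atlas.nrrd"), file.path(tmp, "ont.tsv"))
  expect_identical(atlas2$labels, st$atlas$labels)
  expect_equal(atlas2$ontology$parent_label, st$atlas$ontology$parent_label)
})

test_that("atlas validation enforces ontology coverage and forest structure", {
  labels <- array(0L, c(3, 3, 3))
  labels[1, 1, 1] <- 5L
  expect_error(brain_atlas(labels, data.frame(label = 1, name = "a",
                                              parent_label = 0, level = 1)),
               "absent from ontology")
  ont <- data.frame(label = c(1, 2), name = c("a", "b"),
                    parent_label = c(2, 1), level = c(1, 1))
  labels[1, 1, 1] <- 1L
  expect_error(brain_atlas(labels, ont), "cycle")
})
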