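test_that("MatrixMarket coordinate files expand to the expected dense matrix", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "2 2 3"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  m <- read_count_matrix(dir, format = "mtx")
  expect_equal(unname(m$values), rbind(c(5, 0), c(0, 3), c(0, 0)))
  expect_equal(m$gene_ids, c("g1", "g2", "g3"))
  expect_equal(m$sample_ids, c("c1", "c2"))
  expect_equal(m$layer, "raw")
})

test_that("mtx write -> read roundtrip is the identity", {
  dir <- withr::local_tempdir()
  vals <- matrix(rpois(100, 3), 10, 10)
  m <- count_matrix(vals, sprintf("g%d", 1:10), sprintf("s%d", 1:10))
  write_count_matrix(m, dir)
  m2 <- read_count_matrix(dir, format = "mtx")
  expect_identical(m2$values, m$values)
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$sample_ids, m$sample_ids)
  # deterministic re-read
  m3 <- read_count_matrix(dir, format = "mtx")
  expect_identical(m2, m3)
})

test_that("dimension mismatches and bad values are format errors", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 5"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3", "g4"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_count_matrix(dir), "format error")

  writeLines(c("g1", "g2", "g1"), file.path(dir, "features.tsv"))
  expect_error(read_count_matrix(dir), "duplicate gene ids: g1")

  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 -4"),
             file.path(dir, "matrix.mtx"))
  expect_error(read_count_matrix(dir), "negative")
})

test_that("samples-by-genes orientation flag transposes on read", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 2", "1 1 7", "2 3 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  m <- read_count_matrix(dir, orientation = "samples_by_genes")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$values["g1", "c1"], 7)
  expect_equal(m$values["g3", "c2"], 1)
})

test_that("CSV matrices read with genes as rows and sample-id header", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,1,2", "g2,0,4"), path)
  m <- read_count_matrix(path, format = "csv")
  expect_equal(unname(m$values), rbind(c(1, 2), c(0, 4)))
  expect_equal(m$sample_ids, c("s1", "s2"))
})

test_that("fraction map CSV serialisation and roundtrip", {
  path <- withr::local_tempfile(fileext = ".csv")
  fm <- fraction_map(rbind(c(0.3, 0.7), c(1, 0)),
                     spot_ids = c("s1", "s2"),
                     cell_types = c("typeA", "typeB"))
  write_fraction_map(fm, path)
  expect_equal(readLines(path, n = 1), "spot_id,typeA,typeB")
  back <- read_fraction_map(path)
  expect_lt(max(abs(back$fractions - fm$fractions)), 1e-12)

  # random row-stochastic matrix
  set.seed(42)
  raw <- matrix(runif(40), 8, 5)
  fm2 <- fraction_map(raw / rowSums(raw))
  write_fraction_map(fm2, path)
  expect_lt(max(abs(read_fraction_map(path)$fractions - fm2$fractions)),
            1e-12)

  # empty map -> header only
  fm0 <- fraction_map(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("a", "b"))))
  write_fraction_map(fm0, path)
  expect_equal(readLines(path), "spot_id,a,b")
})

test_that("annotation TSVs read with or without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel", "c1\tA", "c2\tB"), path)
  a <- read_annotation(path)
  expect_equal(a$label, c("A", "B"))
  writeLines(c("c1\tA", "c2\tB"), path)
  expect_equal(read_annotation(path), a)
})
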