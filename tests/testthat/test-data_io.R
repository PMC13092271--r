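test_that("MTX round-trip reproduces the CellMatrix", {
  cm <- toyCellMatrix()
  dir <- withr::local_tempdir()
  writeCellMatrix(cm, dir)
  file.rename(file.path(dir, "meta.tsv"), file.path(dir, "cellmeta.tsv"))
  cm2 <- readCellMatrix(dir, file.path(dir, "cellmeta.tsv"))
  expect_equal(dim(cm2), c(3L, 4L))
  expect_identical(
    as.matrix(SummarizedExperiment::assay(cm2, "counts")),
    as.matrix(SummarizedExperiment::assay(cm, "counts")))
  expect_identical(cellMeta(cm2), cellMeta(cm))
})

test_that("dense CSV read agrees with the MTX read", {
  cm <- toyCellMatrix()
  dir <- withr::local_tempdir()
  writeCellMatrix(cm, dir)
  dense <- as.matrix(SummarizedExperiment::assay(cm, "counts"))
  csv <- file.path(dir, "dense.csv")
  utils::write.csv(data.frame(gene = rownames(dense), dense,
                              check.names = FALSE),
                   csv, row.names = FALSE, quote = FALSE)
  a <- readCellMatrix(dir, file.path(dir, "meta.tsv"))
  b <- readCellMatrix(csv, file.path(dir, "meta.tsv"))
  expect_identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                   as.matrix(SummarizedExperiment::assay(b, "counts")))
  expect_identical(cellMeta(a), cellMeta(b))
})

test_that("metadata contract is enforced, naming the missing column", {
  cm <- toyCellMatrix()
  dir <- withr::local_tempdir()
  writeCellMatrix(cm, dir)
  meta <- readResultTable(file.path(dir, "meta.tsv"))
  meta$timepoint <- NULL
  writeResultTable(meta, file.path(dir, "meta2.tsv"))
  expect_error(readCellMatrix(dir, file.path(dir, "meta2.tsv")), "timepoint")
  # cells missing from metadata are rejected
  meta3 <- readResultTable(file.path(dir, "meta.tsv"))[-2, ]
  writeResultTable(meta3, file.path(dir, "meta3.tsv"))
  expect_error(readCellMatrix(dir, file.path(dir, "meta3.tsv")),
               "absent from metadata")
})

test_that("duplicate barcodes and duplicate gene symbols are handled", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("G1", "G2"), c("c1", "c1")))
  meta <- data.frame(cell_id = c("c1", "c1"), sample_id = "s1",
                     patient_id = "p1", timepoint = "pre", cell_type = "T")
  expect_error(CellMatrix(m, meta), "duplicate")
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 4"), file.path(dir, "matrix.mtx"))
  writeLines(c("G1", "G1"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1",
                     patient_id = "p1", timepoint = "pre", cell_type = "T")
  writeResultTable(meta, file.path(dir, "meta.tsv"))
  expect_warning(cm <- readCellMatrix(dir, file.path(dir, "meta.tsv")),
                 "disambiguated")
  expect_identical(rownames(cm), c("G1", "G1.1"))
})

test_that("LR databases union, deduplicate, parse complexes, drop blanks", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "db1.tsv"); f2 <- file.path(dir, "db2.csv")
  writeResultTable(data.frame(
    ligand = c("TNF", "ICAM1", "RPS19", "CSF1", "BAD"),
    receptor = c("TNFRSF1A", "ITGAL/ITGB2", "C5AR1", "CSF1R", ""),
    source = "kegg"), f1)
  utils::write.csv(data.frame(ligand = c("TNF", "TNFSF14"),
                              receptor = c("TNFRSF1A", "LTBR"),
                              source = "rami"), f2, row.names = FALSE)
  expect_warning(db <- readLRDatabase(c(f1, f2)), "blank")
  expect_equal(nrow(db), 4 + 2 - 1)        # union minus shared pair
  expect_identical(receptorSubunits(db$receptor[db$ligand == "ICAM1"])[[1]],
                   c("ITGAL", "ITGB2"))
  expect_identical(db$source[db$ligand == "TNF"], "kegg")
})

test_that("result tables round-trip losslessly", {
  x <- data.frame(gene = c("a", "b"), n = c(3L, 5L),
                  p = c(0.12345678901234567, 1e-300),
                  ok = c(TRUE, FALSE), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeResultTable(x, path)
  y <- readResultTable(path)
  expect_identical(y$gene, x$gene)
  expect_identical(y$n, x$n)
  expect_identical(y$ok, x$ok)
  expect_equal(y$p, x$p, tolerance = 1e-14)
})

test_that("network JSON round-trips, including the empty network", {
  path <- withr::local_tempfile(fileext = ".json")
  empty <- buildNetwork(list())
  writeNetwork(empty, path)
  expect_equal(length(readNetwork(path)), 0L)
  tr <- data.frame(x_gene = c("a", "b"), y_gene = "c",
                   sender_type = "T", receiver_type = "M",
                   ligand = "L1", receptor = "R1_R2",
                   p_value = c(0.4, 0.6), stringsAsFactors = FALSE)
  net <- buildNetwork(groupGEMs(tr))
  writeNetwork(net, path)
  net2 <- readNetwork(path)
  expect_equal(channels(net2), channels(net))
})
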