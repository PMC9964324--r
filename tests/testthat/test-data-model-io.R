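test_that("expression matrix validates labels, mode and missing values", {
  x <- matrix(1:6, 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  e <- expression_matrix(x + 0, "log_intensity")
  expect_s3_class(e, "ExpressionMatrix")
  expect_identical(dim(e), c(3L, 2L))
  expect_error(expression_matrix(unname(x + 0), "counts"), "identifiers")
  xd <- x; rownames(xd) <- c("A", "A", "C")
  expect_error(expression_matrix(xd + 0, "counts"), "duplicate gene")
  xn <- x + 0; xn[1, 1] <- NA
  expect_error(expression_matrix(xn, "counts"), "missing")
  expect_error(expression_matrix(x - 10, "counts"), ">= 0")
})

test_that("dense TSV round-trips to an identical matrix", {
  e <- random_expr(3, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(e, path)
  back <- read_expression(path)
  expect_identical(gene_ids(back), gene_ids(e))
  expect_identical(sample_ids(back), sample_ids(e))
  expect_equal(back$values, e$values, tolerance = 1e-6)
})

test_that("duplicate gene rows collapse to the highest-mean row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "G1\t5.0\t5.0",
               "G2\t2.0\t2.0",
               "G1\t1.0\t1.0"), path)
  expect_message(e <- read_expression(path), "collapsed 1 duplicate")
  expect_identical(gene_ids(e), c("G1", "G2"))
  expect_equal(unname(e$values["G1", ]), c(5, 5))
})

test_that("MTX with sidecars loads with the expected zeros", {
  dirp <- withr::local_tempdir()
  counts <- matrix(c(3, 0, 1, 0, 2, 5), nrow = 3,
                   dimnames = list(c("GA", "GB", "GC"), c("c1", "c2")))
  e0 <- expression_matrix(counts, "counts")
  write_mtx(e0, file.path(dirp, "m.mtx"), file.path(dirp, "genes.txt"),
            file.path(dirp, "cells.txt"))
  e <- read_expression(file.path(dirp, "m.mtx"), mode = "counts",
                       genes_path = file.path(dirp, "genes.txt"),
                       samples_path = file.path(dirp, "cells.txt"))
  expect_equal(sum(e$values == 0), 2L)
  expect_equal(e$values, counts)
  # dimension mismatch between matrix and sidecar is an error
  writeLines(c("GA", "GB"), file.path(dirp, "genes.txt"))
  expect_error(
    read_expression(file.path(dirp, "m.mtx"), mode = "counts",
                    genes_path = file.path(dirp, "genes.txt"),
                    samples_path = file.path(dirp, "cells.txt")),
    "sidecar")
})

test_that("missing values error with location, or drop on request", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\tNA", "G2\t2\t3"), path)
  expect_error(read_expression(path), "G1.*s2")
  expect_message(e <- read_expression(path, drop_missing = TRUE), "dropping 1")
  expect_identical(gene_ids(e), "G2")
})

test_that("GMT parsing follows the 3-field contract", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("CUP_POS\tna\tLIAS\tDLD",
               "DUPSET\tna\tGLS\tGLS"), path)
  expect_warning(sets <- read_gmt(path), "duplicate")
  expect_length(sets, 2L)
  expect_identical(names(sets), c("CUP_POS", "DUPSET"))
  expect_setequal(sets$CUP_POS$genes, c("LIAS", "DLD"))
  expect_length(sets$DUPSET$genes, 1L)
  writeLines(c("OK\tna\tA", "BAD\tna"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("bundled gene-set pairs load and keep components disjoint", {
  for (f in c("cuproptosis_cpi.gmt", "cuproptosis_cpi_fdx1.gmt",
              "fpi_synthetic.gmt")) {
    pair <- read_gene_set_pair(system.file("extdata", f, package = "fpicpi"))
    expect_s3_class(pair, "GeneSetPair")
    expect_length(intersect(pair$positive$genes, pair$negative$genes), 0L)
  }
  printed <- read_gene_set_pair(
    system.file("extdata", "cuproptosis_cpi.gmt", package = "fpicpi"))
  expect_setequal(printed$positive$genes, cpi_definition()$pair$positive$genes)
  expect_setequal(printed$negative$genes, cpi_definition()$pair$negative$genes)
})

test_that("write_table produces stable TSV and round-trips to 6 s.f.", {
  path <- withr::local_tempfile(fileext = ".tsv")
  es <- data.frame(gene_set = rep(c("A", "B"), each = 3),
                   sample_id = rep(paste0("s", 1:3), 2),
                   es = c(pi, exp(1), sqrt(2), -pi, 1 / 3, 2 / 7))
  write_table(es, path)
  lines <- readLines(path)
  expect_length(lines, 7L)  # header + 2 sets x 3 samples
  back <- read_table(path)
  expect_equal(back$es, es$es, tolerance = 1e-5)
  # empty result writes a header-only file
  write_table(es[0, ], path)
  expect_length(readLines(path), 1L)
  expect_error(write_table(es, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})

test_that("metadata and survival readers enforce required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(data.frame(sample_id = c("s1", "s2"), treatment = "control"),
              path)
  meta <- read_sample_metadata(path)
  expect_s3_class(meta, "SampleMetadata")
  write_table(data.frame(id = "s1"), path)
  expect_error(read_sample_metadata(path), "sample_id")
  write_table(data.frame(subject_id = c("p1", "p2"), time = c(1, 2),
                         event = c(1, 0), covariate = c(0.5, -0.5)), path)
  rec <- read_survival_records(path)
  expect_s3_class(rec, "SurvivalRecords")
  expect_equal(rec$event, c(1L, 0L))
  write_table(data.frame(subject_id = "p1", time = 1), path)
  expect_error(read_survival_records(path), "columns")
})
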