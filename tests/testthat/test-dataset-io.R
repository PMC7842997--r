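test_that("CSV read maps labels in first-appearance order and transposes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,label",
               "1.5,2,healthy",
               "3,4,disease",
               "5,6.25,healthy",
               "7,8,disease"), path)
  ds <- read_csv_dataset(path)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds), c(2L, 4L))
  expect_equal(ds$gene_ids, c("g1", "g2"))
  expect_equal(ds$labels, c(0L, 1L, 0L, 1L))        # healthy first -> 0
  expect_equal(ds$class_names, c("healthy", "disease"))
  expect_equal(unname(ds$values["g2", ]), c(2, 4, 6.25, 8))
})

test_that("CSV write/read round-trips a dataset", {
  ds <- toy_ds()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_csv_dataset(path)
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  # a written 2-gene dataset has exactly 3 header fields
  expect_length(strsplit(readLines(path, n = 1), ",")[[1]], 3L)
})

test_that("CSV reader rejects malformed inputs with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(read_csv_dataset("no/such/file.csv"), "not found")

  writeLines(c("g1,label", "1,a", "2,b", "3,c"), path)
  expect_error(read_csv_dataset(path), "exactly 2 distinct")

  writeLines(c("g1,g2,label", "1,x,a", "2,3,b", "4,5,a"), path)
  expect_error(read_csv_dataset(path), "row 1, column 'g2'")
})

test_that("dataset constructor enforces its invariants", {
  m <- matrix(1:8, 2, 4)
  expect_error(expression_dataset(m, "g1", paste0("S", 1:4),
                                  c(0L, 0L, 1L, 1L)), "row count")
  expect_error(expression_dataset(m, c("g1", "g1"), paste0("S", 1:4),
                                  c(0L, 0L, 1L, 1L)), "duplicate gene ids")
  expect_error(expression_dataset(m, c("g1", "g2"), c("S1", "S1", "S2", "S3"),
                                  c(0L, 0L, 1L, 1L)), "duplicate sample ids")
  expect_error(expression_dataset(m, c("g1", "g2"), paste0("S", 1:4),
                                  c(0L, 0L, 0L, 0L)), "two classes")
  expect_error(expression_dataset(m, c("g1", "g2"), paste0("S", 1:4),
                                  c(0L, 0L, 0L, 1L)), "at least 2 samples")
})

test_that("empty gene set refuses to be written", {
  ds <- toy_ds()
  ds$values <- ds$values[0, , drop = FALSE]
  ds$gene_ids <- character(0)
  expect_error(write_dataset_csv(ds, withr::local_tempfile()), "no genes")
})

test_that("gene list export orders by descending score with id tie-break", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gene_list(c("b", "a", "c", "d"), c(2, 3, 1, 2), path)
  out <- read.csv(path)
  expect_equal(out$gene_id, c("a", "b", "d", "c"))
  expect_equal(out$score, c(3, 2, 2, 1))
  # 200 genes in -> 200 data rows out
  write_gene_list(sprintf("g%03d", 1:200), 200:1, path)
  expect_equal(nrow(read.csv(path)), 200L)
})

test_that("SOFT parser reads a hand-written fixture in table order", {
  path <- withr::local_tempfile(fileext = ".soft")
  writeLines(c("^DATASET = tiny",
               "!dataset_table_begin",
               "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3\tGSM4",
               "p1\tGENE1\t1\t2\t3\t4",
               "p2\tGENE2\t5\t6\t7\t8",
               "p3\tGENE3\t9\t10\t11\t12",
               "!dataset_table_end"), path)
  spec <- soft_class_spec("1-2", "3-4", names = c("ctrl", "case"))
  ds <- read_soft_gds(path, spec)
  expect_equal(ds$gene_ids, c("p1", "p2", "p3"))
  expect_equal(ds$sample_ids, paste0("GSM", 1:4))
  expect_equal(ds$labels, c(0L, 0L, 1L, 1L))
  expect_equal(unname(ds$values["p2", ]), c(5, 6, 7, 8))
  expect_length(attr(ds, "parse_log"), 0L)
})

test_that("SOFT parser applies the null-cell policies and logs them", {
  path <- withr::local_tempfile(fileext = ".soft")
  writeLines(c("!dataset_table_begin",
               "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3\tGSM4",
               "p1\tG\t1\t2\t3\t4",
               "p2\tG\t5\tnull\t7\t8",
               "p1\tG\t9\t10\t11\t12",
               "!dataset_table_end"), path)
  spec <- soft_class_spec("1-2", "3-4")

  ds <- read_soft_gds(path, spec)                   # default: drop
  expect_equal(ds$gene_ids, c("p1", "p1#1"))        # duplicate suffixed
  log <- attr(ds, "parse_log")
  expect_equal(sum(grepl("^DROPPED p2", log)), 1L)
  expect_true(any(grepl("^RENAMED p1", log)))

  ds2 <- read_soft_gds(path, spec, na_policy = "impute")
  expect_equal(length(ds2$gene_ids), 3L)
  expect_equal(unname(ds2$values["p2", "GSM2"]), mean(c(5, 7, 8)))
  expect_true(any(grepl("^IMPUTED p2", attr(ds2, "parse_log"))))
})

test_that("SOFT parser validates delimiters and class ranges", {
  path <- withr::local_tempfile(fileext = ".soft")
  writeLines(c("!dataset_table_begin",
               "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3\tGSM4",
               "p1\tG\t1\t2\t3\t4"), path)
  spec <- soft_class_spec("1-2", "3-4")
  expect_error(read_soft_gds(path, spec), "table_begin")

  writeLines(c("!dataset_table_begin",
               "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3\tGSM4",
               "p1\tG\t1\t2\t3\t4",
               "p2\tG\t1\t2\t3\t4",
               "!dataset_table_end"), path)
  expect_error(read_soft_gds(path, soft_class_spec("1-2", "3-6")),
               "only 4 sample columns")
  expect_error(soft_class_spec("1-3", "3-4"), "overlap")
})
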