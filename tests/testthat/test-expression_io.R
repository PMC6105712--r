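test_that("expression matrix reader validates shape, ids and values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "GA\t8\t8", "GB\t9\t8", "GC\t7\t7"), path)
  m <- read_expression_matrix(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("GA", "GB", "GC"))
  expect_equal(m["GB", "s1"], 9)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "MYOD1\t8", "MYOD1\t9"), dup)
  expect_error(read_expression_matrix(dup), class = "kdtc_duplicate_id")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "GA\toops"), bad)
  expect_error(read_expression_matrix(bad), class = "kdtc_non_numeric")

  expect_error(read_expression_matrix(file.path(tempdir(), "nope.tsv")),
               class = "kdtc_missing_file")
})

test_that("linear-scale input is log2-transformed on load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "GA\t256", "GB\t2"), path)
  m <- read_expression_matrix(path, input_scale = "linear")
  expect_equal(unname(m[, 1]), c(8, 1))
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "GA\t-1"), neg)
  expect_error(read_expression_matrix(neg, input_scale = "linear"),
               class = "kdtc_non_positive")
})

test_that("generator matrix and sheet round-trip value-identically", {
  sim <- generate_dataset(small_config(), seed = 11)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$values, mpath)
  write_sample_sheet(sim$sheet, spath)
  m2 <- read_expression_matrix(mpath)
  s2 <- read_sample_sheet(spath)
  ord <- rownames(sim$values)[order(rownames(sim$values), method = "radix")]
  expect_equal(m2, sim$values[ord, colnames(m2)], tolerance = 1e-12)
  expect_setequal(s2$sample_id, sim$sheet$sample_id)
  expect_identical(nrow(s2), 5L * 4L)
  expect_identical(
    s2$condition[match(sim$sheet$sample_id, s2$sample_id)],
    sim$sheet$condition)
})

test_that("sample sheet vocabulary is enforced", {
  ok <- sample_sheet(data.frame(sample_id = "s1", condition = "siCBP",
                                timepoint = "T48"))
  expect_s3_class(ok, "kdtc_sheet")
  expect_error(
    sample_sheet(data.frame(sample_id = "s2", condition = "siFOO",
                            timepoint = "T48")),
    class = "kdtc_unknown_condition")
  expect_error(
    sample_sheet(data.frame(sample_id = "s2", condition = "siCBP",
                            timepoint = "T13")),
    class = "kdtc_unknown_timepoint")
  expect_error(
    sample_sheet(data.frame(sample_id = c("s1", "s1"),
                            condition = "siCBP", timepoint = "T48")),
    class = "kdtc_duplicate_id")
})

test_that("validate_design catches missing samples and reference gaps", {
  sheet <- full_sheet()
  values <- design_matrix(sheet)
  expect_true(validate_design(values, sheet))
  expect_error(validate_design(values[, -1], sheet), class = "kdtc_design_error")
  no_ref <- sheet[sheet$condition != "siCTR", ]
  attr(no_ref, "timepoints") <- attr(sheet, "timepoints")
  class(no_ref) <- class(sheet)
  expect_error(validate_design(values, no_ref), class = "kdtc_design_error")
})

test_that("gene lists read from plain text and GMT", {
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Myod1", "MYOG", " myog "), plain)
  gl <- read_gene_list(plain, format = "plain")
  expect_identical(gl$genes, c("Myod1", "MYOG", "myog"))

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("blum_enh\tdesc\tA\tB", gmt)
  g2 <- read_gene_list(gmt, format = "gmt")
  expect_identical(g2$name, "blum_enh")
  expect_setequal(g2$genes, c("A", "B"))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_gene_list(empty, format = "plain"), class = "kdtc_empty_list")

  malformed <- withr::local_tempfile(fileext = ".gmt")
  writeLines("name_only\tdesc", malformed)
  expect_error(read_gene_list(malformed, format = "gmt"),
               class = "kdtc_malformed_gmt")
})

test_that("gene sets written as GMT round-trip exactly", {
  sim <- generate_dataset(small_config(noise_sd = 0), seed = 3)
  cl <- classify_dataset(sim)
  dir <- withr::local_tempdir()
  write_gene_sets(cl, dir)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  for (nm in names(sets)) {
    expect_setequal(sets[[nm]]$genes, cl$gene_id[cl$category == nm])
  }
  expect_setequal(names(sets), unique(cl$category))
  long <- read.delim(file.path(dir, "gene_sets.tsv"), stringsAsFactors = FALSE)
  expect_identical(sort(unique(long$condition)),
                   sort(c("siCBP", "siP300", "siCBP_P300")))
  expect_identical(nrow(long), nrow(cl) * 3L * 4L)
})
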