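test_that("expression matrices round-trip through TSV bitwise", {
  x <- make_expr(15, 6, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  y <- read_expression(path)
  expect_identical(unclass(y), unclass(x))

  small <- read_expression({
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4", "C\t5\t6"), p)
    p
  })
  expect_equal(dim(small), c(3L, 2L))
})

test_that("malformed expression input raises typed parse errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t2", "A\t3\t4"), p)
  expect_error(read_expression(p), "A", class = "icb_validation_error")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\tnot_a_number"), p2)
  expect_error(read_expression(p2), "not_a_number", class = "icb_parse_error")
})

test_that("linear-scale loading applies log2(x + 1)", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t0\t3", "B\t7\t1"), p)
  x <- read_expression(p, linear = TRUE)
  expect_equal(unname(x["A", ]), c(0, 2))
  expect_equal(unname(x["B", ]), c(3, 1))
})

test_that("copy calls accept long and wide dialects equivalently", {
  cc <- copy_call_table(
    sample_id = rep(c("s1", "s2"), each = 2),
    gene_id = rep(c("CDKN2A", "MTAP"), 2),
    call = c(-2, -2, 0, -1)
  )
  long <- withr::local_tempfile(fileext = ".tsv")
  wide <- withr::local_tempfile(fileext = ".tsv")
  write_copy_calls(cc, long, format = "long")
  write_copy_calls(cc, wide, format = "wide")
  a <- read_copy_calls(long)
  b <- read_copy_calls(wide)
  key <- function(d) d[order(d$sample_id, d$gene_id), ]
  expect_equal(key(as.data.frame(a)), key(as.data.frame(b)),
               ignore_attr = TRUE)
  expect_equal(nrow(a), 4L)
})

test_that("out-of-range copy calls are rejected with the offending value", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tcall", "s1\tCDKN2A\t-3"), p)
  expect_error(read_copy_calls(p), "-3", class = "icb_validation_error")
})

test_that("clinical tables validate vocabulary and time fields", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tresponse\tos_time\tos_event",
               "s1\tCR\t12\t1", "s2\tSD\t3.5\t0"), p)
  cl <- read_clinical(p)
  expect_s3_class(cl, "clinical_table")
  expect_identical(cl$os_event, c(TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tresponse", "s1\tRESPONDER"), bad)
  expect_error(read_clinical(bad), "RESPONDER", class = "icb_validation_error")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_time", "s1\t-2"), neg)
  expect_error(read_clinical(neg), "negative", class = "icb_validation_error")
})

test_that("explicit dcb column agrees with derive_dcb on derivable rows", {
  cl <- clinical_table(data.frame(
    sample_id = c("s1", "s2", "s3"),
    response = c("SD", "SD", "PR"),
    pfs_time = c(7, 5, 2),
    dcb = c(TRUE, FALSE, TRUE)
  ))
  expect_identical(derive_dcb(cl$response, cl$pfs_time), cl$dcb)
})

test_that("gene sets round-trip through GMT and deduplicate with warning", {
  gs <- gene_set_collection(list(alpha = c("A", "B", "C"), beta = c("D", "E")))
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(gs, p)
  back <- read_gene_sets(p)
  expect_identical(unclass(back)[names(gs)], unclass(gs)[names(gs)],
                   ignore_attr = TRUE)
  expect_equal(length(back), 2L)

  expect_warning(gene_set_collection(list(s = c("A", "A", "B"))),
                 "duplicate")
  dup <- suppressWarnings(gene_set_collection(list(s = c("A", "A", "B"))))
  expect_identical(dup$s, c("A", "B"))
  expect_error(gene_set_collection(list(s = character(0))),
               class = "icb_validation_error")
})

test_that("write_results emits a TSV plus JSON sidecar carrying the seed", {
  res <- data.frame(stratum = c("hi_hi", "lo_lo"), rate = c(0.32, 0.12))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, p, seed = 42L, config = list(basis = "surrogate"))
  back <- read.delim(p)
  expect_equal(back$rate, res$rate)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$seed, 42L)
  expect_true(nzchar(meta$config_hash))

  empty <- res[0, ]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(empty, p2)
  expect_equal(nrow(read.delim(p2)), 0L)
})
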