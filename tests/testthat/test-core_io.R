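test_that("omic matrix round-trips through the tab-separated format", {
  m <- tiny_matrix(3, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omic_matrix(m, path)
  back <- read_omic_matrix(path, "mrna")
  expect_identical(back$feature_ids, m$feature_ids)
  expect_identical(back$sample_ids, m$sample_ids)
  expect_lt(max(abs(back$values - m$values)), 1e-9)

  # missing cells survive as NA, never zero
  m$values[2, 1] <- NA
  write_omic_matrix(m, path)
  expect_true(is.na(read_omic_matrix(path, "mrna")$values[2, 1]))
})

test_that("matrix reader rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_omic_matrix(path, "mrna"), "gA")
  writeLines(c("feature_id\ts1\ts2", "gA\t1\tx", "gB\t3\t4"), path)
  expect_error(read_omic_matrix(path, "mrna"), "row 1.*column 2")
  expect_error(omic_matrix(matrix(c(0.2, 1.4), 2, 1,
                                  dimnames = list(c("c1", "c2"), "s1")),
                           "methylation"),
               "\\[0, 1\\]")
})

test_that("GMT reader loads sets, de-duplicates members, and flags short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg1\tg2\tg3\tg4\tg5"), path)
  gs <- read_gmt(path)
  expect_length(gs$sets, 2)
  expect_identical(lengths(gs$sets), c(setA = 3L, setB = 5L))

  writeLines("setA\tdesc\tg1\tg1\tg2", path)
  expect_warning(gs <- read_gmt(path), "duplicate")
  expect_identical(gs$sets$setA, c("g1", "g2"))

  writeLines("setA\tdesc", path)
  expect_error(read_gmt(path), "line 1")

  writeLines(character(), path)
  expect_length(read_gmt(path)$sets, 0)

  # round trip
  writeLines(c("setA\ta set\tg1\tg2\tg3", "setB\tother\tg4\tg5\tg6\tg7"), path)
  gs <- read_gmt(path)
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path2)
  expect_identical(read_gmt(path2)$sets, gs$sets)
})

test_that("clinical table enforces required columns and value ranges", {
  df <- data.frame(sample_id = paste0("s", 1:5), age = c(3, 7, 12, 9, 15),
                   sex = "F", location = "Infratentorial",
                   braf_status = "Fusion", pfs_time = c(10, 20, 30, 5, 12),
                   pfs_event = c(1, 0, 1, 0, 1), extra = letters[1:5])
  ct <- clinical_table(df)
  expect_s3_class(ct, "clinical_table")
  expect_identical(nrow(ct), 5L)
  expect_identical(unique(ct$location), "infratentorial")  # lower-cased
  expect_true("extra" %in% names(ct))                      # extras preserved

  expect_error(clinical_table(transform(df, pfs_event = 2)), "pfs_event")
  expect_error(clinical_table(df[, setdiff(names(df), "age")]), "age")
  expect_error(clinical_table(transform(df, pfs_time = -1)), "negative")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_table(ct, path)
  back <- read_clinical_table(path)
  expect_equal(back$pfs_time, ct$pfs_time)
  expect_identical(back$sample_id, ct$sample_id)
})

test_that("align_cohort restricts every object to shared samples in one order", {
  a <- tiny_matrix(4, 3, seed = 1)   # s01..s03
  b0 <- tiny_matrix(4, 3, seed = 2)
  b <- omic_matrix(b0$values, "protein",
                   sample_ids = c("s02", "s03", "s04"),
                   feature_ids = b0$feature_ids)
  al <- suppressMessages(align_cohort(list(mrna = a, protein = b)))
  expect_identical(al$matrices$mrna$sample_ids, c("s02", "s03"))
  expect_identical(al$matrices$protein$sample_ids, c("s02", "s03"))
  expect_equal(al$matrices$protein$values[, "s02"], b$values[, "s02"])

  # identity when sample sets match
  al2 <- suppressMessages(align_cohort(list(a = a, b = tiny_matrix(4, 3, seed = 3))))
  expect_equal(al2$matrices$a$values, a$values)

  # disjoint -> error
  c0 <- omic_matrix(b0$values, "protein",
                    sample_ids = c("x1", "x2", "x3"),
                    feature_ids = b0$feature_ids)
  expect_error(suppressMessages(align_cohort(list(a, c0))), "shared")

  # clinical restricted in the same order
  cl <- clinical_table(data.frame(sample_id = c("s03", "s02", "s01"),
                                  age = 1:3, sex = "f", location = "i",
                                  braf_status = "fusion", pfs_time = 1:3,
                                  pfs_event = 0))
  al3 <- suppressMessages(align_cohort(list(mrna = a, protein = b), cl))
  expect_identical(al3$clinical$sample_id, c("s02", "s03"))
})

test_that("signature matrix rejects negative and all-zero profiles", {
  p <- matrix(runif(8), 4, 2, dimnames = list(paste0("m", 1:4), c("t1", "t2")))
  expect_s3_class(signature_matrix(p), "signature_matrix")
  p_neg <- p; p_neg[1, 1] <- -1
  expect_error(signature_matrix(p_neg), "non-negative")
  p0 <- p; p0[, 2] <- 0
  expect_error(signature_matrix(p0), "all-zero")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(signature_matrix(p), path)
  expect_lt(max(abs(read_signature_matrix(path)$profiles - p)), 1e-9)
})
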