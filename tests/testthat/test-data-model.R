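test_that("beta_matrix validates ranges, ids, and detection alignment", {
  b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
              dimnames = list(c("Cg01", "cg02"), c("s1", "s2")))
  m <- beta_matrix(b)
  expect_identical(probe_ids(m), c("cg01", "cg02"))  # canonical lower case
  expect_identical(dim(m), c(2L, 2L))

  bad <- b; bad[1, 1] <- 1.2
  expect_error(beta_matrix(bad), "out of \\[0,1\\].*cg01.*s1")
  dup <- b; rownames(dup) <- c("cg01", "CG01")
  expect_error(beta_matrix(dup), "duplicate probe ids")
  dp <- matrix(0.01, 2, 2)
  expect_error(beta_matrix(b, dp), "dimnames|dimensions")
  dimnames(dp) <- dimnames(b)
  expect_silent(beta_matrix(b, dp))
})

test_that("beta matrix file round-trip preserves every cell bit-exactly", {
  set.seed(11)
  b <- matrix(runif(30), 5, 6)
  b[2, 3] <- NA
  m <- make_bm(b)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(m, f1)
  m2 <- read_beta_matrix(f1)
  expect_identical(m2$betas, m$betas)
  # independent check: rewriting the re-read matrix reproduces the file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # csv dialect and transposed orientation
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_numeric <- utils::write.table
  write_numeric(t(as.data.frame(m$betas)), f3, sep = ",", quote = FALSE,
                col.names = NA)
  m3 <- read_beta_matrix(f3, dialect = "samples_in_rows")
  expect_equal(m3$betas, m$betas)
})

test_that("out-of-range and non-numeric cells in files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cg01\t0.2\t1.2", "cg02\t0.3\t0.4"), f)
  expect_error(read_beta_matrix(f), "out of \\[0,1\\]")
  writeLines(c("probe_id\ts1", "cg01\tabc"), f)
  expect_error(read_beta_matrix(f), "non-numeric")
})

test_that("metadata parsing enforces tier/age invariants and enums", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,age_years,confidence_tier,sex,tissue_source",
               "a,8.5,STRICT,f,Biopsy",
               "b,,relaxed_only,M,beachcast",
               "c,,unknown,,"), f)
  meta <- read_metadata(f)
  expect_identical(meta$confidence_tier, c("strict", "relaxed_only", "unknown"))
  expect_identical(meta$sex, c("F", "M", "unknown"))
  expect_identical(meta$tissue_source, c("biopsy", "beachcast", NA))
  expect_equal(meta$age_years[1], 8.5)

  writeLines(c("sample_id,age_years,confidence_tier", "a,,strict"), f)
  expect_error(read_metadata(f), "strict-tier sample")
  writeLines(c("sample_id,confidence_tier", "a,bogus"), f)
  expect_error(read_metadata(f), "unknown token")
})

test_that("strict subset is contained in the relaxed subset (31 of 48)", {
  meta <- make_tiered_meta(31, 48)
  strict <- training_subset(meta, "strict")
  relaxed <- training_subset(meta, "relaxed")
  expect_equal(nrow(strict), 31)
  expect_equal(nrow(relaxed), 48)
  expect_true(all(strict$sample_id %in% relaxed$sample_id))
})

test_that("the packaged dolphin clock matches its published definition", {
  clock <- load_published_clock("maui_hectors_8cpg")
  expect_length(clock$coefficients, 8)
  expect_equal(clock$intercept, -4.6720053)
  expect_equal(clock$coefficients[["cg20582188"]], -9.9140532)
  expect_equal(clock$coefficients[["cg24276148"]], 16.2120942)
  expect_error(load_published_clock("nope"), "unknown published clock")
})

test_that("clock serialization round-trips bit-exactly", {
  clock <- methyl_clock(
    intercept = -4.6720053 + 1e-9,
    coefficients = c(cg00000001 = 1 / 3, cg00000002 = -sqrt(2)),
    training_meta = list(alpha = 0.9, penalty = 0.123456789123456,
                         cpg_filter_threshold = 10,
                         training_set_label = "strict",
                         n_training = 31, seed = 7))
  f <- withr::local_tempfile(fileext = ".clock")
  write_clock(clock, f)
  back <- read_clock(f)
  expect_identical(back$intercept, clock$intercept)
  expect_identical(back$coefficients, clock$coefficients)
  expect_equal(back$training_meta$alpha, 0.9)
  expect_equal(back$training_meta$n_training, 31)
  expect_identical(back$training_meta$training_set_label, "strict")
})

test_that("merging training sets intersects probes and pools samples", {
  b1 <- make_bm(matrix(runif(12), 3, 4,
                       dimnames = list(c("cga", "cgb", "cgc"), NULL)))
  b2 <- make_bm(matrix(runif(6), 3, 2,
                       dimnames = list(c("cgb", "cgc", "cgd"),
                                       c("x1", "x2"))))
  m1 <- sample_metadata(sample_ids(b1), age_years = 1:4,
                        group_label = "dolphin")
  m2 <- sample_metadata(sample_ids(b2), age_years = 5:6,
                        group_label = "beluga")
  merged <- merge_training_sets(list(m = b1, meta = m1),
                                list(m = b2, meta = m2))
  expect_setequal(probe_ids(merged$m), c("cgb", "cgc"))
  expect_equal(ncol(merged$m$betas), 6)
  expect_setequal(merged$meta$group_label, c("dolphin", "beluga"))
  # commutativity up to ordering
  merged_ba <- merge_training_sets(list(m = b2, meta = m2),
                                   list(m = b1, meta = m1))
  expect_equal(merged$m$betas[, sort(colnames(merged$m$betas))],
               merged_ba$m$betas[probe_ids(merged$m),
                                 sort(colnames(merged_ba$m$betas))])
  # pooling a 67-sample set with a 31-sample strict set gives 98 samples
  big <- make_bm(matrix(0.5, 2, 67,
                        dimnames = list(c("cga", "cgb"),
                                        sprintf("bw%03d", 1:67))))
  small <- make_bm(matrix(0.5, 2, 31,
                          dimnames = list(c("cga", "cgb"),
                                          sprintf("md%03d", 1:31))))
  joint <- merge_training_sets(
    list(m = big, meta = sample_metadata(sample_ids(big))),
    list(m = small, meta = sample_metadata(sample_ids(small))))
  expect_equal(ncol(joint$m$betas), 98)
  expect_equal(nrow(joint$meta), 98)
  # errors: no shared probes, duplicate samples
  b3 <- make_bm(matrix(runif(4), 2, 2,
                       dimnames = list(c("cgx", "cgy"), c("z1", "z2"))))
  m3 <- sample_metadata(sample_ids(b3))
  expect_error(merge_training_sets(list(m = b1, meta = m1),
                                   list(m = b3, meta = m3)),
               "no shared probes")
  expect_error(merge_training_sets(list(m = b1, meta = m1),
                                   list(m = b1, meta = m1)),
               "duplicate sample ids")
})

test_that("joining betas and metadata fails loudly on sample mismatch", {
  b <- make_bm(matrix(runif(20), 4, 5))
  meta <- sample_metadata(sample_ids(b)[-5], age_years = 1:4)
  expect_error(probe_age_correlations(b, meta), "missing from metadata")
})
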