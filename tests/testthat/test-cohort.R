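test_that("rank-sum statistic and exact p match hand enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(w$W, 0)
  expect_equal(w$p, 1 / 3)
  # identical multisets: p = 1 under exact enumeration with midranks
  w2 <- wilcoxon_rank_sum(c(2, 5, 5), c(2, 5, 5), mode = "exact")
  expect_equal(w2$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum p equals brute-force enumeration for all small instances", {
  set.seed(51)
  for (rep in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    # half the draws from a small integer support to force ties
    pool <- if (rep %% 2 == 0) sample(1:4, nx + ny, replace = TRUE)
            else rnorm(nx + ny)
    x <- pool[seq_len(nx)]; y <- pool[-seq_len(nx)]
    got <- wilcoxon_rank_sum(x, y, mode = "exact")
    want <- oracle_ranksum(x, y)
    expect_equal(got$W, want$W)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    # agreement with the standard implementation when tie-free
    if (!anyDuplicated(pool)) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(got$W, unname(ref$statistic))
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("exact and normal-approximate rank-sum p agree for moderate n", {
  set.seed(52)
  x <- rnorm(15); y <- rnorm(15, mean = 0.8)
  pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p
  pa <- wilcoxon_rank_sum(x, y, mode = "normal_approx")$p
  expect_lt(abs(pe - pa), 0.02)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(pa, ref$p.value, tolerance = 1e-10)
})

test_that("rank-sum statistic is invariant under monotone transforms", {
  set.seed(53)
  x <- runif(8); y <- runif(10)
  w0 <- wilcoxon_rank_sum(x, y)
  for (f in list(function(z) z^3, function(z) exp(z), function(z) 5 * z - 2)) {
    wf <- wilcoxon_rank_sum(f(x), f(y))
    expect_equal(wf$W, w0$W)
    expect_equal(wf$p, w0$p)
  }
})

test_that("signed-rank test matches enumeration, identities, and edge cases", {
  v <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3), mode = "exact")
  expect_equal(v$V, 6)
  expect_equal(v$p, 0.25)
  # x = y is degenerate: V = 0, p = 1
  expect_equal(wilcoxon_signed_rank(1:5, 1:5), list(V = 0, p = 1))
  # antisymmetry: swapping the pair maps V to n(n+1)/2 - V
  set.seed(54)
  x <- rnorm(9); y <- rnorm(9)
  v1 <- wilcoxon_signed_rank(x, y); v2 <- wilcoxon_signed_rank(y, x)
  expect_equal(v1$V + v2$V, 9 * 10 / 2)
  expect_equal(v1$p, v2$p)
  # brute-force sign-pattern enumeration on random small instances
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    xx <- if (rep %% 2 == 0) sample(0:3, n, replace = TRUE) else rnorm(n)
    yy <- if (rep %% 2 == 0) sample(0:3, n, replace = TRUE) else rnorm(n)
    got <- wilcoxon_signed_rank(xx, yy, mode = "exact")
    want <- oracle_signrank(xx, yy)
    expect_equal(got$V, want$V)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # tie-free agreement with the standard implementation
  set.seed(55)
  a <- rnorm(12); b <- rnorm(12)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  got <- wilcoxon_signed_rank(a, b, mode = "exact")
  expect_equal(got$V, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("age structure summarizes periods and compares them", {
  preds <- setNames(c(7, 8, 9, 7, 8, 9), sprintf("s%d", 1:6))
  meta <- sample_metadata(sprintf("s%d", 1:6),
                          survey_period = rep(c("2015-2016", "2020-2021"),
                                              each = 3))
  rep <- age_structure(preds, meta, c("2015-2016", "2020-2021"),
                       n_boot = 500, seed = 3)
  p1 <- rep$per_period[["2015-2016"]]
  expect_equal(p1$mean, 8); expect_equal(p1$median, 8)
  # identical periods: exact two-sided p = 1
  expect_equal(rep$comparisons$p_value, 1)
  # bootstrap CI contains the sample mean and is seed-stable
  expect_true(p1$ci95_mean[1] <= 8 && 8 <= p1$ci95_mean[2])
  rep2 <- age_structure(preds, meta, c("2015-2016", "2020-2021"),
                        n_boot = 500, seed = 3)
  expect_identical(rep$per_period[["2015-2016"]]$ci95_mean, p1$ci95_mean)
  expect_error(age_structure(preds, meta, "2030-2031"), "validation error")
})

test_that("duplicate individuals contribute their latest sample once", {
  preds <- setNames(c(5, 11, 7), c("a1", "a2", "b1"))
  meta <- sample_metadata(c("a1", "a2", "b1"),
                          individual_id = c("A", "A", "B"),
                          survey_period = "2020-2021",
                          collection_date = as.Date(c("2020-01-01",
                                                      "2021-06-01",
                                                      "2020-05-01")))
  rep <- age_structure(preds, meta, "2020-2021", n_boot = 200, seed = 1)
  expect_setequal(rep$per_period[["2020-2021"]]$ages, c(11, 7))
  rep_all <- age_structure(preds, meta, "2020-2021", per_sample = TRUE,
                           n_boot = 200, seed = 1)
  expect_length(rep_all$per_period[["2020-2021"]]$ages, 3)
})

test_that("a modest age shift is detected with high power at n = 40 per group", {
  set.seed(56)
  hits <- 0
  for (i in 1:100) {
    a <- rnorm(40, mean = 8.5, sd = 1.5)
    b <- rnorm(40, mean = 8.5 - 1.1, sd = 1.5)
    if (wilcoxon_rank_sum(a, b)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("serial consistency pairs consecutive samples per individual", {
  preds <- setNames(c(4.0, 6.5, 3.0, 2.0, 9.9),
                    c("i1_t1", "i1_t2", "i2_t1", "i2_t2", "solo"))
  meta <- sample_metadata(
    names(preds),
    individual_id = c("i1", "i1", "i2", "i2", "i3"),
    collection_date = as.Date(c("2015-01-01", "2018-01-01",
                                "2015-01-01", "2017-01-01", "2016-01-01")))
  sc <- serial_consistency(preds, meta)
  expect_equal(nrow(sc), 2)  # single-sample individuals excluded
  r1 <- sc[sc$individual_id == "i1", ]
  expect_equal(r1$predicted_interval, 2.5)
  expect_equal(r1$actual_interval, 3.0, tolerance = 1e-3)
  expect_true(r1$direction_correct)
  expect_false(sc$direction_correct[sc$individual_id == "i2"])
  # missing dates: individual skipped with warning
  meta$collection_date[1] <- NA
  expect_warning(sc2 <- serial_consistency(preds, meta), "missing collection")
  expect_equal(nrow(sc2), 1)
})
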