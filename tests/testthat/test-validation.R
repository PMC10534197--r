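test_that("metrics match hand arithmetic and the direct-formula oracle", {
  m0 <- compute_metrics(c(1, 5, 9), c(1, 5, 9))
  expect_equal(m0$mae, 0); expect_equal(m0$medae, 0)
  expect_equal(m0$pearson_r, 1); expect_equal(m0$reg_slope, 1)
  expect_equal(m0$reg_intercept, 0)

  m1 <- compute_metrics(c(0, 10, 5), c(1, 9, 5))
  expect_equal(m1$mae, 2 / 3); expect_equal(m1$medae, 1)

  # 6-point fixture against brute-force formulas to 1e-12
  true <- c(0.5, 3, 6.5, 9, 13, 18)
  pred <- c(1.2, 2.1, 7.3, 8.2, 14.9, 16.0)
  m2 <- compute_metrics(true, pred)
  expect_equal(m2$mae, sum(abs(pred - true)) / 6, tolerance = 1e-12)
  d <- sort(abs(pred - true))
  expect_equal(m2$medae, (d[3] + d[4]) / 2, tolerance = 1e-12)
  expect_equal(m2$pearson_r, oracle_pearson(true, pred), tolerance = 1e-12)
  expect_equal(m2$r_squared, oracle_pearson(true, pred)^2, tolerance = 1e-12)
  slope <- sum((true - mean(true)) * (pred - mean(pred))) /
    sum((true - mean(true))^2)
  expect_equal(m2$reg_slope, slope, tolerance = 1e-12)
  expect_equal(m2$reg_intercept, mean(pred) - slope * mean(true),
               tolerance = 1e-12)

  # negating residuals leaves the absolute-error metrics unchanged
  m3 <- compute_metrics(true, true - (pred - true))
  expect_equal(m3$mae, m2$mae); expect_equal(m3$medae, m2$medae)
  expect_error(compute_metrics(1:2, 1:2), "insufficient")
})

test_that("LOOCV on near-noise-free data is accurate but not optimistic", {
  sim <- generate_synthetic(synth_config(n_samples = 24, n_probes = 80,
                                         n_informative = 5, noise_sd = 0.005,
                                         seed = 12))
  spec <- elastic_net_spec(alpha = 0.9, seed = 12, n_folds = 5)
  cv <- loocv(sim$m, sim$meta, threshold = 10, spec = spec)
  expect_equal(cv$mode, "loocv")
  expect_gte(cv$metrics$pearson_r, 0.99)
  ins <- fit_clock(sim$m, sim$meta, threshold = 10, spec = spec)
  expect_gte(cv$metrics$mae, ins$report$metrics$mae - 1e-9)
})

test_that("held-out predictions do not depend on sample order", {
  sim <- generate_synthetic(synth_config(n_samples = 15, n_probes = 50,
                                         n_informative = 4, seed = 13))
  spec <- elastic_net_spec(alpha = 0.5, seed = 13, n_folds = 5)
  cv1 <- loocv(sim$m, sim$meta, threshold = 0, spec = spec)
  perm <- sample(ncol(sim$m$betas))
  m2 <- beta_matrix(sim$m$betas[, perm], sim$m$detection_p[, perm])
  cv2 <- loocv(m2, sim$meta[perm, ], threshold = 0, spec = spec)
  expect_identical(cv1$per_sample, cv2$per_sample)
})

test_that("LOOCV driver agrees with itself under refilter toggle shape", {
  sim <- generate_synthetic(synth_config(n_samples = 15, n_probes = 40,
                                         n_informative = 3,
                                         detection_fail_rate = 0.3,
                                         seed = 14))
  spec <- elastic_net_spec(alpha = 0.9, seed = 14, n_folds = 5)
  cv_refilter <- loocv(sim$m, sim$meta, threshold = 8, spec = spec)
  cv_global <- loocv(sim$m, sim$meta, threshold = 8, spec = spec,
                     refilter = FALSE)
  expect_equal(nrow(cv_refilter$per_sample), 15)
  expect_equal(nrow(cv_global$per_sample), 15)
  expect_error(loocv(sim$m, sim$meta[1:4, ], spec = spec), "missing from metadata")
})

test_that("confounder screening finds a separating probe and ignores noise", {
  set.seed(41)
  n <- 40; p <- 120
  b <- matrix(runif(n * p, 0.2, 0.8), p, n)
  labels <- setNames(rep_len(c(0L, 1L), n), sprintf("s%03d", 1:n))
  # probe 7 perfectly separates the classes
  b[7, ] <- ifelse(labels == 1, 0.9, 0.1)
  m <- make_bm(b)
  names(labels) <- sample_ids(m)
  sc <- confounder_screen(m, labels, label_name = "subspecies")
  expect_equal(sc$alpha_used, 0.5)
  expect_true(probe_ids(m)[7] %in% sc$diagnostic_probes)

  # permuted labels (independent of all probes): median screen size 0
  sizes <- vapply(1:5, function(s) {
    set.seed(100 + s)
    perm_labels <- setNames(sample(labels), names(labels))
    length(confounder_screen(m, perm_labels,
                             spec = elastic_net_spec(alpha = 0.5, seed = s,
                                                     lambda_rule = "1se"))$diagnostic_probes)
  }, 0L)
  expect_equal(median(sizes), 0)
  # loose type-I bound: non-empty screens in at most 40% of seeds
  expect_lte(mean(sizes > 0), 0.4)

  expect_error(confounder_screen(m, setNames(rep(1L, n), names(labels))),
               "both classes")
})

test_that("clock contamination check reports shared diagnostic probes", {
  clock <- methyl_clock(0, c(cg000a = 1, cg000b = 2))
  s_clean <- structure(list(label_name = "tissue",
                            diagnostic_probes = c("cg000x", "cg000y"),
                            alpha_used = 0.5), class = "diagnostic_screen")
  s_dirty <- structure(list(label_name = "subspecies",
                            diagnostic_probes = c("cg000b", "cg000z"),
                            alpha_used = 0.5), class = "diagnostic_screen")
  rep <- check_clock_confounding(clock, list(s_clean, s_dirty))
  expect_true(rep$pass[rep$label_name == "tissue"])
  expect_false(rep$pass[rep$label_name == "subspecies"])
  expect_identical(rep$shared_probes[rep$label_name == "subspecies"], "cg000b")
  # nested-loop oracle
  manual <- sum(vapply(names(clock$coefficients),
                       function(p) p %in% s_dirty$diagnostic_probes, TRUE))
  expect_equal(rep$n_shared[rep$label_name == "subspecies"], manual)
})
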