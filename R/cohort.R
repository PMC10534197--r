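#' Wilcoxon rank-sum (Mann-Whitney) test with exact enumeration
#'
#' Two-sided two-sample rank test on midranks. The statistic is the
#' Mann-Whitney U for the first sample: the rank sum of `x` in the pooled
#' ranking minus `n_x(n_x + 1)/2`.
#'
#' Mode `"exact"` computes the p-value from the permutation null: by full
#' enumeration of all group assignments when feasible (this handles ties
#' via midranks), or from the exact no-tie null distribution otherwise.
#' Mode `"normal_approx"` uses the normal approximation with tie and
#' continuity corrections. `"auto"` (default) picks exact for small
#' instances (`n_x * n_y <= 400` or enumerable) and the approximation
#' otherwise.
#'
#' @param x,y numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return list with `W` (the U statistic) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("precondition error: both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  enumerable <- choose(n, nx) <= 1e5
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = enumerable || (!ties && nx * ny <= 400))
  if (use_exact) {
    if (enumerable) {
      p <- ranksum_enum_p(rk, nx, W)
    } else if (!ties) {
      p <- ranksum_dwilcox_p(W, nx, ny)
    } else {
      stop("exact mode infeasible: ties present and instance too large to enumerate")
    }
  } else {
    p <- ranksum_normal_p(W, rk, nx, ny)
  }
  list(W = W, p = p)
}

# exact permutation p: enumerate all size-nx subsets of the pooled midranks
ranksum_enum_p <- function(rk, nx, W) {
  offset <- nx * (nx + 1) / 2
  stats <- utils::combn(rk, nx, FUN = sum) - offset
  mu <- nx * (length(rk) - nx) / 2
  eps <- 1e-9
  mean(abs(stats - mu) >= abs(W - mu) - eps)
}

ranksum_dwilcox_p <- function(W, nx, ny) {
  # standard two-sided doubling on the symmetric exact null
  p <- if (W > nx * ny / 2)
    2 * stats::pwilcox(W - 1, nx, ny, lower.tail = FALSE)
  else
    2 * stats::pwilcox(W, nx, ny)
  min(1, p)
}

ranksum_normal_p <- function(W, rk, nx, ny) {
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(rk)
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test with exact enumeration
#'
#' Two-sided paired rank test. Zero differences are dropped before
#' ranking; `V` is the sum of the ranks (midranks under ties) of the
#' positive differences. Exact p-values enumerate all 2^n sign patterns
#' when feasible (handling ties), or use the exact no-tie null otherwise;
#' the normal approximation applies tie and continuity corrections. When
#' every difference is zero the result is degenerate: `V = 0`, `p = 1`.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return list with `V` and `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop("precondition error: paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(V = 0, p = 1))
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  enumerable <- n <= 16
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = enumerable || (!ties && n <= 20))
  if (use_exact) {
    if (enumerable) {
      p <- signrank_enum_p(rk, V)
    } else if (!ties) {
      p <- signrank_dsignrank_p(V, n)
    } else {
      stop("exact mode infeasible: ties present and instance too large to enumerate")
    }
  } else {
    p <- signrank_normal_p(V, rk, n)
  }
  list(V = V, p = p)
}

# exact p over all 2^n sign assignments of the midranks
signrank_enum_p <- function(rk, V) {
  n <- length(rk)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- drop(signs %*% rk)
  mu <- sum(rk) / 2
  eps <- 1e-9
  mean(abs(stats - mu) >= abs(V - mu) - eps)
}

signrank_dsignrank_p <- function(V, n) {
  mu <- n * (n + 1) / 4
  p <- if (V > mu) 2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
       else 2 * stats::psignrank(V, n)
  min(1, p)
}

signrank_normal_p <- function(V, rk, n) {
  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(1)
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Characterize population age structure across survey periods
#'
#' Builds per-period age summaries from clock predictions: age lists (one
#' record per individual, the latest-dated sample winning for duplicates,
#' unless `per_sample = TRUE`), mean, median, a seeded bootstrap percentile
#' 95% CI for the mean, pairwise rank-sum comparisons between periods, and
#' histogram counts by sex.
#'
#' @param predictions named numeric vector of predicted ages keyed by
#'   sample id.
#' @param meta a `sample_metadata` data frame with `survey_period` (and
#'   `individual_id`, `sex`, `collection_date`) for the predicted samples.
#' @param periods character vector of survey periods to analyze; each must
#'   have at least one predicted sample.
#' @param bin_width histogram bin width in years (default 1).
#' @param per_sample keep every sample rather than one per individual.
#' @param n_boot bootstrap resamples for the CI of the mean (default 10000).
#' @param seed bootstrap seed.
#' @return a list of class `age_structure_report`: `per_period` (named list
#'   with `ages`, `mean`, `median`, `ci95_mean`, `histogram`), `comparisons`
#'   (data.frame with `period_a`, `period_b`, `statistic_W`, `p_value`),
#'   `bin_width`.
#' @export
age_structure <- function(predictions, meta, periods, bin_width = 1,
                          per_sample = FALSE, n_boot = 10000, seed = 1L) {
  if (is.null(names(predictions)))
    stop("'predictions' must be named by sample id")
  idx <- match(names(predictions), meta$sample_id)
  if (anyNA(idx))
    stop("validation error: predicted sample(s) missing from metadata: ",
         paste(names(predictions)[is.na(idx)], collapse = ", "))
  df <- data.frame(sample_id = names(predictions),
                   age = as.numeric(predictions),
                   individual_id = meta$individual_id[idx],
                   sex = meta$sex[idx],
                   period = meta$survey_period[idx],
                   collection_date = meta$collection_date[idx],
                   stringsAsFactors = FALSE)
  per_period <- list()
  set.seed(seed)
  for (p in periods) {
    sub <- df[!is.na(df$period) & df$period == p, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("validation error: no predicted samples in period '", p, "'")
    if (!per_sample) {
      ord <- order(sub$individual_id,
                   as.numeric(sub$collection_date), sub$sample_id,
                   na.last = FALSE)
      sub <- sub[ord, , drop = FALSE]
      sub <- sub[!duplicated(sub$individual_id, fromLast = TRUE), , drop = FALSE]
    }
    ages <- sub$age
    boot_means <- vapply(seq_len(n_boot), function(i)
      mean(sample(ages, replace = TRUE)), 0)
    edges <- seq(floor(min(ages) / bin_width) * bin_width,
                 ceiling(max(ages) / bin_width) * bin_width + bin_width,
                 by = bin_width)
    hist_by_sex <- table(
      sex = factor(sub$sex, levels = c("F", "M", "unknown")),
      bin = cut(ages, breaks = edges, right = FALSE))
    per_period[[p]] <- list(
      ages = ages,
      mean = mean(ages),
      median = stats::median(ages),
      ci95_mean = stats::quantile(boot_means, c(0.025, 0.975), names = FALSE),
      histogram = hist_by_sex)
  }
  comparisons <- NULL
  if (length(periods) >= 2) {
    pairs <- utils::combn(periods, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      w <- wilcoxon_rank_sum(per_period[[a]]$ages, per_period[[b]]$ages)
      data.frame(period_a = a, period_b = b, statistic_W = w$W,
                 p_value = w$p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_period = per_period, comparisons = comparisons,
                 bin_width = bin_width),
            class = "age_structure_report")
}

#' @export
print.age_structure_report <- function(x, ...) {
  for (p in names(x$per_period)) {
    pp <- x$per_period[[p]]
    cat(sprintf("%s: n=%d, mean=%.2f y (95%% CI %.2f-%.2f), median=%.2f y\n",
                p, length(pp$ages), pp$mean, pp$ci95_mean[1], pp$ci95_mean[2],
                pp$median))
  }
  if (!is.null(x$comparisons)) {
    cat("pairwise rank-sum comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Consistency of predicted ages across serial samples
#'
#' For every individual sampled more than once, compares the predicted age
#' difference between consecutive samples with the elapsed calendar time:
#' a well-behaved clock predicts later samples older. Individuals with
#' missing collection dates are skipped with a warning.
#'
#' @param predictions named numeric vector of predicted ages by sample id.
#' @param meta a `sample_metadata` data frame with `individual_id` and
#'   `collection_date`.
#' @return a data.frame with one row per consecutive sample pair:
#'   `individual_id`, `sample_a`, `sample_b`, `predicted_interval`,
#'   `actual_interval` (years), `direction_correct`.
#' @export
serial_consistency <- function(predictions, meta) {
  idx <- match(names(predictions), meta$sample_id)
  if (anyNA(idx))
    stop("predicted sample(s) missing from metadata: ",
         paste(names(predictions)[is.na(idx)], collapse = ", "))
  df <- data.frame(sample_id = names(predictions),
                   age = as.numeric(predictions),
                   individual_id = meta$individual_id[idx],
                   collection_date = meta$collection_date[idx],
                   stringsAsFactors = FALSE)
  rows <- list()
  skipped <- character(0)
  for (ind in unique(df$individual_id)) {
    sub <- df[df$individual_id == ind, , drop = FALSE]
    if (nrow(sub) < 2) next
    if (anyNA(sub$collection_date)) {
      skipped <- c(skipped, ind)
      next
    }
    sub <- sub[order(sub$collection_date, sub$sample_id), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1)) {
      pred_int <- sub$age[i + 1] - sub$age[i]
      act_int <- as.numeric(sub$collection_date[i + 1] -
                              sub$collection_date[i]) / 365.25
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = ind,
        sample_a = sub$sample_id[i], sample_b = sub$sample_id[i + 1],
        predicted_interval = pred_int, actual_interval = act_int,
        direction_correct = sign(pred_int) == sign(act_int),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0)
    warning("skipped individuals with missing collection dates: ",
            paste(skipped, collapse = ", "))
  if (length(rows) == 0)
    return(data.frame(individual_id = character(0), sample_a = character(0),
                      sample_b = character(0),
                      predicted_interval = numeric(0),
                      actual_interval = numeric(0),
                      direction_correct = logical(0)))
  do.call(rbind, rows)
}
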