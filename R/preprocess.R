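#' Flag technical outlier samples by interarray correlation
#'
#' Computes all pairwise Pearson correlations between sample beta vectors
#' (complete-case probes only), clusters samples by average-linkage
#' agglomeration on distance 1 - r for manual review, and flags samples
#' whose mean interarray correlation falls more than `z_cut` standard
#' deviations below the across-sample mean. The z-score rule is a
#' reproducible stand-in for the visual dendrogram call typically used on
#' real arrays; the dendrogram is kept in the report.
#'
#' @param m a [beta_matrix()] with at least 3 samples.
#' @param z_cut flagging threshold in standard deviations (default 2).
#' @return a list of class `outlier_report`: `flagged_samples`,
#'   `mean_interarray_r` (named vector), `hclust` (the dendrogram),
#'   `method_params`.
#' @export
detect_outlier_samples <- function(m, z_cut = 2) {
  b <- m$betas[stats::complete.cases(m$betas), , drop = FALSE]
  if (ncol(b) < 3)
    stop("insufficient data: need at least 3 samples")
  if (nrow(b) < 2)
    stop("insufficient data: need at least 2 complete-case probes")
  r <- stats::cor(b)
  diag(r) <- NA
  mean_r <- rowMeans(r, na.rm = TRUE)
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(b)), method = "average")
  s <- stats::sd(mean_r)
  flagged <- if (is.na(s) || s == 0) character(0)
             else names(mean_r)[mean_r < mean(mean_r) - z_cut * s]
  structure(list(flagged_samples = sort(flagged),
                 mean_interarray_r = mean_r,
                 hclust = hc,
                 method_params = list(linkage = "average",
                                      cut_rule = sprintf("mean r < mean - %g sd", z_cut))),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d/%d samples flagged (%s)\n",
              length(x$flagged_samples), length(x$mean_interarray_r),
              x$method_params$cut_rule))
  if (length(x$flagged_samples) > 0)
    cat("  flagged:", paste(x$flagged_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Filter CpG probes by detection p-value support
#'
#' Retains probes whose detection p-value is significant (strictly below
#' `significance_level`) in at least `threshold_individuals` samples. This
#' is the pre-training quality filter: probes that fail detection in most
#' individuals carry background signal rather than methylation.
#'
#' @param m a [beta_matrix()] carrying a detection p-value matrix.
#' @param threshold_individuals minimum number of samples with significant
#'   detection, in `1..n_samples`.
#' @param significance_level detection significance cut (default 0.05).
#' @return a list of class `filter_result`: `retained_probes`,
#'   `significant_counts` (named integer vector over all probes),
#'   `threshold_individuals`, `significance_level`.
#' @export
filter_probes_by_detection <- function(m, threshold_individuals,
                                       significance_level = 0.05) {
  if (is.null(m$detection_p))
    stop("precondition error: beta matrix has no detection p-value matrix")
  n <- ncol(m$betas)
  if (threshold_individuals < 1 || threshold_individuals > n)
    stop(sprintf("precondition error: threshold_individuals must be in [1, %d]", n))
  counts <- rowSums(m$detection_p < significance_level, na.rm = TRUE)
  retained <- names(counts)[counts >= threshold_individuals]
  structure(list(retained_probes = retained,
                 significant_counts = counts,
                 threshold_individuals = as.integer(threshold_individuals),
                 significance_level = significance_level),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d/%d probes retained (detection p < %g in >= %d samples)\n",
              length(x$retained_probes), length(x$significant_counts),
              x$significance_level, x$threshold_individuals))
  invisible(x)
}

#' Per-CpG Pearson correlation with age
#'
#' For each probe, computes the Pearson correlation between its beta values
#' and sample age over pairwise-complete observations, with a two-sided
#' p-value from the t-distribution on n - 2 degrees of freedom. Probes with
#' fewer than 3 complete pairs or zero variance are excluded (r undefined,
#' never reported as 0).
#'
#' @param m a [beta_matrix()]
#' @param meta a `sample_metadata` data frame covering the samples of `m`;
#'   samples with unknown age are dropped.
#' @return a data.frame of class `correlation_table` with columns
#'   `probe_id`, `r`, `p_value`, `n`.
#' @export
probe_age_correlations <- function(m, meta) {
  meta <- align_samples(m, meta)
  keep <- !is.na(meta$age_years)
  if (sum(keep) < 3)
    stop("insufficient data: need at least 3 samples with known age")
  age <- meta$age_years[keep]
  b <- m$betas[, keep, drop = FALSE]
  nobs <- rowSums(!is.na(b))
  r <- suppressWarnings(as.numeric(stats::cor(t(b), age,
                                              use = "pairwise.complete.obs")))
  ok <- !is.na(r) & nobs >= 3
  r <- r[ok]
  n <- nobs[ok]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(probe_id = rownames(b)[ok], r = r, p_value = p,
                    n = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Bin per-CpG age correlations by absolute value
#'
#' Summarizes a correlation table into ten |r| bins \[0,.1), \[.1,.2), ...,
#' \[.9,1.0\] (half-open, final bin closed at 1), reporting the probe count
#' and the percent of probes with a positive correlation in each bin, plus
#' a total row. The percent positive is `NA` for empty bins.
#'
#' @param tab a `correlation_table` from [probe_age_correlations()], or any
#'   data frame with an `r` column.
#' @return a data.frame with columns `bin`, `n_cpgs`, `pct_positive`; the
#'   last row is the total.
#' @export
bin_correlations <- function(tab) {
  r <- tab$r
  edges <- seq(0, 1, by = 0.1)
  idx <- findInterval(abs(r), edges, rightmost.closed = TRUE)
  labels <- sprintf("%.1f-%.1f", edges[-11], edges[-1])
  counts <- tabulate(idx, nbins = 10)
  pos <- vapply(1:10, function(k) sum(r[idx == k] > 0), 0L)
  pct <- ifelse(counts > 0, 100 * pos / counts, NA_real_)
  out <- data.frame(bin = c(labels, "total"),
                    n_cpgs = c(counts, length(r)),
                    pct_positive = c(pct,
                                     if (length(r) > 0) 100 * sum(r > 0) / length(r)
                                     else NA_real_),
                    stringsAsFactors = FALSE)
  out
}

#' Write a binned correlation summary as delimited text
#' @param binned output of [bin_correlations()]
#' @param path output path (TSV/CSV by extension)
#' @return `path`, invisibly
#' @export
write_correlation_bins <- function(binned, path) {
  utils::write.table(binned, path, sep = delim_for_path(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
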