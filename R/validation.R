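#' Clock accuracy metrics
#'
#' Computes the standard clock performance summary for paired true and
#' predicted ages: mean and median absolute error (years), Pearson
#' correlation and its square, and the simple linear regression of
#' predicted age on true age (slope, intercept, and the slope's two-sided
#' p-value).
#'
#' @param true_ages,predicted_ages equal-length numeric vectors, n >= 3.
#' @return a list of class `clock_metrics` with elements `mae`, `medae`,
#'   `pearson_r`, `r_squared`, `reg_slope`, `reg_intercept`, `reg_p`, `n`.
#' @export
compute_metrics <- function(true_ages, predicted_ages) {
  if (length(true_ages) != length(predicted_ages))
    stop("true and predicted ages must have equal length")
  ok <- !is.na(true_ages) & !is.na(predicted_ages)
  true_ages <- true_ages[ok]
  predicted_ages <- predicted_ages[ok]
  if (length(true_ages) < 3)
    stop("insufficient data: need at least 3 paired ages")
  err <- predicted_ages - true_ages
  r <- stats::cor(true_ages, predicted_ages)
  fit <- stats::lm(predicted_ages ~ true_ages)
  # summary.lm warns on an exactly perfect fit; noise-free predictions are
  # a legitimate input here
  sm <- suppressWarnings(summary(fit))
  structure(list(mae = mean(abs(err)),
                 medae = stats::median(abs(err)),
                 pearson_r = r,
                 r_squared = r^2,
                 reg_slope = unname(stats::coef(fit)[2]),
                 reg_intercept = unname(stats::coef(fit)[1]),
                 reg_p = unname(sm$coefficients[2, 4]),
                 n = length(true_ages)),
            class = "clock_metrics")
}

#' @export
print.clock_metrics <- function(x, ...) {
  cat(sprintf("clock_metrics (n=%d): mae=%.3f y, medae=%.3f y, r=%.3f, r2=%.3f\n",
              x$n, x$mae, x$medae, x$pearson_r, x$r_squared))
  cat(sprintf("  regression predicted~true: slope=%.3f, intercept=%.3f y, p=%.3g\n",
              x$reg_slope, x$reg_intercept, x$reg_p))
  invisible(x)
}

#' Fit a clock and report in-sample performance
#'
#' Convenience wrapper: assembles the training design at one detection
#' threshold, fits a cross-validated elastic-net clock, and scores it on
#' its own training samples.
#'
#' @inheritParams alpha_grid_search
#' @param threshold detection-filter threshold (0 = no filtering).
#' @param spec an [elastic_net_spec()] (its `alpha` is used).
#' @return a list: `model` (a [methyl_clock()]) and `report` (a
#'   `validation_report` with `mode = "in_sample"`).
#' @export
fit_clock <- function(m, meta, threshold = 0, spec = elastic_net_spec(),
                      significance_level = 0.05) {
  tr <- prepare_training(m, meta, threshold, significance_level)
  model <- fit_elastic_net(tr$x, tr$y, spec)
  model$training_meta$cpg_filter_threshold <- threshold
  pred <- model$intercept +
    drop(tr$x[, names(model$coefficients), drop = FALSE] %*% model$coefficients)
  per_sample <- data.frame(sample_id = tr$sample_id, true_age = tr$y,
                           predicted_age = pred, stringsAsFactors = FALSE)
  list(model = model,
       report = validation_report(per_sample, mode = "in_sample"))
}

validation_report <- function(per_sample, mode) {
  rownames(per_sample) <- NULL
  structure(list(per_sample = per_sample,
                 metrics = compute_metrics(per_sample$true_age,
                                           per_sample$predicted_age),
                 mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report (%s, n=%d)\n", x$mode, nrow(x$per_sample)))
  print(x$metrics)
  invisible(x)
}

#' Leave-one-out cross-validation of a clock recipe
#'
#' For each aged sample in turn, re-applies the detection filter to the
#' remaining samples (unless `refilter = FALSE`, which reproduces the
#' optimistic variant that filters once on all samples), refits the
#' cross-validated elastic-net clock on them, and predicts the held-out
#' sample. Metrics are computed over the held-out predictions.
#'
#' Folds are processed in sample-id order with the fold seed reset from
#' `spec$seed`, so held-out predictions do not depend on the order of
#' samples in the input.
#'
#' @inheritParams fit_clock
#' @param refilter re-apply the detection filter within each fold
#'   (default `TRUE`; avoids filter leakage from the held-out sample).
#' @return a `validation_report` with `mode = "loocv"`.
#' @export
loocv <- function(m, meta, threshold = 0, spec = elastic_net_spec(),
                  refilter = TRUE, significance_level = 0.05) {
  meta <- align_samples(m, meta)
  aged <- meta$sample_id[!is.na(meta$age_years)]
  if (length(aged) < spec$n_folds + 1)
    stop("precondition error: need n >= n_folds + 1 aged samples for LOOCV")
  aged <- sort(aged)
  global_probes <- if (!refilter && threshold > 0) {
    mt <- subset(m, samples = match(aged, sample_ids(m)))
    filter_probes_by_detection(mt, threshold,
                               significance_level)$retained_probes
  }
  preds <- vapply(aged, function(sid) {
    train_ids <- setdiff(aged, sid)
    mt <- subset(m, samples = match(train_ids, sample_ids(m)))
    if (refilter) {
      tr <- tryCatch(prepare_training(mt, meta, threshold, significance_level),
                     error = function(e)
                       stop("fold holding out '", sid, "': ",
                            conditionMessage(e), call. = FALSE))
    } else {
      probes <- if (is.null(global_probes)) probe_ids(mt) else global_probes
      mt2 <- subset(mt, probes = probes)
      tr <- prepare_training(mt2, meta, 0)
    }
    model <- fit_elastic_net(tr$x, tr$y, spec)
    pr <- names(model$coefficients)
    b <- m$betas[pr, sid]
    if (anyNA(b)) NA_real_
    else model$intercept + sum(model$coefficients * b)
  }, 0)
  per_sample <- data.frame(sample_id = aged,
                           true_age = meta$age_years[match(aged, meta$sample_id)],
                           predicted_age = unname(preds),
                           stringsAsFactors = FALSE)
  validation_report(per_sample, mode = "loocv")
}

#' Screen CpGs diagnostic of a binary confounder
#'
#' Fits a penalized logistic regression (binomial elastic net at
#' `alpha = 0.5`, penalty chosen by cross-validated binomial deviance) of a
#' binary sample label — e.g. subspecies or tissue source — on all probe
#' betas, and returns the probes with nonzero coefficients. CpGs selected
#' here are diagnostic of the confounder and must not appear in an age
#' clock trained on the same data.
#'
#' The penalty defaults to the one-standard-error rule rather than the
#' deviance minimum: a screen should have high specificity, reporting a
#' CpG as diagnostic only on strong evidence, so that an empty screen on
#' label-permuted data is the typical outcome.
#'
#' @param m a [beta_matrix()].
#' @param labels named 0/1 (or logical) vector keyed by sample id, covering
#'   the samples of `m`; `1` marks the second group by convention.
#' @param spec an [elastic_net_spec()]; defaults to `alpha = 0.5` with
#'   `lambda_rule = "1se"`.
#' @param label_name descriptive name recorded in the result.
#' @return a list of class `diagnostic_screen`: `label_name`,
#'   `diagnostic_probes`, `alpha_used`, `coefficients`.
#' @export
confounder_screen <- function(m, labels,
                              spec = elastic_net_spec(alpha = 0.5,
                                                      lambda_rule = "1se"),
                              label_name = "label") {
  if (is.null(names(labels)))
    stop("'labels' must be named by sample id")
  missing_l <- setdiff(sample_ids(m), names(labels))
  if (length(missing_l) > 0)
    stop("labels missing for sample(s): ", paste(missing_l, collapse = ", "))
  y <- as.integer(labels[sample_ids(m)])
  if (!all(y %in% c(0L, 1L))) stop("'labels' must be 0/1 or logical")
  if (length(unique(y)) < 2)
    stop("precondition error: both classes must be present")
  b <- m$betas
  b <- b[rowSums(is.na(b)) == 0, , drop = FALSE]
  x <- t(b)
  set.seed(spec$seed)
  foldid <- sample(rep(seq_len(spec$n_folds), length.out = length(y)))
  cv <- quiet_cv(glmnet::cv.glmnet(x, y, family = "binomial",
                                   alpha = spec$alpha,
                                   foldid = foldid, nlambda = spec$n_penalties,
                                   lambda.min.ratio = spec$penalty_min_ratio,
                                   standardize = spec$standardize,
                                   type.measure = "deviance"))
  s <- if (spec$lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  co <- drop(as.matrix(stats::coef(cv, s = s)))[-1]
  co <- co[co != 0]
  structure(list(label_name = label_name,
                 diagnostic_probes = names(co),
                 alpha_used = spec$alpha,
                 coefficients = co),
            class = "diagnostic_screen")
}

#' @export
print.diagnostic_screen <- function(x, ...) {
  cat(sprintf("diagnostic_screen '%s' (alpha=%g): %d diagnostic CpGs\n",
              x$label_name, x$alpha_used, length(x$diagnostic_probes)))
  invisible(x)
}

#' Check a clock for confounder contamination
#'
#' Intersects the clock's CpG set with each diagnostic screen; the clock
#' passes a screen when the intersection is empty.
#'
#' @param model a [methyl_clock()].
#' @param screens a `diagnostic_screen` or list of them.
#' @return a data.frame of class `confounding_report` with columns
#'   `label_name`, `n_shared`, `shared_probes` (comma-separated), `pass`.
#' @export
check_clock_confounding <- function(model, screens) {
  if (inherits(screens, "diagnostic_screen")) screens <- list(screens)
  rows <- lapply(screens, function(s) {
    shared <- intersect(names(model$coefficients), s$diagnostic_probes)
    data.frame(label_name = s$label_name, n_shared = length(shared),
               shared_probes = paste(shared, collapse = ","),
               pass = length(shared) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confounding_report", "data.frame")
  out
}
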