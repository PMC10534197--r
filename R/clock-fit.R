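#' Elastic-net training specification
#'
#' Bundles the hyperparameters of a penalized clock fit. The mixing
#' parameter `alpha` interpolates between ridge (`alpha = 0`) and lasso
#' (`alpha = 1`); the penalty strength lambda is selected by internal
#' K-fold cross-validation over a geometric path of `n_penalties` values
#' running from the smallest all-zero-coefficient lambda down by a factor
#' `penalty_min_ratio`.
#'
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param n_folds number of internal cross-validation folds (default 10).
#' @param n_penalties number of lambda values on the path (default 100).
#' @param penalty_min_ratio ratio of smallest to largest path lambda
#'   (default 1e-4).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda_rule `"min"` selects the lambda minimizing cross-validated
#'   mean squared error; `"1se"` the largest lambda within one standard
#'   error of that minimum.
#' @param standardize center and scale predictors to unit variance inside
#'   the optimizer (coefficients are always reported back on the raw beta
#'   scale); the intercept is never penalized.
#' @return a list of class `elastic_net_spec`.
#' @export
elastic_net_spec <- function(alpha = 0.9, n_folds = 10, n_penalties = 100,
                             penalty_min_ratio = 1e-4, seed = 1L,
                             lambda_rule = c("min", "1se"),
                             standardize = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("precondition error: alpha must be in [0, 1]")
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 n_penalties = as.integer(n_penalties),
                 penalty_min_ratio = penalty_min_ratio,
                 seed = as.integer(seed),
                 lambda_rule = match.arg(lambda_rule),
                 standardize = isTRUE(standardize)),
            class = "elastic_net_spec")
}

#' Elastic-net objective function
#'
#' The penalized least-squares objective minimized by the clock fit:
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - x_i b)^2 +
#'       \lambda\left[\alpha \|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2\right]}
#' Exposed so fitted solutions can be checked against direct minimization.
#'
#' @param x predictor matrix (samples x probes)
#' @param y response vector
#' @param intercept,beta candidate intercept and coefficient vector
#' @param lambda,alpha penalty strength and mixing parameter
#' @return the objective value (scalar)
#' @export
enet_objective <- function(x, y, intercept, beta, lambda, alpha) {
  n <- length(y)
  resid <- y - intercept - drop(x %*% beta)
  sum(resid^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Fit an elastic-net age clock
#'
#' Fits a penalized linear regression of age on methylation betas and
#' returns the sparse scoring function as a [methyl_clock()]. When
#' `lambda` is `NULL` (the default), the penalty is selected by seeded
#' internal K-fold cross-validation minimizing mean squared error; a fixed
#' `lambda` skips cross-validation and solves at that penalty exactly.
#'
#' @param x numeric predictor matrix, samples in rows and probes in
#'   columns, no missing values.
#' @param y numeric age vector (years), one per row of `x`.
#' @param spec an [elastic_net_spec()].
#' @param lambda optional fixed penalty strength.
#' @return a [methyl_clock()] whose `training_meta` records `alpha`, the
#'   selected `penalty`, `n_training`, and `seed`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 20, 10,
#'             dimnames = list(NULL, sprintf("cg%08d", 1:10)))
#' y <- 2 + 30 * x[, 1] - 20 * x[, 2] + rnorm(20, sd = 0.1)
#' fit <- fit_elastic_net(x, y, elastic_net_spec(alpha = 0.9, seed = 7))
#' coef(fit)
#' @export
fit_elastic_net <- function(x, y, spec = elastic_net_spec(), lambda = NULL) {
  if (!inherits(spec, "elastic_net_spec")) stop("'spec' must be an elastic_net_spec")
  x <- as.matrix(x)
  if (anyNA(x)) stop("precondition error: missing predictor values")
  if (anyNA(y) || any(!is.finite(y))) stop("precondition error: y must be finite")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (stats::var(y) == 0) stop("degenerate fit: y is constant")
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  n <- nrow(x)

  if (is.null(lambda)) {
    if (n < spec$n_folds)
      stop("precondition error: need n_samples >= n_folds")
    set.seed(spec$seed)
    foldid <- sample(rep(seq_len(spec$n_folds), length.out = n))
    cv <- quiet_cv(glmnet::cv.glmnet(x, y, alpha = spec$alpha, foldid = foldid,
                                     nlambda = spec$n_penalties,
                                     lambda.min.ratio = spec$penalty_min_ratio,
                                     standardize = spec$standardize,
                                     type.measure = "mse", family = "gaussian"))
    s <- if (spec$lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    co <- stats::coef(cv, s = s)
    penalty <- s
  } else {
    # Solve at the requested penalty under the stated objective
    #   (1/2n)RSS + lambda * (alpha*L1 + (1-alpha)/2 * L2).
    # The optimizer's internal response scaling divides its quadratic
    # penalty by the population sd of y, so convert (lambda, alpha) into
    # its parameter space first, then warm-start down a path terminating
    # exactly at the converted penalty.
    s_y <- stats::sd(y) * sqrt((n - 1) / n)
    a_g <- spec$alpha / (spec$alpha + s_y * (1 - spec$alpha))
    l_g <- lambda * (spec$alpha + s_y * (1 - spec$alpha))
    xc <- if (spec$standardize) scale(x) * sqrt(n / (n - 1))
          else scale(x, scale = FALSE)
    lmax <- max(abs(crossprod(xc, y - mean(y)))) / (n * max(a_g, 1e-3))
    top <- max(lmax, l_g * 1.001)
    path <- exp(seq(log(top), log(l_g), length.out = 30))
    fit <- glmnet::glmnet(x, y, alpha = a_g, lambda = path,
                          standardize = spec$standardize,
                          thresh = 1e-16, maxit = 1e7, family = "gaussian")
    # the path terminates exactly at l_g, so no refit is needed
    co <- stats::coef(fit, s = l_g)
    penalty <- lambda
  }
  co <- drop(as.matrix(co))
  beta <- co[-1]
  methyl_clock(co[["(Intercept)"]], beta[beta != 0],
               training_meta = list(alpha = spec$alpha, penalty = penalty,
                                    n_training = n, seed = spec$seed))
}

# Run a cv.glmnet call while muffling its purely informational warning
# about small folds (emitted for leave-one-out-sized training sets).
quiet_cv <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("grouped=FALSE enforced", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Assemble the training design for a given detection-filter threshold:
# keep aged samples, apply the detection filter (threshold 0 = none), and
# drop probes with any missing beta in the training set.
prepare_training <- function(m, meta, threshold = 0,
                             significance_level = 0.05) {
  meta <- align_samples(m, meta)
  keep <- !is.na(meta$age_years)
  if (sum(keep) < 3) stop("insufficient data: need >= 3 aged samples")
  mt <- subset(m, samples = which(keep))
  probes <- if (threshold > 0)
    filter_probes_by_detection(mt, threshold, significance_level)$retained_probes
  else probe_ids(mt)
  b <- mt$betas[probes, , drop = FALSE]
  complete <- rowSums(is.na(b)) == 0
  b <- b[complete, , drop = FALSE]
  if (nrow(b) == 0) stop("no complete probes left after filtering")
  list(x = t(b), y = meta$age_years[keep],
       sample_id = meta$sample_id[keep], probes = rownames(b))
}

#' Evaluate candidate clocks over an alpha and filter-threshold grid
#'
#' For every combination of detection-filter threshold and elastic-net
#' alpha, filters probes, fits a cross-validated clock on the aged samples,
#' and scores it in-sample. Fold assignments are generated once from the
#' seed and shared across all alphas, so candidates differ only in their
#' hyperparameters.
#'
#' @param m a [beta_matrix()] (detection p-values required when any
#'   threshold is positive).
#' @param meta a `sample_metadata` data frame.
#' @param thresholds integer detection-filter thresholds; `0` means no
#'   filtering (default `c(0, 10, 20, 30)`).
#' @param alphas elastic-net mixing values (default `seq(0.1, 0.9, 0.1)`).
#' @param spec an [elastic_net_spec()] supplying the remaining settings
#'   (its `alpha` is ignored).
#' @param significance_level detection significance cut (default 0.05).
#' @return a list of class `candidate_grid`: `grid` (a data.frame with one
#'   row per candidate: `alpha`, `cpg_filter_threshold`, `n_coefficients`,
#'   and in-sample `mae`, `medae`, `pearson_r`, `r_squared`) and `models`
#'   (the corresponding [methyl_clock()]s).
#' @export
alpha_grid_search <- function(m, meta, thresholds = c(0, 10, 20, 30),
                              alphas = seq(0.1, 0.9, by = 0.1),
                              spec = elastic_net_spec(),
                              significance_level = 0.05) {
  rows <- list()
  models <- list()
  k <- 0
  for (th in thresholds) {
    tr <- prepare_training(m, meta, th, significance_level)
    for (a in alphas) {
      k <- k + 1
      sp <- spec
      sp$alpha <- a
      model <- fit_elastic_net(tr$x, tr$y, sp)
      model$training_meta$cpg_filter_threshold <- th
      pred <- model$intercept +
        drop(tr$x[, names(model$coefficients), drop = FALSE] %*%
               model$coefficients)
      met <- compute_metrics(tr$y, pred)
      rows[[k]] <- data.frame(alpha = a, cpg_filter_threshold = th,
                              n_coefficients = length(model$coefficients),
                              mae = met$mae, medae = met$medae,
                              pearson_r = met$pearson_r,
                              r_squared = met$r_squared)
      models[[k]] <- model
    }
  }
  structure(list(grid = do.call(rbind, rows), models = models),
            class = "candidate_grid")
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat(sprintf("candidate_grid: %d candidate clocks\n", nrow(x$grid)))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Select the most parsimonious near-optimal candidate clock
#'
#' Among candidates whose median absolute error is within
#' `medae_tolerance` years of the grid minimum, returns the model with the
#' fewest CpG terms; remaining ties are broken by larger alpha, then larger
#' filter threshold. This encodes the selection preference of minimizing
#' age error while avoiding over-parametrized clocks.
#'
#' @param grid a `candidate_grid` from [alpha_grid_search()].
#' @param medae_tolerance slack in years around the minimum median
#'   absolute error (default 0.5).
#' @return the selected [methyl_clock()], with the winning grid row
#'   attached as attribute `"selection"`.
#' @export
select_model <- function(grid, medae_tolerance = 0.5) {
  g <- grid$grid
  if (is.null(g) || nrow(g) == 0) stop("precondition error: empty grid")
  near <- which(g$medae <= min(g$medae) + medae_tolerance)
  ord <- near[order(g$n_coefficients[near], -g$alpha[near],
                    -g$cpg_filter_threshold[near])]
  best <- ord[1]
  model <- grid$models[[best]]
  attr(model, "selection") <- g[best, , drop = FALSE]
  model
}
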