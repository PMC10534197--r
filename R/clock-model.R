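#' Epigenetic clock model objects
#'
#' A `methyl_clock` is a sparse linear scoring function mapping methylation
#' beta values to chronological age in years:
#' \deqn{\widehat{age} = b_0 + \sum_j b_j \beta_j}
#' with an intercept `b_0` (years) and nonzero coefficients `b_j` (years per
#' unit beta) on a small set of CpG probes. Negative predictions are
#' meaningful (fetal/neonatal samples) and are never truncated.
#'
#' @param intercept numeric scalar, years.
#' @param coefficients named numeric vector of nonzero probe coefficients;
#'   names are CpG probe ids (canonicalized to lower case).
#' @param training_meta list of training provenance: any of `alpha`,
#'   `penalty` (the selected lambda), `cpg_filter_threshold`,
#'   `training_set_label`, `n_training`, `seed`.
#' @return an object of class `methyl_clock`.
#' @seealso [predict.methyl_clock()], [load_published_clock()],
#'   [fit_elastic_net()]
#' @export
methyl_clock <- function(intercept, coefficients, training_meta = list()) {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept))
    stop("'intercept' must be a finite numeric scalar")
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
      stop("'coefficients' must be named by probe id")
    names(coefficients) <- canonical_probe_id(names(coefficients))
    if (anyDuplicated(names(coefficients)))
      stop("duplicate probe ids in coefficients")
    coefficients <- coefficients[coefficients != 0]
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 training_meta = training_meta),
            class = "methyl_clock")
}

#' @export
print.methyl_clock <- function(x, ...) {
  cat(sprintf("methyl_clock: %d CpG terms, intercept %.4f years\n",
              length(x$coefficients), x$intercept))
  tm <- x$training_meta
  if (length(tm) > 0)
    cat("  training:", paste(names(tm), unlist(lapply(tm, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.methyl_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.methyl_clock <- function(object, ...) {
  co <- object$coefficients
  cat(sprintf("Epigenetic clock with %d CpG sites\n", length(co)))
  cat(sprintf("  intercept: %.7f years\n", object$intercept))
  if (length(co) > 0) {
    df <- data.frame(probe_id = names(co), coefficient = unname(co))
    print(df[order(df$probe_id), ], row.names = FALSE)
  }
  invisible(object)
}

#' Predict DNA methylation age
#'
#' Applies a clock to a beta matrix: for each sample, age is the intercept
#' plus the dot product of the clock coefficients with that sample's beta
#' values at the clock CpGs.
#'
#' The handling of missing clock probes (probe absent from the matrix, or
#' beta `NA` for a sample) is an explicit policy: `"error"` (default)
#' refuses with the offending probes named, `"skip_sample"` returns `NA`
#' for affected samples and predicts the rest.
#'
#' @param object a [methyl_clock()]
#' @param newdata a [beta_matrix()], or a numeric matrix of betas
#'   (probes x samples) with dimnames.
#' @param missing_policy `"error"` or `"skip_sample"`.
#' @param ... unused
#' @return named numeric vector of predicted ages (years), one per sample.
#' @export
predict.methyl_clock <- function(object, newdata,
                                 missing_policy = c("error", "skip_sample"),
                                 ...) {
  missing_policy <- match.arg(missing_policy)
  if (is.matrix(newdata)) newdata <- beta_matrix(newdata)
  if (!inherits(newdata, "beta_matrix"))
    stop("'newdata' must be a beta_matrix or probes x samples matrix")
  probes <- names(object$coefficients)
  absent <- setdiff(probes, probe_ids(newdata))
  if (length(absent) > 0) {
    if (missing_policy == "error")
      stop("clock probes missing from beta matrix: ",
           paste(absent, collapse = ", "))
    return(stats::setNames(rep(NA_real_, ncol(newdata$betas)),
                           sample_ids(newdata)))
  }
  x <- newdata$betas[probes, , drop = FALSE]
  pred <- drop(crossprod(x, object$coefficients)) + object$intercept
  has_na <- colSums(is.na(x)) > 0
  if (any(has_na)) {
    if (missing_policy == "error")
      stop("missing beta at clock probes for sample(s): ",
           paste(colnames(x)[has_na], collapse = ", "))
    pred[has_na] <- NA_real_
  }
  stats::setNames(as.numeric(pred), sample_ids(newdata))
}

#' @rdname predict.methyl_clock
#' @param model a [methyl_clock()]
#' @param m a [beta_matrix()]
#' @export
predict_age <- function(model, m, missing_policy = c("error", "skip_sample")) {
  predict(model, m, missing_policy = match.arg(missing_policy))
}

#' Shared CpG sites between two clocks
#'
#' @param a,b [methyl_clock()] objects
#' @return character vector of probe ids present in both clocks' coefficient
#'   sets (empty when the clocks are disjoint).
#' @export
clock_overlap <- function(a, b) {
  intersect(names(a$coefficients), names(b$coefficients))
}

#' Write / read a clock model as delimited text
#'
#' The on-disk format is a plain tab-separated file: a header block of
#' `#key<TAB>value` metadata lines (intercept plus training provenance),
#' then one `probe_id<TAB>coefficient` row per CpG. Numbers are written with
#' `%.17g`, so serialization round-trips doubles bit-exactly and the file
#' stays diff-able and language-neutral.
#'
#' @param model a [methyl_clock()]
#' @param path file path
#' @return `write_clock` returns `path` invisibly; `read_clock` returns a
#'   [methyl_clock()].
#' @export
write_clock <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#intercept\t%.17g", model$intercept), con)
  tm <- model$training_meta
  for (k in names(tm)) {
    v <- tm[[k]]
    v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    writeLines(sprintf("#%s\t%s", k, v), con)
  }
  writeLines("probe_id\tcoefficient", con)
  if (length(model$coefficients) > 0)
    writeLines(sprintf("%s\t%.17g", names(model$coefficients),
                       model$coefficients), con)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else NA_character_
  }
  if (is.null(meta$intercept)) stop("clock file lacks an #intercept line")
  intercept <- as.numeric(meta$intercept)
  meta$intercept <- NULL
  numeric_keys <- c("alpha", "penalty", "cpg_filter_threshold",
                    "n_training", "seed")
  for (k in intersect(names(meta), numeric_keys))
    meta[[k]] <- as.numeric(meta[[k]])
  body <- lines[!hdr]
  if (length(body) < 1 || body[1] != "probe_id\tcoefficient")
    stop("malformed clock file: expected 'probe_id\\tcoefficient' header")
  coefs <- numeric(0)
  if (length(body) > 1) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    coefs <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                             vapply(parts, `[`, "", 1))
  }
  methyl_clock(intercept, coefs, meta)
}

# Table of published clocks packaged with cetaclock. Coefficients are in
# years per unit beta on the raw (normalized) beta scale.
.published_clocks <- list(
  maui_hectors_8cpg = list(
    intercept = -4.6720053,
    coefficients = c(
      cg00817637 =  0.2573007,
      cg09026530 = -2.0929561,
      cg09402653 =  2.4794632,
      cg09461098 = -0.8055783,
      cg16496042 =  2.7959477,
      cg20582188 = -9.9140532,
      cg24276148 = 16.2120942,
      cg25254739 = -5.6220444
    ),
    training_meta = list(alpha = 0.9, cpg_filter_threshold = 10,
                         training_set_label = "strict", n_training = 31)
  )
)

#' Load a packaged published clock
#'
#' `"maui_hectors_8cpg"` is the eight-CpG skin clock for Maui and Hector's
#' dolphins (*Cephalorhynchus hectori*), trained on 31 tooth-aged
#' individuals with elastic-net mixing alpha = 0.9 after requiring
#' significant detection p-values in at least 10 individuals.
#'
#' @param name clock identifier; currently only `"maui_hectors_8cpg"`.
#' @return a [methyl_clock()]
#' @examples
#' clock <- load_published_clock("maui_hectors_8cpg")
#' length(clock$coefficients)  # 8
#' @export
load_published_clock <- function(name = "maui_hectors_8cpg") {
  entry <- .published_clocks[[name]]
  if (is.null(entry))
    stop("unknown published clock '", name, "'; available: ",
         paste(names(.published_clocks), collapse = ", "))
  methyl_clock(entry$intercept, entry$coefficients, entry$training_meta)
}
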