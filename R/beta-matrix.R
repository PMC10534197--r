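#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds normalized methylation fractions (beta values) for
#' a set of CpG probes measured on a set of samples, optionally paired with
#' a detection p-value for every measurement. Beta values lie in \[0, 1\]
#' (0 = fully unmethylated); detection p-values measure confidence that a
#' probe's signal exceeds background, with large values indicating failed
#' measurements.
#'
#' Probe identifiers are canonicalized to lower case on construction, since
#' array probe names are conventionally "cg"-prefixed but appear in mixed
#' case in published coefficient tables.
#'
#' @param betas numeric matrix, probes in rows and samples in columns, with
#'   rownames (probe ids) and colnames (sample ids). Values must be in
#'   \[0, 1\]; `NA` is allowed.
#' @param detection_p optional numeric matrix of per-measurement detection
#'   p-values, same dimensions and dimnames as `betas`.
#' @return An object of class `beta_matrix`: a list with elements `betas`
#'   and `detection_p` (possibly `NULL`).
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' m <- beta_matrix(b)
#' probe_ids(m)
#' @export
beta_matrix <- function(betas, detection_p = NULL) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("'betas' must be a numeric matrix (probes x samples)")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("'betas' must have probe ids as rownames and sample ids as colnames")
  rownames(betas) <- canonical_probe_id(rownames(betas))
  if (anyDuplicated(rownames(betas)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(betas)[duplicated(rownames(betas))]), collapse = ", "))
  if (anyDuplicated(colnames(betas)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(betas)[duplicated(colnames(betas))]), collapse = ", "))
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1 | !is.finite(betas)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]],
                 betas[bad[1, 1], bad[1, 2]]))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(betas)))
      stop("'detection_p' must be a matrix with the same dimensions as 'betas'")
    rownames(detection_p) <- canonical_probe_id(rownames(detection_p))
    if (!identical(rownames(detection_p), rownames(betas)) ||
        !identical(colnames(detection_p), colnames(betas)))
      stop("'detection_p' dimnames must match 'betas'")
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values must lie in [0,1]")
  }
  structure(list(betas = betas, detection_p = detection_p),
            class = "beta_matrix")
}

canonical_probe_id <- function(x) tolower(trimws(x))

#' @rdname beta_matrix
#' @param m a `beta_matrix`
#' @export
probe_ids <- function(m) rownames(m$betas)

#' @rdname beta_matrix
#' @export
sample_ids <- function(m) colnames(m$betas)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%s detection p-values, %d missing betas)\n",
              nrow(x$betas), ncol(x$betas),
              if (is.null(x$detection_p)) "no" else "with",
              sum(is.na(x$betas))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$betas)

#' Subset a beta matrix by probe and/or sample
#'
#' @param x a `beta_matrix`
#' @param probes,samples character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @param ... unused
#' @return a `beta_matrix`
#' @export
subset.beta_matrix <- function(x, probes = NULL, samples = NULL, ...) {
  if (is.null(probes)) probes <- seq_len(nrow(x$betas))
  if (is.character(probes)) {
    probes <- canonical_probe_id(probes)
    missing_p <- setdiff(probes, rownames(x$betas))
    if (length(missing_p) > 0)
      stop("probes not present: ", paste(missing_p, collapse = ", "))
  }
  if (is.null(samples)) samples <- seq_len(ncol(x$betas))
  if (is.character(samples)) {
    missing_s <- setdiff(samples, colnames(x$betas))
    if (length(missing_s) > 0)
      stop("samples not present: ", paste(missing_s, collapse = ", "))
  }
  beta_matrix(x$betas[probes, samples, drop = FALSE],
              if (!is.null(x$detection_p))
                x$detection_p[probes, samples, drop = FALSE])
}

delim_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV/CSV matrix (delimiter chosen by file extension: `.csv` is
#' comma, anything else tab) with identifiers in the first row and column.
#' Empty cells and `NA` are missing values. Values outside \[0, 1\] are
#' rejected with the offending probe and sample named.
#'
#' @param path path to the delimited beta matrix.
#' @param dialect `"probes_in_rows"` (default) if rows are probes, or
#'   `"samples_in_rows"` if transposed; output is always probes x samples.
#' @param detection_p_path optional path to a detection p-value matrix with
#'   the same layout and identifiers.
#' @return a [beta_matrix()]
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path,
                             dialect = c("probes_in_rows", "samples_in_rows"),
                             detection_p_path = NULL) {
  dialect <- match.arg(dialect)
  betas <- read_numeric_matrix(path, dialect)
  dp <- if (!is.null(detection_p_path))
    read_numeric_matrix(detection_p_path, dialect)
  beta_matrix(betas, dp)
}

read_numeric_matrix <- function(path, dialect) {
  sep <- delim_for_path(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(x), dim(x)))) & !is.na(x),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   x[bad[1, 1], bad[1, 2]], rownames(x)[bad[1, 1]],
                   colnames(x)[bad[1, 2]], path))
    storage.mode(x) <- "numeric"
  }
  if (dialect == "samples_in_rows") x <- t(x)
  x
}

#' Write a beta-value matrix to delimited text
#'
#' Values are written with `%.17g` so a read/write round-trip preserves
#' every stored double bit-exactly.
#'
#' @param m a [beta_matrix()]
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @param what `"betas"` or `"detection_p"`.
#' @return `path`, invisibly
#' @export
write_beta_matrix <- function(m, path, what = c("betas", "detection_p")) {
  what <- match.arg(what)
  x <- m[[what]]
  if (is.null(x)) stop("matrix has no ", what)
  write_numeric_matrix(x, path)
  invisible(path)
}

write_numeric_matrix <- function(x, path) {
  sep <- delim_for_path(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(x)), collapse = sep), con)
  body <- apply(x, 1, function(row)
    paste(ifelse(is.na(row), "", sprintf("%.17g", row)), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
}

#' Merge two training sets on their shared probes
#'
#' Joint multi-species clocks are trained by pooling samples from several
#' training sets over the intersection of their probe universes; samples are
#' concatenated and species membership is carried only through the metadata
#' `group_label` (no species covariate is added to the design).
#'
#' @param a,b lists with elements `m` (a [beta_matrix()]) and `meta` (a
#'   metadata data frame from [read_metadata()] or [sample_metadata()]).
#' @return a list with merged `m` and `meta`.
#' @export
merge_training_sets <- function(a, b) {
  shared <- intersect(probe_ids(a$m), probe_ids(b$m))
  if (length(shared) == 0) stop("merge error: no shared probes between sets")
  dup <- intersect(sample_ids(a$m), sample_ids(b$m))
  if (length(dup) > 0)
    stop("merge error: duplicate sample ids across sets: ",
         paste(dup, collapse = ", "))
  betas <- cbind(a$m$betas[shared, , drop = FALSE],
                 b$m$betas[shared, , drop = FALSE])
  dp <- if (!is.null(a$m$detection_p) && !is.null(b$m$detection_p))
    cbind(a$m$detection_p[shared, , drop = FALSE],
          b$m$detection_p[shared, , drop = FALSE])
  meta <- rbind(a$meta, b$meta)
  list(m = beta_matrix(betas, dp), meta = meta)
}
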