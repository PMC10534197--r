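#' Sample metadata table
#'
#' Builds and validates the per-sample annotation table used throughout the
#' pipeline: chronological age (from tooth growth layer groups for training
#' animals; absent for unaged biopsy samples), an age-confidence tier, sex,
#' species/subspecies group, tissue source, and survey period.
#'
#' Confidence tiers encode the training-subset design: `strict` samples have
#' high-confidence ages and must carry one; `relaxed_only` samples carry at
#' least a minimum age estimate and enter only the relaxed (strict ∪
#' relaxed_only) subset; `unknown` marks unaged test samples.
#'
#' @param sample_id,individual_id character vectors; `individual_id` is
#'   shared across serial samples of the same animal (defaults to
#'   `sample_id`).
#' @param age_years non-negative ages in years, `NA` when unknown.
#' @param confidence_tier one of `"strict"`, `"relaxed_only"`, `"unknown"`.
#' @param sex one of `"F"`, `"M"`, `"unknown"`.
#' @param group_label free-text species/subspecies label.
#' @param tissue_source one of `"beachcast"`, `"biopsy"`, or `NA`.
#' @param survey_period free-text survey period, `NA` when absent.
#' @param collection_date `Date` (or parseable string), `NA` when absent.
#' @return a `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id,
                            individual_id = sample_id,
                            age_years = NA_real_,
                            confidence_tier = "unknown",
                            sex = "unknown",
                            group_label = NA_character_,
                            tissue_source = NA_character_,
                            survey_period = NA_character_,
                            collection_date = as.Date(NA)) {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    individual_id = as.character(individual_id),
    age_years = rep_len(as.numeric(age_years), n),
    confidence_tier = rep_len(as.character(confidence_tier), n),
    sex = rep_len(as.character(sex), n),
    group_label = rep_len(as.character(group_label), n),
    tissue_source = rep_len(as.character(tissue_source), n),
    survey_period = rep_len(as.character(survey_period), n),
    collection_date = rep_len(as.Date(collection_date), n),
    stringsAsFactors = FALSE
  )
  validate_metadata(df)
}

parse_enum <- function(x, levels, field, allow_na = TRUE) {
  x <- as.character(x)
  out <- levels[match(tolower(trimws(x)), tolower(levels))]
  bad <- !is.na(x) & nzchar(trimws(x)) & is.na(out)
  if (any(bad))
    stop(sprintf("format error in '%s': unknown token '%s' (expected one of %s)",
                 field, x[which(bad)[1]], paste(levels, collapse = ", ")))
  if (!allow_na && any(is.na(out)))
    stop(sprintf("format error: '%s' may not be empty", field))
  out
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$confidence_tier <- parse_enum(df$confidence_tier,
                                   c("strict", "relaxed_only", "unknown"),
                                   "confidence_tier")
  df$confidence_tier[is.na(df$confidence_tier)] <- "unknown"
  df$sex <- parse_enum(df$sex, c("F", "M", "unknown"), "sex")
  df$sex[is.na(df$sex)] <- "unknown"
  df$tissue_source <- parse_enum(df$tissue_source, c("beachcast", "biopsy"),
                                 "tissue_source")
  if (any(!is.na(df$age_years) & df$age_years < 0))
    stop("age_years must be non-negative")
  bad_strict <- df$confidence_tier == "strict" & is.na(df$age_years)
  if (any(bad_strict))
    stop("validation error: strict-tier sample(s) with missing age: ",
         paste(df$sample_id[bad_strict], collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a sample metadata table from delimited text
#'
#' Expects named columns (any subset of the [sample_metadata()] fields
#' beyond the mandatory `sample_id`); enum fields are parsed
#' case-insensitively and empty cells become unknowns. A `strict`
#' confidence tier with a missing age is a validation error.
#'
#' @param path path to a TSV/CSV file (delimiter by extension).
#' @return a `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  sep <- delim_for_path(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a 'sample_id' column")
  defaults <- list(individual_id = df$sample_id, age_years = NA_real_,
                   confidence_tier = "unknown", sex = "unknown",
                   group_label = NA_character_, tissue_source = NA_character_,
                   survey_period = NA_character_, collection_date = NA)
  for (f in names(defaults))
    if (!f %in% names(df)) df[[f]] <- defaults[[f]]
  df$age_years <- as.numeric(df$age_years)
  df$collection_date <- as.Date(as.character(df$collection_date))
  validate_metadata(df[c("sample_id", "individual_id", "age_years",
                         "confidence_tier", "sex", "group_label",
                         "tissue_source", "survey_period", "collection_date")])
}

#' Write a sample metadata table
#' @param meta a `sample_metadata` data frame
#' @param path output path (TSV/CSV by extension)
#' @return `path`, invisibly
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = delim_for_path(path),
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Select a training subset by confidence tier
#'
#' `"strict"` keeps only high-confidence aged samples; `"relaxed"` keeps
#' strict plus relaxed-only samples (the strict set is always a subset of
#' the relaxed set).
#'
#' @param meta a `sample_metadata` data frame
#' @param tier `"strict"` or `"relaxed"`
#' @return the filtered metadata
#' @export
training_subset <- function(meta, tier = c("strict", "relaxed")) {
  tier <- match.arg(tier)
  keep <- if (tier == "strict") meta$confidence_tier == "strict"
          else meta$confidence_tier %in% c("strict", "relaxed_only")
  out <- meta[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Align a beta matrix with metadata on sample_id; errors on any mismatch
# rather than silently dropping or reordering.
align_samples <- function(m, meta) {
  missing_meta <- setdiff(sample_ids(m), meta$sample_id)
  if (length(missing_meta) > 0)
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta[match(sample_ids(m), meta$sample_id), , drop = FALSE]
}
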