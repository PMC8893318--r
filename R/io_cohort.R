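#' Construct a clinical record
#'
#' @param case_id Case identifier (string).
#' @param sex `"female"` or `"male"`.
#' @param age Age in years, non-negative.
#' @param ruptured Binary rupture label (0/1), or `NA` if unknown.
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(case_id, sex, age, ruptured = NA) {
  sex <- as.character(sex)
  if (!sex %in% c("female", "male"))
    .anf_stop("anf_validation_error", "sex must be 'female' or 'male' (got '%s')", sex)
  age <- suppressWarnings(as.numeric(age))
  if (is.na(age) || age < 0)
    .anf_stop("anf_validation_error", "age must be a non-negative number")
  if (!is.na(ruptured) && !ruptured %in% c(0, 1))
    .anf_stop("anf_validation_error", "ruptured label must be 0 or 1")
  structure(list(case_id = as.character(case_id), sex = sex, age = age,
                 ruptured = if (is.na(ruptured)) NA_integer_ else as.integer(ruptured)),
            class = "clinical_record")
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header columns `case_id, volume, mask, mesh,
#' sex, age, ruptured`. File paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param manifest Path to the manifest CSV.
#' @param check_files Report entries whose files are missing (default TRUE;
#'   missing files raise a validation error listing the case ids).
#' @return A list of cohort entries, each a list with `case_id`, `volume`,
#'   `mask`, `mesh` (paths) and `clinical` (a [clinical_record()]).
#' @export
read_cohort <- function(manifest, check_files = TRUE) {
  if (!file.exists(manifest))
    .anf_stop("anf_format_error", "manifest '%s' does not exist", manifest)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("case_id", "volume", "mask", "mesh", "sex", "age", "ruptured")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .anf_stop("anf_format_error", "manifest missing columns: %s",
              paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    .anf_stop("anf_validation_error", "manifest has no rows")
  dup <- unique(df$case_id[duplicated(df$case_id)])
  if (length(dup))
    .anf_stop("anf_validation_error", "duplicated case_id: %s",
              paste(dup, collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age))
  if (any(is.na(age)))
    .anf_stop("anf_validation_error", "unparseable age for case(s): %s",
              paste(df$case_id[is.na(age)], collapse = ", "))
  lab <- suppressWarnings(as.numeric(df$ruptured))
  if (any(is.na(lab)) || any(!lab %in% c(0, 1)))
    .anf_stop("anf_validation_error", "ruptured label outside {0,1} for case(s): %s",
              paste(df$case_id[is.na(lab) | !lab %in% c(0, 1)], collapse = ", "))
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    list(case_id = df$case_id[i],
         volume = resolve(df$volume[i]),
         mask = resolve(df$mask[i]),
         mesh = resolve(df$mesh[i]),
         clinical = clinical_record(df$case_id[i], df$sex[i], age[i], lab[i]))
  })
  if (isTRUE(check_files)) {
    missing_files <- vapply(entries, function(e)
      !all(file.exists(c(e$volume, e$mask, e$mesh))), logical(1))
    if (any(missing_files))
      .anf_stop("anf_validation_error", "missing files for case(s): %s",
                paste(vapply(entries[missing_files], `[[`, "", "case_id"),
                      collapse = ", "))
  }
  entries
}

# ---- feature tables -------------------------------------------------------

#' Construct a per-case feature table
#'
#' @param ids Character vector of case ids (unique).
#' @param features Numeric matrix, cases x features, with unique column names.
#' @param labels Binary labels (0/1), one per case, or NULL.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(ids, features, labels = NULL) {
  features <- as.matrix(features); storage.mode(features) <- "double"
  ids <- as.character(ids)
  if (nrow(features) != length(ids))
    .anf_stop("anf_validation_error", "ids and feature rows differ in length")
  if (anyDuplicated(ids))
    .anf_stop("anf_validation_error", "duplicated case ids in feature table")
  if (is.null(colnames(features)) || anyDuplicated(colnames(features)))
    .anf_stop("anf_validation_error", "features must have unique column names")
  if (any(!is.finite(features)))
    .anf_stop("anf_validation_error", "feature table contains non-finite values")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(ids) || any(!labels %in% c(0L, 1L)))
      .anf_stop("anf_validation_error", "labels must be 0/1, one per case")
  }
  structure(list(ids = ids, features = features, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases x %d features%s\n",
              nrow(x$features), ncol(x$features),
              if (is.null(x$labels)) "" else
                sprintf(", %d positive labels", sum(x$labels))))
  invisible(x)
}

#' Write a feature table as CSV
#'
#' One row per case; columns `case_id`, one per feature, and `label` when
#' labels are present. Values are written with enough digits to round-trip
#' (read-back reproduces values to 1e-12 relative).
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) == 0L || ncol(table$features) == 0L)
    .anf_stop("anf_validation_error", "empty feature table: nothing to write")
  df <- data.frame(case_id = table$ids, stringsAsFactors = FALSE)
  vals <- apply(table$features, 2, function(col) sprintf("%.17g", col))
  vals <- matrix(vals, nrow = nrow(table$features),
                 dimnames = list(NULL, colnames(table$features)))
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  if (!is.null(table$labels)) df$label <- table$labels
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .anf_stop("anf_io_error", "cannot write '%s'", path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    .anf_stop("anf_format_error", "file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"case_id" %in% names(df))
    .anf_stop("anf_format_error", "'%s' lacks a case_id column", path)
  labels <- NULL
  if ("label" %in% names(df)) { labels <- df$label; df$label <- NULL }
  ids <- as.character(df$case_id); df$case_id <- NULL
  m <- as.matrix(as.data.frame(lapply(df, as.numeric)))
  colnames(m) <- names(df)
  feature_table(ids, m, labels)
}

# ---- cross-validation reports ---------------------------------------------

#' Write a cross-validation report as JSON
#'
#' @param report A `cv_report` as returned by [nested_cv()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  payload <- unclass(report)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .anf_stop("anf_io_error", "cannot write '%s'", path)
  invisible(path)
}

#' Read a cross-validation report written by [write_report()]
#'
#' @param path JSON path.
#' @return A `cv_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    .anf_stop("anf_format_error", "file '%s' does not exist", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "cv_report")
}
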