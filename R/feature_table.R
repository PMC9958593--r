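#' Write a feature table to CSV at full precision
#'
#' Columns are the feature columns (named `<feature>_<channel>`,
#' feature-major) followed by `label`, `subject_id`, `session_id`. Numeric
#' values are written with 17 significant digits so the round trip through
#' [read_feature_table()] is lossless.
#'
#' @param features feature table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  need <- c("label", "subject_id", "session_id")
  if (!all(need %in% names(features))) {
    stopf("feature table must contain columns %s", paste(need, collapse = ", "))
  }
  out <- features
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- sprintf("%.17g", out[[cl]])
    }
  }
  write.table(out, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric feature columns and metadata columns;
#'   empty (zero-row) tables round-trip to zero-row data.frames.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    for (cl in setdiff(names(df), c("subject_id"))) {
      if (cl %in% c("label", "session_id")) df[[cl]] <- as.integer(df[[cl]])
      else df[[cl]] <- as.numeric(df[[cl]])
    }
    df$subject_id <- as.character(df$subject_id)
  }
  df
}
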