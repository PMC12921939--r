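#' Write a field table to CSV
#'
#' Works for both truth tables ([make_true_field()], [cohort_truths()]) and
#' measured tables ([run_exam()]). Values are written at full double
#' precision; `-Inf` (absolute scotoma in truth tables) is serialized as the
#' literal token `"-inf"`. Measured tables never contain `-Inf` (the floor
#' is 0 dB).
#'
#' @param field A field tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  out <- as.data.frame(field)
  for (col in c("true_db", "sensitivity_db")) {
    if (col %in% names(out)) {
      v <- sprintf("%.15g", out[[col]])
      v[is.infinite(out[[col]]) & out[[col]] < 0] <- "-inf"
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field table from CSV
#'
#' Inverse of [write_field_csv()]: parses the `"-inf"` token back to `-Inf`
#' and restores numeric types.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in intersect(c("x_deg", "y_deg"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in intersect(c("true_db", "sensitivity_db"), names(df))) {
    v <- rep(NA_real_, nrow(df))
    inf <- df[[col]] %in% c("-inf", "-Inf")
    v[!inf] <- as.numeric(df[[col]][!inf])
    v[inf] <- -Inf
    df[[col]] <- v
  }
  if ("n_presentations" %in% names(df)) {
    df$n_presentations <- as.integer(df$n_presentations)
  }
  tibble::as_tibble(df)
}

#' Compare two measured-field CSV files
#'
#' Convenience wrapper: reads the projection-device and head-mounted CSVs
#' (schema of [write_field_csv()]), runs [compare_fields()], and optionally
#' writes the JSON report.
#'
#' @param octopus_csv,hmp_csv Input CSV paths.
#' @param json_out Optional path for the serialized report.
#' @param ... Passed to [compare_fields()].
#' @return The `agreement_report`.
#' @export
compare_csv <- function(octopus_csv, hmp_csv, json_out = NULL, ...) {
  report <- compare_fields(read_field_csv(octopus_csv),
                           read_field_csv(hmp_csv), ...)
  if (!is.null(json_out)) report_to_json(report, json_out)
  report
}
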