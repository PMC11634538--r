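# Serialized report dialect:
#  - scores printed to 2 decimals; thresholding upstream uses unrounded values
#  - logical flags as "True"/"False"
#  - pairs with no shared markers carry empty score cells and an explicit
#    "no shared markers" note (a 0 would falsely imply evidence of mismatch)

#' Write the batch summary report
#'
#' One row per profile: mixing flag (with offending markers), top Tanabe
#' match(es), and the per-algorithm threshold match lists serialized as
#' `"id (score); id (score)"`. Column order is fixed; output is
#' byte-identical across runs on identical input.
#'
#' @param summary The `summary` tibble from [compare_many_to_many()] or
#'   [compare_query_to_database()].
#' @param path Output file (`.csv`, `.tsv`/`.txt` or `.xlsx`).
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(summary, path) {
  if (is.null(summary) || nrow(summary) == 0L) {
    stop("summary is empty; nothing to write", call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = summary$sample_id,
    mixing_flagged = ifelse(summary$mixing_flagged, "True", "False"),
    mixing_markers = summary$mixing_markers,
    top_match_id = summary$top_match_id,
    top_match_tanabe = format_score(summary$top_match_tanabe),
    tanabe_matches = summary$tanabe_matches,
    masters_query_matches = summary$masters_query_matches,
    masters_reference_matches = summary$masters_reference_matches
  )
  write_table_file(out, path, sheet_name = "summary")
  invisible(path)
}

#' Write per-sample comparison reports
#'
#' One file per profile, named `<sample_id>.<fmt>` (ids sanitized to file
#' names), each holding that profile's ranked comparisons against all
#' others. These files support closer interrogation of samples with
#' potential mixing or genetic drift.
#'
#' @param reports The `reports` list from [compare_many_to_many()] or
#'   [compare_query_to_database()].
#' @param directory Output directory (created if missing).
#' @param fmt `"csv"`, `"tsv"` or `"xlsx"`.
#' @return Character vector of file paths written, invisibly.
#' @export
write_sample_reports <- function(reports, directory, fmt = c("csv", "tsv",
                                                             "xlsx")) {
  fmt <- match.arg(fmt)
  if (length(reports) == 0L) {
    stop("no reports to write", call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(reports))
  for (k in seq_along(reports)) {
    id <- names(reports)[k]
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", id), ".", fmt)
    paths[k] <- file.path(directory, fname)
    write_table_file(format_report_rows(reports[[k]]), paths[k],
                     sheet_name = sanitize_sheet_name(id))
  }
  invisible(paths)
}

format_report_rows <- function(rows) {
  undefined <- rows$n_markers_used == 0L
  tibble::tibble(
    query_id = rows$query_id,
    reference_id = rows$reference_id,
    n_shared = as.character(rows$n_shared),
    n_query = as.character(rows$n_query),
    n_reference = as.character(rows$n_reference),
    n_markers_used = as.character(rows$n_markers_used),
    tanabe = format_score(rows$tanabe),
    masters_query = format_score(rows$masters_query),
    masters_reference = format_score(rows$masters_reference),
    note = ifelse(undefined, "no shared markers", "")
  )
}
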