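#' Read STR profiles from a table file
#'
#' Supports two layouts across CSV, TSV and XLSX:
#' * **wide** -- header row of `Sample` plus marker names, one row per
#'   sample; a cell may carry several alleles, comma- or space-separated.
#' * **long** -- columns `Sample`, `Marker`, `Allele` (case-insensitive),
#'   one row per sample/marker/allele triple.
#'
#' The delimiter is chosen by extension (`.csv` comma; `.tsv`/`.txt` tab;
#' `.xlsx` first sheet unless `sheet` is given), never sniffed, so parsing is
#' deterministic. Marker names are harmonized through the panel alias table
#' and alleles normalized; collection order is row order.
#'
#' @param path Input file; extension one of `.csv`, `.tsv`, `.txt`, `.xlsx`.
#' @param layout `"wide"` or `"long"`.
#' @param panel An [str_panel()] configuration.
#' @param sheet XLSX sheet name or index (default first).
#' @return An `str_collection`.
#' @export
read_profiles <- function(path, layout = c("wide", "long"),
                          panel = str_panel(), sheet = 1L) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  tab <- read_table_file(path, sheet)
  if (layout == "wide") parse_wide(tab, panel) else parse_long(tab, panel)
}

read_table_file <- function(path, sheet = 1L) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv  = readr::read_csv(path, col_types = readr::cols(
             .default = readr::col_character()), progress = FALSE),
    tsv  = ,
    txt  = readr::read_tsv(path, col_types = readr::cols(
             .default = readr::col_character()), progress = FALSE),
    xlsx = readxl::read_excel(path, sheet = sheet, col_types = "text"),
    stop("unsupported file extension '.", ext,
         "' (expected .csv/.tsv/.txt/.xlsx): ", path, call. = FALSE)
  )
  tab[] <- lapply(tab, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  tab
}

parse_wide <- function(tab, panel) {
  if (ncol(tab) < 2L) {
    stop("wide layout needs a sample column plus at least one marker column",
         call. = FALSE)
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  markers <- vapply(names(tab)[-1L], harmonize_marker_name, character(1),
                    panel = panel)
  profiles <- lapply(seq_along(ids), function(i) {
    g <- lapply(seq_along(markers), function(j) {
      tryCatch(parse_allele_cell(tab[[j + 1L]][i]),
               error = function(e) stop(
                 conditionMessage(e), " (sample '", ids[i], "', marker ",
                 markers[j], ")", call. = FALSE))
    })
    names(g) <- markers
    str_profile(ids[i], g[lengths(g) > 0L])
  })
  str_collection(profiles)
}

parse_long <- function(tab, panel) {
  idx <- match(c("sample", "marker", "allele"), tolower(names(tab)))
  if (anyNA(idx)) {
    stop("long layout needs columns Sample, Marker, Allele; found: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  samples <- tab[[idx[1]]]
  markers <- vapply(tab[[idx[2]]], harmonize_marker_name, character(1),
                    panel = panel, USE.NAMES = FALSE)
  ids <- unique(samples)
  profiles <- lapply(ids, function(id) {
    sel <- samples == id
    g <- split(tab[[idx[3]]][sel], markers[sel])
    str_profile(id, g)
  })
  str_collection(profiles)
}

#' Write STR profiles to a table file
#'
#' Serializes a collection in the wide or long layout; format by extension
#' (`.csv`, `.tsv`/`.txt`, `.xlsx`). Alleles within a cell are comma-joined
#' in canonical order (ascending numeric, microvariants by fractional part,
#' letters last with X before Y), so outputs are byte-stable and
#' `read_profiles(write_profiles(p))` reproduces every (sample, marker,
#' allele-set) triple exactly.
#'
#' @param profiles An `str_collection` (or list of `str_profile`), non-empty.
#' @param path Output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (length(profiles) == 0L) {
    stop("cannot write an empty profile collection", call. = FALSE)
  }
  tab <- if (layout == "wide") profiles_to_wide(profiles)
         else profiles_to_long(profiles)
  write_table_file(tab, path)
  invisible(path)
}

write_table_file <- function(tab, path, sheet_name = "Sheet1") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv  = readr::write_csv(tab, path, progress = FALSE),
    tsv  = ,
    txt  = readr::write_tsv(tab, path, progress = FALSE),
    xlsx = write_xlsx(stats::setNames(list(tab), sheet_name), path),
    stop("unsupported file extension '.", ext,
         "' (expected .csv/.tsv/.txt/.xlsx): ", path, call. = FALSE)
  )
  invisible(path)
}
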