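# Minimal XLSX writer.
#
# XLSX is a ZIP archive of SpreadsheetML parts. This writer emits stored
# (uncompressed) ZIP entries with a fixed timestamp, inline-string cells,
# and per-sheet external hyperlink relationships. Fixed timestamps and
# deterministic part ordering make outputs byte-identical across runs.

#' Write data frames to an XLSX workbook
#'
#' One worksheet per element of `sheets`. Character cells are written as
#' inline strings, numeric cells as numbers. `hyperlinks` optionally attaches
#' external links to cells: a named list (by sheet) of data frames with
#' columns `row` (1-based data row, excluding the header), `col` (1-based
#' column) and `target` (URL).
#'
#' @param sheets Named list of data frames; names become worksheet names
#'   (sanitized to Excel's sheet-name rules, see [sanitize_sheet_name()]).
#' @param path Output `.xlsx` path.
#' @param hyperlinks Optional named list of hyperlink tables (see above).
#' @return `path`, invisibly.
#' @export
write_xlsx <- function(sheets, path, hyperlinks = NULL) {
  stopifnot(is.list(sheets), length(sheets) >= 1L)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    stop("every sheet must be named", call. = FALSE)
  }
  nms <- sanitize_sheet_name(names(sheets))
  n <- length(sheets)

  entries <- list()
  add <- function(name, xml) entries[[length(entries) + 1L]] <<-
    list(name = name, data = charToRaw(xml))

  sheet_overrides <- paste0(
    '<Override PartName="/xl/worksheets/sheet', seq_len(n),
    '.xml" ContentType="application/vnd.openxmlformats-officedocument',
    '.spreadsheetml.worksheet+xml"/>', collapse = "")
  add("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType=',
    '"application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    sheet_overrides, '</Types>'))

  add("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'))

  sheet_tags <- paste0(
    '<sheet name="', xml_escape(nms), '" sheetId="', seq_len(n),
    '" r:id="rId', seq_len(n), '"/>', collapse = "")
  add("xl/workbook.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheet_tags, '</sheets></workbook>'))

  wb_rels <- paste0(
    '<Relationship Id="rId', seq_len(n), '" Type="http://schemas.',
    'openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet', seq_len(n), '.xml"/>', collapse = "")
  add("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    wb_rels,
    '<Relationship Id="rId', n + 1L, '" Type="http://schemas.openxmlformats',
    '.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
    '</Relationships>'))

  add("xl/styles.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf/></cellXfs></styleSheet>'))

  for (i in seq_len(n)) {
    links <- if (!is.null(hyperlinks)) hyperlinks[[names(sheets)[i]]]
    add(paste0("xl/worksheets/sheet", i, ".xml"),
        sheet_xml(sheets[[i]], links))
    if (!is.null(links) && nrow(links) > 0L) {
      rels <- paste0(
        '<Relationship Id="rIdL', seq_len(nrow(links)),
        '" Type="http://schemas.openxmlformats.org/officeDocument/2006/',
        'relationships/hyperlink" Target="', xml_escape(links$target),
        '" TargetMode="External"/>', collapse = "")
      add(paste0("xl/worksheets/_rels/sheet", i, ".xml.rels"), paste0(
        '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
        '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
        rels, '</Relationships>'))
    }
  }

  zip_write_stored(entries, path)
  invisible(path)
}

sheet_xml <- function(df, links = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rows <- character(nrow(df) + 1L)
  header <- vapply(seq_along(df), function(j)
    cell_xml(1L, j, names(df)[j], FALSE), character(1))
  rows[1L] <- paste0('<row r="1">', paste(header, collapse = ""), '</row>')
  numeric_col <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (is.na(v)) return("")
      cell_xml(i + 1L, j, v, numeric_col[j])
    }, character(1))
    rows[i + 1L] <- paste0('<row r="', i + 1L, '">',
                           paste(cells, collapse = ""), '</row>')
  }
  link_xml <- ""
  if (!is.null(links) && nrow(links) > 0L) {
    link_xml <- paste0(
      "<hyperlinks>",
      paste0('<hyperlink ref="', cell_ref(links$row + 1L, links$col),
             '" r:id="rIdL', seq_len(nrow(links)), '"/>', collapse = ""),
      "</hyperlinks>")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData>',
    link_xml, '</worksheet>')
}

cell_xml <- function(row, col, value, numeric) {
  ref <- cell_ref(row, col)
  if (numeric) {
    paste0('<c r="', ref, '"><v>', format(value, scientific = FALSE), '</v></c>')
  } else {
    paste0('<c r="', ref, '" t="inlineStr"><is><t xml:space="preserve">',
           xml_escape(as.character(value)), '</t></is></c>')
  }
}

# A1-style reference; col is 1-based
cell_ref <- function(row, col) {
  letters_for <- function(n) {
    out <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      out <- paste0(LETTERS[r + 1L], out)
      n <- (n - 1L) %/% 26L
    }
    out
  }
  paste0(vapply(col, letters_for, character(1)), row)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Sanitize worksheet names
#'
#' Applies Excel's sheet-name rules: the characters `[ ] : * ? / \`
#' become `_`, names are truncated to 31 characters, empty names become
#' `Sheet`, and duplicates get numeric suffixes.
#'
#' @param x Character vector of proposed names.
#' @return Valid, unique worksheet names.
#' @export
sanitize_sheet_name <- function(x) {
  x <- gsub("[\\[\\]:*?/\\\\]", "_", x, perl = TRUE)
  x <- substr(x, 1L, 31L)
  x[!nzchar(x)] <- "Sheet"
  make.unique(x, sep = "_")
}

# ---- store-only ZIP container ------------------------------------------

zip_write_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  # fixed DOS timestamp (2024-01-01 00:00) for reproducible archives
  dos_date <- bitwOr(bitwOr(bitwShiftL(44L, 9L), bitwShiftL(1L, 5L)), 1L)
  dos_time <- 0L

  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crcs[i] <- crc32(e$data)
    offsets[i] <- pos
    u32(0x04034b50); u16(20L); u16(0L); u16(0L)  # local header, no flags
    u16(dos_time); u16(dos_date)
    u32(crcs[i]); u32(length(e$data)); u32(length(e$data))
    u16(length(nm)); u16(0L)
    writeBin(nm, con); writeBin(e$data, con)
    pos <- pos + 30L + length(nm) + length(e$data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    u32(0x02014b50); u16(20L); u16(20L); u16(0L); u16(0L)
    u16(dos_time); u16(dos_date)
    u32(crcs[i]); u32(length(e$data)); u32(length(e$data))
    u16(length(nm)); u16(0L); u16(0L); u16(0L); u16(0L)
    u32(0L); u32(offsets[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  u32(0x06054b50); u16(0L); u16(0L)
  u16(length(entries)); u16(length(entries))
  u32(pos - cd_start); u32(cd_start); u16(0L)
  invisible(path)
}

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(.crc_env$tab)) {
    poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
    tab <- integer(256L)
    for (n in 0:255) {
      c <- as.integer(n)
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(poly, bitwShiftR(c, 1L))
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tab[n + 1L] <- c
    }
    .crc_env$tab <- tab
  }
  .crc_env$tab
}

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  bytes <- as.integer(data)
  for (b in bytes) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}
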