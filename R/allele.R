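#' Normalize a raw allele token
#'
#' STR alleles are named by repeat count ("12"), by repeat count plus a
#' microvariant suffix ("13.3"), or -- for the sex-typing marker amelogenin --
#' by the letters "X"/"Y". Spreadsheet exports routinely mangle these tokens
#' (stray whitespace, lower case, a trailing ".0" from float coercion);
#' `normalize_allele()` maps any such variant onto one canonical string so
#' that allele identity is plain string equality.
#'
#' Empty cells and the conventional not-typed vocabulary (`""`, `"NA"`,
#' `"N/A"`, `"-"`, `"--"`, case-insensitive) normalize to no allele at all,
#' returned as `character(0)`.
#'
#' @param raw A single character string, the raw cell token.
#' @return A length-one character vector with the canonical token, or
#'   `character(0)` if the input means "not typed".
#' @examples
#' normalize_allele(" 12.0 ")  # "12"
#' normalize_allele("x")       # "X"
#' normalize_allele("13.3")    # "13.3"
#' normalize_allele("NA")      # character(0)
#' @export
normalize_allele <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  tok <- gsub("[[:space:]]+", "", raw)
  if (is_na_token(tok)) {
    return(character(0))
  }
  if (grepl("[^0-9A-Za-z.]", tok)) {
    stop("malformed allele token: ", encodeString(raw, quote = "\""),
         call. = FALSE)
  }
  tok <- toupper(tok)
  # spreadsheet float artifact: 12.0 -> 12 (but 13.3 untouched)
  tok <- sub("\\.0$", "", tok)
  if (!grepl("^([0-9]+(\\.[0-9]+)?|[A-Z]+)$", tok)) {
    stop("malformed allele token: ", encodeString(raw, quote = "\""),
         call. = FALSE)
  }
  tok
}

is_na_token <- function(tok) {
  is.na(tok) || toupper(tok) %in% c("", "NA", "N/A", "-", "--")
}

#' Parse one wide-format cell into a set of alleles
#'
#' A wide-layout cell may carry several alleles separated by commas and/or
#' whitespace ("8,10", "X Y"). Each token is normalized and the result is
#' de-duplicated: the homozygous notation "10,10" stores the single allele
#' "10", matching the distinct-allele counting used by the similarity scores.
#'
#' @param raw A single character string (one table cell).
#' @return Character vector of distinct canonical alleles, possibly empty,
#'   in canonical display order (see [sort_alleles()]).
#' @examples
#' parse_allele_cell("8,10")   # c("8", "10")
#' parse_allele_cell("10,10")  # "10"
#' parse_allele_cell("X Y")    # c("X", "Y")
#' @export
parse_allele_cell <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is_na_token(gsub("[[:space:]]+", "", raw))) {
    return(character(0))
  }
  parts <- strsplit(raw, "[,[:space:]]+")[[1]]
  parts <- parts[nzchar(parts)]
  toks <- unlist(lapply(parts, normalize_allele), use.names = FALSE)
  sort_alleles(unique(toks))
}

#' Sort alleles into canonical display order
#'
#' Numeric tokens ascend by repeat count (microvariants by their fractional
#' part, so "13" < "13.3" < "14"); letter tokens follow all numeric tokens,
#' alphabetically, which places "X" before "Y". This fixed order makes every
#' serialized output bit-stable and diffable.
#'
#' @param alleles Character vector of canonical allele tokens.
#' @return The same tokens, canonically ordered.
#' @export
sort_alleles <- function(alleles) {
  if (length(alleles) == 0L) return(character(0))
  num <- suppressWarnings(as.numeric(alleles))
  is_num <- !is.na(num)
  c(alleles[is_num][order(num[is_num])],
    alleles[!is_num][order(alleles[!is_num])])
}
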