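#' Marker panel configuration
#'
#' Commercial STR kits (PowerPlex, Identifiler, ...) type overlapping but
#' differently spelled marker sets ("Penta_D", "PENTA D", "Penta D" are the
#' same locus). A panel configuration bundles the alias table that maps raw
#' spellings onto canonical names, identifies the sex-typing marker
#' (amelogenin), and records two scoring switches.
#'
#' @param marker_aliases Optional extra aliases, either a named character
#'   vector (`c(raw = "Canonical", ...)`) or a path to a two-column CSV with
#'   columns `alias,canonical`. These are merged over the table shipped with
#'   the package (`system.file("extdata", "marker_aliases.csv", package =
#'   "strmatch")`), which users may also copy and edit wholesale.
#' @param amelogenin_name Canonical name of the sex-typing marker
#'   (default `"AMEL"`).
#' @param include_amelogenin Logical; count amelogenin in similarity scores
#'   and mixing flags? Default `FALSE` -- a sex-marker match inflates
#'   similarity without carrying identity information, the convention also
#'   used by the Cellosaurus CLASTR service.
#' @param penalize_missing Logical; if `TRUE`, score denominators count each
#'   profile's alleles over all its typed markers rather than only the
#'   markers typed in both profiles, so a locus typed in only one profile
#'   depresses the score. Default `FALSE` (common-marker scoring).
#' @return An object of class `str_panel`.
#' @examples
#' p <- str_panel()
#' harmonize_marker_name("PENTA D", p)  # "PentaD"
#' @export
str_panel <- function(marker_aliases = NULL,
                      amelogenin_name = "AMEL",
                      include_amelogenin = FALSE,
                      penalize_missing = FALSE) {
  stopifnot(is.character(amelogenin_name), length(amelogenin_name) == 1L,
            is.logical(include_amelogenin), length(include_amelogenin) == 1L,
            is.logical(penalize_missing), length(penalize_missing) == 1L)
  aliases <- default_marker_aliases()
  if (!is.null(marker_aliases)) {
    extra <- if (is.character(marker_aliases) && is.null(names(marker_aliases))
                 && length(marker_aliases) == 1L) {
      read_alias_table(marker_aliases)
    } else {
      stopifnot(is.character(marker_aliases), !is.null(names(marker_aliases)))
      marker_aliases
    }
    names(extra) <- marker_key(names(extra))
    aliases[names(extra)] <- unname(extra)
  }
  # idempotence: every canonical name must resolve to itself
  canon_keys <- marker_key(unname(aliases))
  missing_self <- setdiff(canon_keys, names(aliases))
  aliases[missing_self] <-
    unname(aliases)[match(missing_self, canon_keys)]
  structure(
    list(marker_aliases = aliases,
         amelogenin_name = amelogenin_name,
         include_amelogenin = include_amelogenin,
         penalize_missing = penalize_missing),
    class = "str_panel"
  )
}

# normalized lookup key: case-folded, separators stripped
marker_key <- function(x) toupper(gsub("[ _-]", "", x))

default_marker_aliases <- function() {
  read_alias_table(system.file("extdata", "marker_aliases.csv",
                               package = "strmatch", mustWork = TRUE))
}

read_alias_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("alias", "canonical") %in% names(tab))) {
    stop("alias table must have columns 'alias' and 'canonical': ", path,
         call. = FALSE)
  }
  stats::setNames(tab$canonical, marker_key(tab$alias))
}

#' Harmonize a raw marker name to its canonical form
#'
#' Case-folds the name, strips spaces, underscores and hyphens, then looks it
#' up in the panel's alias table. Unknown markers are never dropped: they
#' pass through in case-folded form with a warning, so custom loci still
#' participate in comparisons.
#'
#' @param raw A single marker name as it appears in an input file.
#' @param panel An [str_panel()] configuration.
#' @return The canonical marker name.
#' @examples
#' harmonize_marker_name("vWA", str_panel())   # "vWA"
#' harmonize_marker_name("th01", str_panel())  # "TH01"
#' @export
harmonize_marker_name <- function(raw, panel = str_panel()) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw),
            inherits(panel, "str_panel"))
  key <- marker_key(raw)
  hit <- panel$marker_aliases[key]
  if (is.na(hit)) {
    warning("unknown marker name '", raw, "' kept as '", key, "'",
            call. = FALSE)
    return(unname(key))
  }
  unname(hit)
}

#' @export
print.str_panel <- function(x, ...) {
  cat("<str_panel> ", length(unique(x$marker_aliases)), " canonical markers, ",
      length(x$marker_aliases), " aliases\n", sep = "")
  cat("  amelogenin: ", x$amelogenin_name,
      if (x$include_amelogenin) " (scored)" else " (excluded from scores)",
      "\n", sep = "")
  cat("  denominators: ",
      if (x$penalize_missing) "all typed markers" else "common markers only",
      "\n", sep = "")
  invisible(x)
}
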