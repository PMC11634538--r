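#' Construct an STR profile
#'
#' An STR profile is one sample's genotype: a sample identifier plus, for each
#' typed marker, the set of distinct alleles observed there. Allele sets are
#' stored de-duplicated and canonically ordered, so a homozygous locus holds
#' one allele -- the convention under which the similarity scores count
#' alleles.
#'
#' @param sample_id Unique sample identifier (non-empty string).
#' @param genotypes Named list: canonical marker name -> character vector of
#'   canonical allele tokens (may be raw; tokens are normalized here).
#' @param metadata Optional named character vector of free-form annotations
#'   (source, passage, ...).
#' @return An object of class `str_profile`.
#' @examples
#' p <- str_profile("S1", list(CSF1PO = c("11", "12"), TH01 = "9.3"))
#' p$genotypes$CSF1PO
#' @export
str_profile <- function(sample_id, genotypes, metadata = character(0)) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            nzchar(sample_id), is.list(genotypes))
  if (length(genotypes) > 0L &&
      (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))) {
    stop("all genotypes must be named by marker", call. = FALSE)
  }
  genotypes <- lapply(genotypes, function(al) {
    al <- as.character(al)
    toks <- unlist(lapply(al, normalize_allele), use.names = FALSE)
    sort_alleles(unique(toks))
  })
  prof <- structure(
    list(sample_id = sample_id, genotypes = genotypes,
         metadata = metadata),
    class = "str_profile"
  )
  validate_profile(prof)
}

#' Validate an STR profile
#'
#' Checks the structural invariants: marker-named allele sets with no
#' duplicate tokens, and at least one marker typed (non-empty allele set).
#'
#' @param profile An `str_profile`.
#' @return The profile, invisibly usable, or an error.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "str_profile"))
  g <- profile$genotypes
  if (length(g) && anyDuplicated(names(g))) {
    stop("profile '", profile$sample_id, "' has duplicated markers: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "),
         call. = FALSE)
  }
  for (m in names(g)) {
    if (anyDuplicated(g[[m]])) {
      stop("profile '", profile$sample_id, "' marker ", m,
           " has duplicate alleles", call. = FALSE)
    }
  }
  if (!any(lengths(g) > 0L)) {
    stop("profile '", profile$sample_id,
         "' has no typed markers", call. = FALSE)
  }
  profile
}

# markers with at least one allele
typed_markers <- function(profile) {
  names(profile$genotypes)[lengths(profile$genotypes) > 0L]
}

#' Assemble profiles into a collection
#'
#' A collection is a list of profiles with unique sample identifiers, in a
#' stable order (the order of the input, which for files is row order).
#'
#' @param profiles List of `str_profile` objects.
#' @return The list, named by sample id, with class `str_collection`.
#' @export
str_collection <- function(profiles) {
  stopifnot(is.list(profiles))
  if (!all(vapply(profiles, inherits, logical(1), "str_profile"))) {
    stop("all elements must be str_profile objects", call. = FALSE)
  }
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(profiles, ids), class = "str_collection")
}

#' @export
print.str_profile <- function(x, ...) {
  cat("<str_profile> ", x$sample_id, ": ",
      sum(lengths(x$genotypes) > 0L), " typed markers, ",
      sum(lengths(x$genotypes)), " alleles\n", sep = "")
  invisible(x)
}

#' @export
print.str_collection <- function(x, ...) {
  cat("<str_collection> ", length(x), " profiles: ",
      paste(utils::head(names(x), 8L), collapse = ", "),
      if (length(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.str_collection` <- function(x, i) {
  structure(NextMethod(), class = "str_collection")
}

#' Tabulate a collection as a long tibble
#'
#' One row per (sample, marker, allele) triple, the long input/output layout.
#'
#' @param profiles An `str_collection` or list of `str_profile`.
#' @return A tibble with columns `Sample`, `Marker`, `Allele`.
#' @export
profiles_to_long <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    g <- p$genotypes[lengths(p$genotypes) > 0L]
    if (!length(g)) return(NULL)
    tibble::tibble(
      Sample = p$sample_id,
      Marker = rep(names(g), lengths(g)),
      Allele = unlist(g, use.names = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Tabulate a collection as a wide tibble
#'
#' One row per sample, one column per marker; multi-allele cells are
#' comma-joined in canonical allele order. Column order is the order in which
#' markers first appear across the collection.
#'
#' @param profiles An `str_collection` or list of `str_profile`.
#' @return A tibble with a `Sample` column followed by marker columns.
#' @export
profiles_to_wide <- function(profiles) {
  markers <- unique(unlist(lapply(profiles, function(p)
    names(p$genotypes)), use.names = FALSE))
  rows <- lapply(profiles, function(p) {
    cells <- vapply(markers, function(m) {
      al <- p$genotypes[[m]]
      if (is.null(al) || !length(al)) "" else paste(al, collapse = ",")
    }, character(1))
    tibble::as_tibble(c(list(Sample = p$sample_id), as.list(cells)))
  })
  dplyr::bind_rows(rows)
}
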