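#' Markers entering a pairwise comparison
#'
#' The similarity formulas are defined over loci typed in both profiles:
#' a marker enters the comparison only if both the query and the reference
#' carry at least one allele there. Amelogenin is excluded unless the panel
#' opts it in.
#'
#' @param query,reference `str_profile` objects.
#' @param panel An [str_panel()] configuration.
#' @return Character vector of canonical marker names (possibly empty).
#' @export
marker_universe <- function(query, reference, panel = str_panel()) {
  m <- intersect(typed_markers(query), typed_markers(reference))
  if (!panel$include_amelogenin) {
    m <- setdiff(m, panel$amelogenin_name)
  }
  m
}

#' Count shared alleles over a set of markers
#'
#' Sums, marker by marker, the size of the intersection of the two profiles'
#' allele sets. Alleles at different markers never match each other.
#'
#' @param query,reference `str_profile` objects.
#' @param markers Marker names to count over (typically from
#'   [marker_universe()]).
#' @return Integer count of shared alleles.
#' @export
shared_allele_count <- function(query, reference, markers) {
  sum(vapply(markers, function(m) {
    length(intersect(query$genotypes[[m]], reference$genotypes[[m]]))
  }, integer(1)))
}

#' Score one ordered profile pair
#'
#' Computes the three similarity scores used for cell line and PDX model
#' authentication, each a percentage of shared alleles:
#' \deqn{Tanabe = 100 \cdot \frac{2 s}{q + r}, \quad
#'       Masters_{query} = 100 \cdot \frac{s}{q}, \quad
#'       Masters_{ref} = 100 \cdot \frac{s}{r}}
#' where \eqn{s} is the number of shared alleles and \eqn{q}, \eqn{r} the
#' query's and reference's distinct-allele counts. The Tanabe score is the
#' Sørensen–Dice coefficient on the pooled per-marker allele sets; the two
#' Masters scores are asymmetric and diagnostic for which sample contaminates
#' which (a mixture scores 100 versus each of its components as reference).
#'
#' By default allele counts are restricted to the common-marker universe
#' (markers typed in both profiles, amelogenin excluded); with
#' `panel$penalize_missing` the denominators count each profile's alleles
#' over all its own typed markers instead. If the profiles share no markers
#' all three scores are `NA` ("no shared markers" -- not evidence of
#' mismatch).
#'
#' @param query,reference `str_profile` objects.
#' @param panel An [str_panel()] configuration.
#' @return A one-row tibble: `query_id`, `reference_id`, `n_shared`,
#'   `n_query`, `n_reference`, `n_markers_used`, `tanabe`, `masters_query`,
#'   `masters_reference`. Scores are percentages in `[0, 100]` at full
#'   precision (reports round to 2 decimals; thresholding never rounds).
#' @examples
#' p <- str_panel()
#' a <- str_profile("A", list(CSF1PO = c("11", "12"), TH01 = c("6", "9.3")))
#' b <- str_profile("B", list(CSF1PO = c("11", "12"), TH01 = c("6", "7")))
#' score_pair(a, b, p)
#' @export
score_pair <- function(query, reference, panel = str_panel()) {
  markers <- marker_universe(query, reference, panel)
  s <- shared_allele_count(query, reference, markers)
  if (panel$penalize_missing) {
    own <- function(p) {
      m <- typed_markers(p)
      if (!panel$include_amelogenin) m <- setdiff(m, panel$amelogenin_name)
      sum(lengths(p$genotypes[m]))
    }
    q <- own(query); r <- own(reference)
  } else {
    q <- sum(lengths(query$genotypes[markers]))
    r <- sum(lengths(reference$genotypes[markers]))
  }
  n_used <- length(markers)
  if (n_used == 0L) {
    tan <- mq <- mr <- NA_real_
  } else {
    tan <- 100 * 2 * s / (q + r)
    mq <- 100 * s / q
    mr <- 100 * s / r
  }
  tibble::tibble(
    query_id = query$sample_id,
    reference_id = reference$sample_id,
    n_shared = as.integer(s),
    n_query = as.integer(q),
    n_reference = as.integer(r),
    n_markers_used = as.integer(n_used),
    tanabe = tan,
    masters_query = mq,
    masters_reference = mr
  )
}

# All-vs-all scoring via incidence-matrix products.
#
# Rows are profiles; columns of X are (marker, allele) tokens. Then
#   shared  S = X X'        (a token in both profiles implies the marker is
#                            typed in both)
#   n_query N = C T'        with C the per-marker allele counts and T the
#                            typed-marker indicator, so N[i, j] is profile
#                            i's allele count over markers typed in j
#   markers U = T T'
# which reproduces score_pair() for every ordered pair at matrix speed.
# Under penalize_missing the denominators are each profile's own totals.
score_matrix <- function(profiles, panel = str_panel()) {
  ids <- unname(vapply(profiles, `[[`, character(1), "sample_id"))
  n <- length(profiles)
  gts <- lapply(profiles, function(p) {
    g <- p$genotypes[lengths(p$genotypes) > 0L]
    if (!panel$include_amelogenin) {
      g <- g[setdiff(names(g), panel$amelogenin_name)]
    }
    g
  })
  tokens <- lapply(gts, function(g) {
    if (!length(g)) character(0)
    else paste(rep(names(g), lengths(g)), unlist(g, use.names = FALSE),
               sep = "\r")
  })
  tok_levels <- unique(unlist(tokens, use.names = FALSE))
  markers <- unique(unlist(lapply(gts, names), use.names = FALSE))
  X <- matrix(0, n, max(length(tok_levels), 1L))
  Tm <- matrix(0, n, max(length(markers), 1L))
  Cm <- matrix(0, n, max(length(markers), 1L))
  for (i in seq_len(n)) {
    X[i, match(tokens[[i]], tok_levels)] <- 1
    mi <- match(names(gts[[i]]), markers)
    Tm[i, mi] <- 1
    Cm[i, mi] <- lengths(gts[[i]])
  }
  S <- X %*% t(X)
  Nq <- if (panel$penalize_missing) {
    matrix(rowSums(Cm), n, n)
  } else {
    Cm %*% t(Tm)
  }
  U <- Tm %*% t(Tm)
  list(ids = ids, shared = S, n_query = Nq, n_reference = t(Nq),
       n_markers = U,
       tanabe = ifelse(U > 0, 100 * 2 * S / (Nq + t(Nq)), NA_real_),
       masters_query = ifelse(U > 0, 100 * S / Nq, NA_real_),
       masters_reference = ifelse(U > 0, 100 * S / t(Nq), NA_real_))
}
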