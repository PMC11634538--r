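#' Matching and mixing thresholds
#'
#' The default match threshold is 80% for all three algorithms -- the level
#' at which the Tanabe and Masters scores have been shown to identify
#' matching profiles in 98--99% of cases -- and the mixing heuristic flags a
#' profile with three or more alleles at three or more loci.
#'
#' @param tanabe_min,masters_query_min,masters_reference_min Minimum
#'   percentage (in `[0, 100]`) for a comparison to be reported as a match
#'   under each algorithm. Default 80.
#' @param mix_allele_min Number of alleles at a locus for it to count toward
#'   the mixing flag (default 3).
#' @param mix_marker_min Number of such loci required to raise the flag
#'   (default 3).
#' @return An object of class `str_thresholds`.
#' @export
str_thresholds <- function(tanabe_min = 80, masters_query_min = 80,
                           masters_reference_min = 80,
                           mix_allele_min = 3L, mix_marker_min = 3L) {
  for (v in c(tanabe_min, masters_query_min, masters_reference_min)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100) {
      stop("score thresholds must be single numbers in [0, 100]",
           call. = FALSE)
    }
  }
  for (v in c(mix_allele_min, mix_marker_min)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop("mixing thresholds must be counts >= 1", call. = FALSE)
    }
  }
  structure(
    list(tanabe_min = as.numeric(tanabe_min),
         masters_query_min = as.numeric(masters_query_min),
         masters_reference_min = as.numeric(masters_reference_min),
         mix_allele_min = as.integer(mix_allele_min),
         mix_marker_min = as.integer(mix_marker_min)),
    class = "str_thresholds"
  )
}

#' Flag potential sample mixing
#'
#' A profile carrying three or more alleles at three or more loci likely
#' contains DNA from more than one individual and is flagged for further
#' investigation. The rule counts loci, not alleles in total: one locus with
#' five alleles does not raise the flag on its own. Amelogenin never counts
#' toward mixing (X,Y in a normal male is already two alleles) unless the
#' panel opts it in.
#'
#' @param profile An `str_profile`.
#' @param thresholds An [str_thresholds()] object; `mix_allele_min` and
#'   `mix_marker_min` control the rule.
#' @param panel An [str_panel()] configuration.
#' @return A list with `flagged` (logical) and `markers` (the offending
#'   marker names, canonically ordered).
#' @export
flag_mixing <- function(profile, thresholds = str_thresholds(),
                        panel = str_panel()) {
  g <- profile$genotypes
  if (!panel$include_amelogenin) {
    g <- g[setdiff(names(g), panel$amelogenin_name)]
  }
  offending <- sort(names(g)[lengths(g) >= thresholds$mix_allele_min])
  list(flagged = length(offending) >= thresholds$mix_marker_min,
       markers = offending)
}

#' Rank comparison results
#'
#' Orders score rows by descending unrounded Tanabe score; ties break by
#' descending Masters (vs query), then ascending reference id. Pairs with no
#' shared markers (undefined scores) sort after all defined scores. The
#' ordering is total, so identical input always yields identical output.
#'
#' @param rows A tibble of score rows as returned by [score_pair()].
#' @return The same tibble, reordered.
#' @export
rank_matches <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  tan <- replace(rows$tanabe, is.na(rows$tanabe), -Inf)
  mq <- replace(rows$masters_query, is.na(rows$masters_query), -Inf)
  rows[order(-tan, -mq, rows$reference_id), , drop = FALSE]
}

#' Compare every profile to every other profile
#'
#' The batch authentication workflow: all ordered pairs in the collection
#' are scored (one computation per unordered pair; the reverse direction
#' follows from Tanabe symmetry and Masters duality), and two kinds of
#' results are assembled:
#' * a **summary** with one row per profile -- its mixing flag, its top
#'   Tanabe match(es) among the other profiles, and, for each algorithm,
#'   every other profile whose unrounded score meets that algorithm's
#'   threshold;
#' * one **sample report** per profile: that profile queried against all
#'   others, ranked by [rank_matches()], for closer interrogation of
#'   mixing or genetic drift.
#'
#' Self-comparisons (trivially 100) are excluded everywhere.
#'
#' @param profiles An `str_collection` (or list of `str_profile`) of at
#'   least two profiles with unique ids.
#' @param thresholds An [str_thresholds()] object.
#' @param panel An [str_panel()] configuration.
#' @return A list with `summary` (tibble, one row per profile) and `reports`
#'   (named list of ranked score tibbles, N-1 rows each).
#' @examples
#' profs <- generate_profiles(n_samples = 4, seed = 1)
#' res <- compare_many_to_many(profs)
#' res$summary
#' @export
compare_many_to_many <- function(profiles, thresholds = str_thresholds(),
                                 panel = str_panel()) {
  profiles <- as_profile_list(profiles)
  if (length(profiles) < 2L) {
    stop("need at least 2 profiles to compare", call. = FALSE)
  }
  sm <- score_matrix(profiles, panel)
  n <- length(profiles)
  keep <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  assemble_results(profiles, profiles, sm, query_rows = seq_len(n),
                   ref_cols = keep, thresholds = thresholds, panel = panel)
}

#' Compare query profiles against a reference database
#'
#' Each query is scored against every database entry; a database entry
#' sharing the query's sample id is taken to be the query itself and is
#' excluded from its own results. Output types match
#' [compare_many_to_many()].
#'
#' @param queries An `str_collection` (or list) of query profiles.
#' @param database An `str_collection` (or list) of reference profiles with
#'   unique ids; must be non-empty.
#' @param thresholds An [str_thresholds()] object.
#' @param panel An [str_panel()] configuration.
#' @return A list with `summary` and `reports` as in
#'   [compare_many_to_many()].
#' @export
compare_query_to_database <- function(queries, database,
                                      thresholds = str_thresholds(),
                                      panel = str_panel()) {
  queries <- as_profile_list(queries)
  database <- as_profile_list(database)
  if (length(database) == 0L) {
    stop("reference database is empty", call. = FALSE)
  }
  db_ids <- vapply(database, `[[`, character(1), "sample_id")
  if (anyDuplicated(db_ids)) {
    stop("duplicate sample ids in database: ",
         paste(unique(db_ids[duplicated(db_ids)]), collapse = ", "),
         call. = FALSE)
  }
  all_prof <- c(queries, database)
  sm <- score_matrix(all_prof, panel)
  nq <- length(queries)
  q_ids <- vapply(queries, `[[`, character(1), "sample_id")
  ref_cols <- lapply(seq_len(nq), function(i)
    nq + which(db_ids != q_ids[i]))
  assemble_results(queries, all_prof, sm, query_rows = seq_len(nq),
                   ref_cols = ref_cols, thresholds = thresholds,
                   panel = panel)
}

as_profile_list <- function(x) {
  if (inherits(x, "str_profile")) x <- list(x)
  str_collection(unclass(x))
}

# shared assembly for both comparison modes; sm indexes all_prof
assemble_results <- function(queries, all_prof, sm, query_rows, ref_cols,
                             thresholds, panel) {
  summaries <- vector("list", length(query_rows))
  reports <- vector("list", length(query_rows))
  for (k in seq_along(query_rows)) {
    i <- query_rows[k]
    j <- ref_cols[[k]]
    rows <- tibble::tibble(
      query_id = queries[[k]]$sample_id,
      reference_id = sm$ids[j],
      n_shared = as.integer(sm$shared[i, j]),
      n_query = as.integer(sm$n_query[i, j]),
      n_reference = as.integer(sm$n_reference[i, j]),
      n_markers_used = as.integer(sm$n_markers[i, j]),
      tanabe = sm$tanabe[i, j],
      masters_query = sm$masters_query[i, j],
      masters_reference = sm$masters_reference[i, j]
    )
    rows <- rank_matches(rows)
    mix <- flag_mixing(queries[[k]], thresholds, panel)
    defined <- !is.na(rows$tanabe)
    top <- if (any(defined)) {
      best <- max(rows$tanabe[defined])
      sort(rows$reference_id[defined & rows$tanabe == best])
    } else character(0)
    summaries[[k]] <- tibble::tibble(
      sample_id = queries[[k]]$sample_id,
      mixing_flagged = mix$flagged,
      mixing_markers = paste(mix$markers, collapse = "; "),
      top_match_id = paste(top, collapse = "; "),
      top_match_tanabe = if (any(defined)) max(rows$tanabe[defined])
                         else NA_real_,
      tanabe_matches = match_list(rows, "tanabe", thresholds$tanabe_min),
      masters_query_matches =
        match_list(rows, "masters_query", thresholds$masters_query_min),
      masters_reference_matches =
        match_list(rows, "masters_reference",
                   thresholds$masters_reference_min)
    )
    reports[[k]] <- rows
  }
  list(summary = dplyr::bind_rows(summaries),
       reports = stats::setNames(
         reports, vapply(queries, `[[`, character(1), "sample_id")))
}

# "id (score); id (score)" for rows meeting the (unrounded) threshold,
# sorted by descending score then id
match_list <- function(rows, column, minimum) {
  sc <- rows[[column]]
  sel <- which(!is.na(sc) & sc >= minimum)
  if (!length(sel)) return("")
  sel <- sel[order(-sc[sel], rows$reference_id[sel])]
  paste0(rows$reference_id[sel], " (", format_score(sc[sel]), ")",
         collapse = "; ")
}

format_score <- function(x) {
  out <- sprintf("%.2f", x)
  out[is.na(x)] <- ""
  out
}
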