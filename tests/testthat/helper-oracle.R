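# Independent brute-force scoring oracle.
#
# Deliberately naive and structurally unlike the package implementation:
# token-by-token double loops over raw named lists of allele vectors, no
# set operations, no matrices. Used to cross-check score_pair() and the
# batch engine.

oracle_score <- function(q_genotypes, r_genotypes,
                         include_amelogenin = FALSE, amel = "AMEL",
                         penalize_missing = FALSE) {
  shared <- 0L
  n_query <- 0L
  n_reference <- 0L
  n_markers <- 0L
  all_markers <- unique(c(names(q_genotypes), names(r_genotypes)))
  for (m in all_markers) {
    if (!include_amelogenin && m == amel) next
    qa <- q_genotypes[[m]]
    ra <- r_genotypes[[m]]
    typed_q <- !is.null(qa) && length(qa) > 0L
    typed_r <- !is.null(ra) && length(ra) > 0L
    if (typed_q && typed_r) {
      n_markers <- n_markers + 1L
      for (a in qa) {
        for (b in ra) {
          if (identical(a, b)) shared <- shared + 1L
        }
      }
    }
    count_q <- if (penalize_missing) typed_q else (typed_q && typed_r)
    count_r <- if (penalize_missing) typed_r else (typed_q && typed_r)
    if (count_q) for (a in qa) n_query <- n_query + 1L
    if (count_r) for (b in ra) n_reference <- n_reference + 1L
  }
  if (n_markers == 0L) {
    tanabe <- mq <- mr <- NA_real_
  } else {
    tanabe <- 100 * 2 * shared / (n_query + n_reference)
    mq <- 100 * shared / n_query
    mr <- 100 * shared / n_reference
  }
  list(n_shared = shared, n_query = n_query, n_reference = n_reference,
       n_markers_used = n_markers, tanabe = tanabe, masters_query = mq,
       masters_reference = mr)
}

# random small profile as a plain named list of allele vectors, drawn from a
# compact shared pool so random pairs genuinely overlap; ~10% empty loci
random_genotypes <- function(markers = c("AMEL", "M1", "M2", "M3", "M4"),
                             pool = as.character(6:12)) {
  g <- lapply(markers, function(m) {
    if (stats::runif(1) < 0.1) return(character(0))
    if (m == "AMEL") {
      unique(sample(c("X", "Y"), 2L, replace = TRUE))
    } else {
      unique(sample(pool, sample(1:3, 1L), replace = TRUE))
    }
  })
  names(g) <- markers
  g
}

genotypes_to_profile <- function(id, g) {
  str_profile(id, g[lengths(g) > 0L])
}

expect_score_matches_oracle <- function(q, r, panel = str_panel()) {
  got <- score_pair(q, r, panel)
  want <- oracle_score(q$genotypes, r$genotypes,
                       include_amelogenin = panel$include_amelogenin,
                       amel = panel$amelogenin_name,
                       penalize_missing = panel$penalize_missing)
  expect_identical(got$n_shared, as.integer(want$n_shared))
  expect_identical(got$n_markers_used, as.integer(want$n_markers_used))
  expect_identical(got$n_query, as.integer(want$n_query))
  expect_identical(got$n_reference, as.integer(want$n_reference))
  expect_equal(got$tanabe, want$tanabe)
  expect_equal(got$masters_query, want$masters_query)
  expect_equal(got$masters_reference, want$masters_reference)
}
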