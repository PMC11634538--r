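panel <- str_panel()
thr <- str_thresholds()

# profile with `n_loci` loci of `n_alleles` alleles each, padded with
# diploid loci so every profile has the same panel width
grid_profile <- function(n_loci, n_alleles, id = "G") {
  g <- list()
  for (i in seq_len(4)) {
    g[[paste0("M", i)]] <- if (i <= n_loci)
      as.character(seq_len(n_alleles)) else c("1", "2")
  }
  str_profile(id, g)
}

test_that("mixing flag reproduces the 3-alleles-at-3-loci truth table", {
  for (n_loci in 1:4) {
    for (n_alleles in 1:4) {
      res <- flag_mixing(grid_profile(n_loci, n_alleles), thr, panel)
      expect_identical(res$flagged, n_loci >= 3 && n_alleles >= 3,
                       label = sprintf("loci=%d alleles=%d", n_loci,
                                       n_alleles))
    }
  }
})

test_that("mixing flag counts loci, not total alleles, and names offenders", {
  one_busy <- str_profile("P", list(M1 = as.character(1:5), M2 = c("1", "2"),
                                    M3 = c("1", "2")))
  expect_false(flag_mixing(one_busy, thr, panel)$flagged)
  expect_identical(flag_mixing(one_busy, thr, panel)$markers, "M1")
  three <- str_profile("P", list(M1 = c("1", "2", "3"),
                                 M2 = c("4", "5", "6"),
                                 M3 = c("7", "8", "9")))
  res <- flag_mixing(three, thr, panel)
  expect_true(res$flagged)
  expect_identical(res$markers, c("M1", "M2", "M3"))
})

test_that("amelogenin never counts toward mixing by default", {
  p <- str_profile("P", list(AMEL = c("X", "Y", "1"),
                             M1 = c("1", "2", "3"),
                             M2 = c("1", "2", "3")))
  expect_false(flag_mixing(p, thr, panel)$flagged)
  expect_true(flag_mixing(p, thr,
                          str_panel(include_amelogenin = TRUE))$flagged)
})

test_that("adding alleles never un-flags a profile", {
  set.seed(5)
  for (i in 1:25) {
    profs <- generate_profiles(1, seed = i)
    p <- profs[[1]]
    grown <- p$genotypes
    for (m in names(grown)) {
      grown[[m]] <- unique(c(grown[[m]], as.character(90:92)))
    }
    p2 <- str_profile("grown", grown)
    before <- flag_mixing(p, thr, panel)$flagged
    after <- flag_mixing(p2, thr, panel)$flagged
    expect_true(!before || after)
    expect_true(after)  # 3 added alleles at every locus always flags
  }
})

test_that("rank_matches orders by Tanabe, Masters-query, then id", {
  rows <- tibble::tibble(
    query_id = "Q",
    reference_id = c("E", "B", "A", "D", "C"),
    n_shared = 0L, n_query = 1L, n_reference = 1L,
    n_markers_used = c(1L, 1L, 1L, 0L, 1L),
    tanabe = c(100, 80, 80, NA, 0),
    masters_query = c(100, 85, 90, NA, 0),
    masters_reference = c(100, 85, 90, NA, 0)
  )
  ranked <- rank_matches(rows)
  expect_identical(ranked$reference_id, c("E", "A", "B", "C", "D"))
  # defined 0 sorts before undefined
  expect_true(which(ranked$reference_id == "C") <
              which(ranked$reference_id == "D"))
})

test_that("many-to-many output has the contracted cardinality", {
  profs <- generate_profiles(5, seed = 2)
  res <- compare_many_to_many(profs, thr, panel)
  expect_identical(nrow(res$summary), 5L)
  expect_length(res$reports, 5L)
  for (r in res$reports) {
    expect_identical(nrow(r), 4L)
  }
  # self never appears
  for (id in names(res$reports)) {
    expect_false(id %in% res$reports[[id]]$reference_id)
  }
  expect_error(compare_many_to_many(profs[1], thr, panel), "at least 2")
})

test_that("identical profiles list each other at 100 under all algorithms", {
  p <- generate_profiles(1, seed = 9)[[1]]
  q <- str_profile("COPY", p$genotypes)
  res <- compare_many_to_many(list(p, q), thr, panel)
  expect_identical(res$summary$top_match_id, c("COPY", p$sample_id))
  expect_equal(res$summary$top_match_tanabe, c(100, 100))
  expect_match(res$summary$tanabe_matches[1], "COPY \\(100\\.00\\)")
  expect_match(res$summary$masters_query_matches[1], "COPY \\(100\\.00\\)")
  expect_match(res$summary$masters_reference_matches[1],
               "COPY \\(100\\.00\\)")
  expect_false(any(res$summary$mixing_flagged))
})

test_that("unrelated profiles report empty threshold lists but a top match", {
  # disjoint allele pools force all cross scores to 0
  pools <- lapply(1:5, function(i)
    stats::setNames(list(as.character(i * 100 + 1:9),
                         as.character(i * 200 + 1:9)), c("M1", "M2")))
  profs <- str_collection(lapply(1:5, function(i)
    generate_profiles(1, allele_pools = pools[[i]], seed = i,
                      prefix = paste0("U", i, "_"))[[1]]))
  res <- compare_many_to_many(profs, thr, panel)
  expect_true(all(res$summary$tanabe_matches == ""))
  expect_true(all(res$summary$masters_query_matches == ""))
  expect_true(all(nzchar(res$summary$top_match_id)))
  expect_equal(res$summary$top_match_tanabe, rep(0, 5))
})

test_that("a union mixture recovers both components via Masters (vs reference)", {
  profs <- generate_profiles(2, seed = 31)
  mixed <- mix_profiles(profs[[1]], profs[[2]], "MIX")
  res <- compare_many_to_many(c(unclass(profs), list(mixed)), thr, panel)
  mix_row <- res$summary[res$summary$sample_id == "MIX", ]
  expect_match(mix_row$masters_reference_matches, "S001 \\(100\\.00\\)")
  expect_match(mix_row$masters_reference_matches, "S002 \\(100\\.00\\)")
  n_busy <- sum(vapply(setdiff(names(mixed$genotypes), "AMEL"),
                       function(m) length(mixed$genotypes[[m]]) >= 3L,
                       logical(1)))
  expect_identical(mix_row$mixing_flagged, n_busy >= 3L)
})

test_that("query-vs-database scores each query against all entries", {
  db <- generate_profiles(20, seed = 4)
  query <- str_profile("Q1", db[[7]]$genotypes)
  res <- compare_query_to_database(list(query), db, thr, panel)
  expect_identical(nrow(res$reports$Q1), 20L)
  expect_identical(res$reports$Q1$reference_id[1], "S007")
  expect_equal(res$reports$Q1$tanabe[1], 100)
  expect_identical(res$summary$top_match_id, "S007")
  # a query whose id is in the database is excluded from its own results
  res2 <- compare_query_to_database(db[3], db, thr, panel)
  expect_identical(nrow(res2$reports$S003), 19L)
  expect_false("S003" %in% res2$reports$S003$reference_id)
  expect_error(compare_query_to_database(db[3], list(), thr, panel),
               "empty")
})

test_that("pairs sharing no markers rank last with undefined scores", {
  q <- str_profile("Q", list(M1 = c("1", "2")))
  r1 <- str_profile("R1", list(M1 = c("3", "4")))
  r2 <- str_profile("R2", list(M9 = c("1", "2")))
  res <- compare_query_to_database(list(q), list(r1, r2), thr, panel)
  expect_identical(res$reports$Q$reference_id, c("R1", "R2"))
  expect_true(is.na(res$reports$Q$tanabe[2]))
})

test_that("reports serialize deterministically with the documented dialect", {
  profs <- c(unclass(generate_profiles(3, seed = 12)),
             list(mix_profiles(generate_profiles(3, seed = 12)[[1]],
                               generate_profiles(3, seed = 12)[[2]],
                               "MIX")))
  res <- compare_many_to_many(profs, thr, panel)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    write_summary_report(res$summary, file.path(d, "summary.csv"))
    write_sample_reports(res$reports, file.path(d, "reports"))
  }
  expect_identical(readBin(file.path(d1, "summary.csv"), "raw", 1e6),
                   readBin(file.path(d2, "summary.csv"), "raw", 1e6))
  for (f in list.files(file.path(d1, "reports"))) {
    expect_identical(readBin(file.path(d1, "reports", f), "raw", 1e6),
                     readBin(file.path(d2, "reports", f), "raw", 1e6))
  }
  summary_tab <- readr::read_csv(file.path(d1, "summary.csv"),
                                 col_types = readr::cols(
                                   .default = readr::col_character()))
  mix_row <- summary_tab[summary_tab$sample_id == "MIX", ]
  expect_identical(mix_row$mixing_flagged, "True")
  expect_true(nzchar(mix_row$mixing_markers))
  # per-sample file count and xlsx variant
  expect_length(list.files(file.path(d1, "reports")), 4L)
  xd <- withr::local_tempdir()
  write_sample_reports(res$reports, xd, fmt = "xlsx")
  back <- readxl::read_excel(file.path(xd, "MIX.xlsx"))
  expect_identical(nrow(back), 3L)
})

test_that("threshold lists agree with a brute-force filter", {
  base <- generate_profiles(8, seed = 77)
  variants <- lapply(1:4, function(i)
    perturb_profile(base[[i]], drop_rate = 0.3, drift_rate = 0.2,
                    seed = i, new_id = paste0("V", i)))
  profs <- c(unclass(base), variants)
  res <- compare_many_to_many(profs, thr, panel)
  ids <- vapply(profs, `[[`, character(1), "sample_id")
  for (k in seq_along(profs)) {
    listed <- res$summary$tanabe_matches[k]
    listed_ids <- if (nzchar(listed))
      sub(" \\(.*\\)$", "", strsplit(listed, "; ")[[1]]) else character(0)
    want <- character(0)
    scores <- numeric(0)
    for (j in seq_along(profs)) {
      if (j == k) next
      s <- score_pair(profs[[k]], profs[[j]], panel)
      if (!is.na(s$tanabe) && s$tanabe >= thr$tanabe_min) {
        want <- c(want, ids[j]); scores <- c(scores, s$tanabe)
      }
    }
    expect_setequal(listed_ids, want)
    # listed scores are sorted descending
    if (length(listed_ids) > 1) {
      shown <- as.numeric(sub(".*\\((.*)\\)$", "\\1",
                              strsplit(listed, "; ")[[1]]))
      expect_true(all(diff(shown) <= 0))
    }
  }
})
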