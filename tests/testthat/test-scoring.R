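panel <- str_panel()

test_that("marker universe is the typed intersection minus amelogenin", {
  q <- str_profile("Q", list(A = "1", B = "2", C = "3", AMEL = "X"))
  r <- str_profile("R", list(B = "2", C = "9", D = "4", AMEL = "X"))
  expect_setequal(marker_universe(q, r, panel), c("B", "C"))
  # amelogenin-only overlap is empty by default, present when opted in
  q2 <- str_profile("Q2", list(AMEL = "X", E = "5"))
  r2 <- str_profile("R2", list(AMEL = "X", F = "6"))
  expect_identical(marker_universe(q2, r2, panel), character(0))
  amel_panel <- str_panel(include_amelogenin = TRUE)
  expect_identical(marker_universe(q2, r2, amel_panel), "AMEL")
})

test_that("shared alleles count per-marker intersections only", {
  q <- str_profile("Q", list(M1 = c("8", "10", "12"), M2 = "X"))
  r <- str_profile("R", list(M1 = c("10", "12", "14"), M2 = c("X", "Y")))
  expect_identical(shared_allele_count(q, r, c("M1", "M2")), 3L)
  expect_identical(shared_allele_count(q, r, "M1"), 2L)
  # same token at different markers never matches
  a <- str_profile("A", list(M1 = "10", M2 = "11"))
  b <- str_profile("B", list(M1 = "11", M2 = "10"))
  expect_identical(shared_allele_count(a, b, c("M1", "M2")), 0L)
})

test_that("worked pair reproduces the hand-enumerated counts", {
  q <- str_profile("Q", list(M1 = c("8", "10"), M2 = c("11", "12")))
  r <- str_profile("R", list(M1 = c("8", "11"), M2 = c("11", "12")))
  s <- score_pair(q, r, panel)
  expect_identical(s$n_shared, 3L)
  expect_identical(s$n_query, 4L)
  expect_identical(s$n_reference, 4L)
  expect_equal(s$tanabe, 75)
  expect_equal(s$masters_query, 75)
  expect_equal(s$masters_reference, 75)
})

test_that("identity and disjoint limits are exact", {
  p1 <- generate_profiles(1, seed = 5)[[1]]
  s <- score_pair(p1, p1, panel)
  expect_equal(s$tanabe, 100)
  expect_equal(s$masters_query, 100)
  expect_equal(s$masters_reference, 100)
  a <- str_profile("A", list(M1 = c("1", "2"), M2 = c("3", "4")))
  b <- str_profile("B", list(M1 = c("5", "6"), M2 = c("7", "8")))
  s2 <- score_pair(a, b, panel)
  expect_equal(s2$tanabe, 0)
  expect_equal(s2$masters_query, 0)
  expect_equal(s2$masters_reference, 0)
})

test_that("no shared markers yields undefined scores, not zero", {
  a <- str_profile("A", list(M1 = "1"))
  b <- str_profile("B", list(M2 = "1"))
  s <- score_pair(a, b, panel)
  expect_identical(s$n_markers_used, 0L)
  expect_true(is.na(s$tanabe))
  expect_true(is.na(s$masters_query))
  expect_true(is.na(s$masters_reference))
})

test_that("scoring matches the brute-force oracle on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    g1 <- random_genotypes()
    g2 <- random_genotypes()
    if (!any(lengths(g1) > 0L) || !any(lengths(g2) > 0L)) next
    q <- genotypes_to_profile("Q", g1)
    r <- genotypes_to_profile("R", g2)
    expect_score_matches_oracle(q, r, panel)
  }
})

test_that("penalized-denominator mode matches its oracle", {
  pen <- str_panel(penalize_missing = TRUE)
  set.seed(43)
  for (i in 1:100) {
    q <- genotypes_to_profile("Q", random_genotypes())
    r <- genotypes_to_profile("R", random_genotypes())
    expect_score_matches_oracle(q, r, pen)
  }
  # a marker typed only in the query depresses its Masters (vs query) score
  q <- str_profile("Q", list(M1 = c("8", "10"), M2 = c("5", "6")))
  r <- str_profile("R", list(M1 = c("8", "10")))
  expect_equal(score_pair(q, r, panel)$masters_query, 100)
  expect_equal(score_pair(q, r, pen)$masters_query, 50)
})

test_that("symmetry, duality, and the harmonic-mean identity hold", {
  set.seed(99)
  checked <- 0L
  for (i in 1:300) {
    q <- genotypes_to_profile("Q", random_genotypes())
    r <- genotypes_to_profile("R", random_genotypes())
    qr <- score_pair(q, r, panel)
    rq <- score_pair(r, q, panel)
    expect_equal(qr$tanabe, rq$tanabe)
    expect_equal(qr$masters_query, rq$masters_reference)
    expect_equal(qr$masters_reference, rq$masters_query)
    if (!is.na(qr$masters_query) && qr$masters_query > 0 &&
        qr$masters_reference > 0) {
      mq <- qr$masters_query / 100
      mr <- qr$masters_reference / 100
      expect_equal(qr$tanabe / 100, 2 * mq * mr / (mq + mr),
                   tolerance = 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("scores are monotone in shared and unshared alleles", {
  set.seed(7)
  for (i in 1:50) {
    gq <- random_genotypes(markers = c("M1", "M2", "M3"))
    gr <- random_genotypes(markers = c("M1", "M2", "M3"))
    gq$M1 <- if (length(gq$M1)) gq$M1 else "6"
    gr$M1 <- if (length(gr$M1)) gr$M1 else "6"
    q <- genotypes_to_profile("Q", gq)
    r <- genotypes_to_profile("R", gr)
    before <- score_pair(q, r, panel)
    # add the same new allele to both profiles at a marker typed in both
    gq2 <- gq; gr2 <- gr
    gq2$M1 <- unique(c(gq2$M1, "99")); gr2$M1 <- unique(c(gr2$M1, "99"))
    after <- score_pair(genotypes_to_profile("Q", gq2),
                        genotypes_to_profile("R", gr2), panel)
    expect_gte(after$tanabe, before$tanabe)
    expect_gte(after$masters_query, before$masters_query)
    expect_gte(after$masters_reference, before$masters_reference)
    # an unshared allele in the query never raises Tanabe
    gq3 <- gq; gq3$M1 <- unique(c(gq3$M1, "98"))
    solo <- score_pair(genotypes_to_profile("Q", gq3), r, panel)
    expect_lte(solo$tanabe, before$tanabe)
  }
})

test_that("Masters (vs reference) is 100 exactly when the reference is contained", {
  set.seed(13)
  for (i in 1:50) {
    a <- genotypes_to_profile("A", random_genotypes())
    b <- genotypes_to_profile("B", random_genotypes())
    mixed <- mix_profiles(a, b, "MIX")
    s <- score_pair(mixed, a, panel)
    expect_equal(s$masters_reference, 100)
    # and conversely: a reference allele missing from the query breaks it
    sb <- score_pair(a, mixed, panel)
    contained <- all(vapply(marker_universe(a, mixed, panel), function(m)
      all(mixed$genotypes[[m]] %in% a$genotypes[[m]]), logical(1)))
    expect_identical(sb$masters_reference == 100, contained)
  }
})

test_that("the matrix engine reproduces per-pair scoring exactly", {
  for (pan in list(str_panel(), str_panel(include_amelogenin = TRUE),
                   str_panel(penalize_missing = TRUE))) {
    profs <- generate_profiles(8, seed = 21)
    sm <- strmatch:::score_matrix(unclass(profs), pan)
    for (i in 1:8) {
      for (j in 1:8) {
        s <- score_pair(profs[[i]], profs[[j]], pan)
        expect_equal(sm$tanabe[i, j], s$tanabe)
        expect_equal(sm$masters_query[i, j], s$masters_query)
        expect_equal(sm$masters_reference[i, j], s$masters_reference)
        expect_equal(sm$shared[i, j], s$n_shared)
      }
    }
  }
})
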