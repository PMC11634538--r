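#' Default marker panel and allele pools for synthetic profiles
#'
#' A PowerPlex 16-style panel: amelogenin plus fifteen autosomal loci, each
#' with an allele pool spanning the repeat-count range commonly observed in
#' human populations (including the familiar microvariants such as TH01
#' 9.3). Pools are uniform -- the generator is a deterministic test
#' substrate, not a simulator of human allele-frequency spectra.
#'
#' @return Named list: canonical marker name -> character vector of allele
#'   tokens.
#' @export
default_allele_pools <- function() {
  list(
    AMEL    = c("X", "Y"),
    CSF1PO  = as.character(7:15),
    D13S317 = as.character(7:15),
    D16S539 = as.character(5:15),
    D18S51  = c(as.character(9:26), "13.2", "14.2"),
    D21S11  = c(as.character(24:38), "28.2", "29.2", "30.2", "31.2",
                "32.2", "33.2"),
    D3S1358 = as.character(12:19),
    D5S818  = as.character(7:16),
    D7S820  = as.character(6:14),
    D8S1179 = as.character(8:18),
    FGA     = c(as.character(17:30), "26.2"),
    PentaD  = as.character(2:17),
    PentaE  = as.character(5:24),
    TH01    = c(as.character(4:11), "9.3"),
    TPOX    = as.character(6:13),
    vWA     = as.character(11:21)
  )
}

# deterministic per-sample substream: reproducible regardless of the order
# in which samples are generated
sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483647)
}

#' Generate a seeded collection of synthetic STR profiles
#'
#' Each sample draws `ploidy` alleles per marker uniformly with replacement
#' from that marker's pool, then collapses to the distinct-allele set (so a
#' locus drawing the same allele twice is homozygous and stores one allele).
#' One integer seed fully determines the collection; each sample uses a
#' substream derived from (seed, sample index), so sample `i` is the same
#' whatever else is generated around it.
#'
#' @param n_samples Number of profiles.
#' @param markers Marker names (default: names of
#'   [default_allele_pools()]).
#' @param allele_pools Named list marker -> allele token pool; defaults to
#'   [default_allele_pools()] (markers missing from the list fall back to a
#'   generic `5:20` repeat range).
#' @param ploidy Alleles drawn per locus before set collapse (default 2).
#' @param seed Integer seed.
#' @param prefix Sample id prefix (ids are `"<prefix>001"`, ...).
#' @return An `str_collection` of `n_samples` profiles.
#' @examples
#' profs <- generate_profiles(n_samples = 3, seed = 7)
#' profs[["S001"]]
#' @export
generate_profiles <- function(n_samples, markers = NULL,
                              allele_pools = default_allele_pools(),
                              ploidy = 2L, seed = 1L, prefix = "S") {
  stopifnot(n_samples >= 1L, ploidy >= 1L)
  if (is.null(markers)) markers <- names(allele_pools)
  if (length(markers) == 0L) {
    stop("marker panel is empty", call. = FALSE)
  }
  pools <- lapply(markers, function(m) {
    p <- allele_pools[[m]]
    if (is.null(p) || !length(p)) as.character(5:20) else as.character(p)
  })
  names(pools) <- markers
  profiles <- lapply(seq_len(n_samples), function(i) {
    set.seed(sample_seed(seed, i))
    g <- lapply(pools, function(pool)
      sample(pool, ploidy, replace = TRUE))
    str_profile(sprintf("%s%03d", prefix, i), g)
  })
  str_collection(profiles)
}

#' Perturb a profile with allelic drop-out and repeat drift
#'
#' Emulates the two common modes of intra-model STR variation seen during
#' culture and PDX passaging: allelic drop-out (loss of heterozygosity
#' removes one allele of a heterozygous pair) and genetic drift (an allele
#' gains or loses one repeat unit, keeping any microvariant suffix, so
#' "13.3" drifts to "12.3" or "14.3"). Each locus is perturbed
#' independently; letter alleles (amelogenin) never drift.
#'
#' @param profile An `str_profile`.
#' @param drop_rate Per-locus probability of dropping one allele of a
#'   heterozygous pair, in `[0, 1]`.
#' @param drift_rate Per-locus probability of shifting one allele by one
#'   repeat, in `[0, 1]`.
#' @param seed Integer seed; the perturbation is deterministic given
#'   (profile, rates, seed).
#' @param new_id Sample id of the perturbed profile (default: original id
#'   with a `"_v"` suffix).
#' @return A new `str_profile`.
#' @export
perturb_profile <- function(profile, drop_rate = 0, drift_rate = 0,
                            seed = 1L, new_id = NULL) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, drift_rate >= 0,
            drift_rate <= 1)
  set.seed(as.integer(seed))
  g <- profile$genotypes
  for (m in names(g)) {
    al <- g[[m]]
    if (length(al) >= 2L && stats::runif(1) < drop_rate) {
      al <- al[-sample.int(length(al), 1L)]
    }
    if (length(al) >= 1L && stats::runif(1) < drift_rate) {
      idx <- sample.int(length(al), 1L)
      shifted <- drift_allele(al[idx])
      if (!is.na(shifted)) {
        al <- sort_alleles(unique(c(al[-idx], shifted)))
      }
    }
    g[[m]] <- al
  }
  str_profile(new_id %||% paste0(profile$sample_id, "_v"), g,
              profile$metadata)
}

# shift a numeric allele token by +-1 repeat, preserving any microvariant
# suffix; NA for letter tokens
drift_allele <- function(token) {
  if (!grepl("^[0-9]", token)) return(NA_character_)
  whole <- as.integer(sub("\\..*$", "", token))
  frac <- if (grepl("\\.", token)) sub("^[0-9]+", "", token) else ""
  step <- if (whole <= 1L) 1L else sample(c(-1L, 1L), 1L)
  paste0(whole + step, frac)
}

#' Mix two profiles into one
#'
#' Models unintentional sample mixing: the mixture carries, at every marker
#' typed in either input, the union of the two allele sets. By construction
#' every allele of either component appears in the mixture, so the Masters
#' (vs reference) score of the mixture against each component is 100 -- the
#' property that makes the Masters scores diagnostic for contamination.
#'
#' @param a,b `str_profile` objects.
#' @param new_id Sample id for the mixture.
#' @return An `str_profile`.
#' @examples
#' profs <- generate_profiles(2, seed = 3)
#' m <- mix_profiles(profs[[1]], profs[[2]], "MIX")
#' score_pair(m, profs[[1]])$masters_reference  # 100
#' @export
mix_profiles <- function(a, b, new_id) {
  markers <- union(names(a$genotypes), names(b$genotypes))
  g <- lapply(markers, function(m)
    sort_alleles(union(a$genotypes[[m]] %||% character(0),
                       b$genotypes[[m]] %||% character(0))))
  names(g) <- markers
  str_profile(new_id, g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
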