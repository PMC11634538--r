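---
title: "strmatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strmatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strmatch)
```

## The problem

Human cell lines and PDX models drift, get mislabeled, and get
cross-contaminated. The accepted identity evidence is an STR profile: for
each of a kit's loci (CSF1PO, vWA, TH01, ...), the set of observed alleles,
each named by its repeat count. Authentication means comparing a test
profile against reference profiles — one's own historical profiles, a
consortium database, or the published lines in Cellosaurus — and judging
whether the similarity is consistent with "same individual".

`strmatch` operationalizes that comparison at batch scale: every profile
against every other (or against a database), three similarity scores per
ordered pair, threshold-filtered match lists, a per-profile mixing flag,
and deterministic report files suitable for audit trails.

## The model

A profile is a map from canonical marker names to *sets* of allele tokens.
Two alleles are the same iff their canonical strings are equal; alleles at
different markers never match. For query $Q$ and reference $R$, with
$\mathcal{M}$ the set of markers typed (non-empty) in *both* profiles and
amelogenin excluded by default:

$$s = \sum_{m \in \mathcal{M}} |Q_m \cap R_m|, \qquad
  q = \sum_{m \in \mathcal{M}} |Q_m|, \qquad
  r = \sum_{m \in \mathcal{M}} |R_m|$$

$$\mathrm{Tanabe} = 100\,\frac{2s}{q+r},\qquad
  \mathrm{Masters}_{q} = 100\,\frac{s}{q},\qquad
  \mathrm{Masters}_{r} = 100\,\frac{s}{r}.$$

Three algebraic consequences matter in practice, and the test suite asserts
all of them on randomized profile pairs:

* **Symmetry**: Tanabe$(Q,R)$ = Tanabe$(R,Q)$.
* **Duality**: Masters$_q(Q,R)$ = Masters$_r(R,Q)$ — the batch engine
  computes each unordered pair once and derives the reverse direction.
* **Harmonic mean**: Tanabe is the harmonic mean of the two Masters
  fractions, which is why it is a good symmetric summary and why the
  asymmetric scores carry extra information: a mixture $M = A \cup B$
  satisfies Masters$_r(M, A) = 100$ exactly, while its Tanabe score
  against $A$ is deflated by the alleles contributed by $B$.

### Assumptions

* **Distinct-allele (set) counting.** A homozygous locus contributes one
  allele to its profile's count ("10,10" stores `{10}`). Labs disagree on
  this; the set convention matches how distinct alleles are compared in the
  CLASTR ecosystem and makes the formulas well-defined under the storage
  model. It is applied uniformly to both profiles of a pair, so identical
  profiles always score 100 regardless of zygosity.
* **Common-marker denominators.** Only markers typed in both profiles enter
  $q$ and $r$. The alternative — counting each profile's full panel, so
  that a locus typed in only one profile depresses the score — is exposed
  as `str_panel(penalize_missing = TRUE)`, because a profile typed at more
  loci should not be penalized for panel width by default, only for
  genotype mismatch.
* **Amelogenin excluded** from scores and from the mixing rule by default
  (`include_amelogenin` switches both): a shared sex marker inflates
  similarity without identity information, and X,Y males would interact
  badly with allele-count rules.
* **No population genetics.** The scores are set-overlap statistics, not
  match probabilities; no allele frequencies, no likelihood ratios.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `tanabe_min`, `masters_query_min`, `masters_reference_min` | 80 | % | the conventional match threshold for these scores in authentication practice |
| `mix_allele_min` | 3 | alleles/locus | two alleles is normal diploidy; a third implies a second contributor or instability |
| `mix_marker_min` | 3 | loci | a single busy locus is more often microsatellite instability than mixing |
| `include_amelogenin` | `FALSE` | — | see above |
| `penalize_missing` | `FALSE` | — | see above |

The mixing rule is deliberately per-profile (not per-pair): it asks whether
the profile *itself* looks like more than one genome, independent of what
it is compared against. Thresholds are validated on entry
(`resolve_config()` fails on out-of-range or unknown keys *before* any I/O,
because a silently-dropped typo in a threshold could change an
authentication decision).

## Mixing-flag boundary

`flag_mixing()` counts loci whose allele-set size is at least
`mix_allele_min` and fires when that count reaches `mix_marker_min`. The
truth table over (loci with $k$ alleles, $k$) for $k, \ell \in \{1..4\}$ is
asserted exhaustively in the tests: 3 loci × 3 alleles flags; 2 × 3 and
3 × 2 do not; 1 locus × 5 alleles does not (the rule counts loci, never the
allele total).

## Ranking, ties, and degenerate pairs

* Reports rank by descending **unrounded** Tanabe; ties break by descending
  Masters (vs query), then ascending reference id. The ordering is total,
  so outputs diff cleanly.
* Scores are kept at full double precision internally; report files print
  two decimals, but threshold tests always use unrounded values — otherwise
  a pair at 79.996 would print 80.00 yet be excluded, or vice versa.
* A pair sharing **no** typed markers has *undefined* scores (`NA`), is
  ranked after all defined scores, and is serialized with empty score cells
  plus an explicit `no shared markers` note. Reporting 0 would falsely
  suggest evidence of mismatch when there is simply no evidence.
* The summary's top match reports **all** ids tied at the best Tanabe
  score, joined with `"; "` — ties are real (e.g. duplicate references) and
  hiding one of them would be misleading.
* Self-comparisons are excluded everywhere.

## The batch engine

All-vs-all scoring is a set of dense matrix products over a profile ×
(marker, allele)-token incidence matrix: shared counts are $XX^\top$,
denominators come from per-marker allele counts against typed-marker
indicators, and the marker-universe sizes from the indicator product. This
reproduces `score_pair()` exactly for every ordered pair (asserted in the
tests against both the per-pair path and an independently written
brute-force double loop) while scaling comfortably: the test suite and the
acceptance script run a 1000-profile all-vs-all batch (≈500k unordered
pairs) as a routine case.

## Input handling

Two layouts are supported — wide (`Sample` + one column per marker,
multi-allele cells comma- or space-separated) and long
(`Sample, Marker, Allele`) — across CSV, TSV and XLSX. These two layouts
are this package's commitment for "flexible" profile tables; capillary
electrophoresis output and genotyper project files are out of scope.
Choices a reader might question:

* **Delimiter by extension, never sniffed** (`.csv` comma, `.tsv`/`.txt`
  tab): deterministic parsing beats convenience.
* **Fixed NA vocabulary** (`""`, `NA`, `N/A`, `-`, `--`, case-insensitive)
  means "locus not typed"; anything else non-conforming is a hard error
  naming the cell. Spreadsheet float artifacts (`12.0`) are normalized.
* **Marker aliases** ship as an editable CSV
  (`inst/extdata/marker_aliases.csv`) and can be overridden per run; kit
  vocabularies drift ("Penta_D", "PENTA D", "Penta D"). Unknown markers
  pass through case-folded with a warning — dropped data must never be
  silent.
* **Serialization order** for alleles (ascending numeric, microvariants by
  fractional value, letters last, X before Y) and for columns is fixed, so
  write→read is the identity on (sample, marker, allele-set) triples —
  asserted for all 2 layouts × 3 formats — and repeated runs are
  byte-identical.

XLSX output is produced by a minimal writer built into the package
(store-only ZIP container, inline-string SpreadsheetML, external hyperlink
relationships, fixed archive timestamps for reproducibility); its output is
round-trip verified against an independent XLSX reader in the tests.

## The CLASTR client

`build_clastr_payload()` maps canonical marker names onto the service's
vocabulary and serializes options and comma-joined alleles in a fixed field
order; `submit_clastr_query()` POSTs with a bounded retry (3 attempts,
exponential backoff, only on 429/503/connection failure — the query is
idempotent); `parse_clastr_response()` validates the schema loudly (missing
fields and malformed CVCL accessions are errors, not NAs) and returns
ranked hits with Cellosaurus hyperlinks, rendered one worksheet per query
by `write_clastr_excel()`. All tests run offline against a fixture file
that is *synthetic* — constructed to the public API's response schema, not
recorded from the live service — plus mocked HTTP responses for the retry
contract; nothing in the test suite or acceptance script touches the
network.

## What the synthetic data does and does not emulate

`generate_profiles()` draws, per locus, `ploidy` (default 2) alleles
uniformly with replacement from per-marker pools spanning realistic human
repeat ranges (including microvariants such as TH01 9.3), then collapses to
sets; one integer seed fully determines a collection, with per-sample
substreams derived from (seed, sample index) so a sample is reproducible
independent of batch size. `perturb_profile()` models the two documented
modes of intra-model variation — allelic drop-out (loss of heterozygosity)
and ±1-repeat drift — and `mix_profiles()` models contamination as the
per-marker union.

Deliberately **not** modeled: population allele-frequency spectra and
linkage (pools are uniform), kit-specific artifacts (stutter, null
alleles), partial-degradation patterns, and mixture stoichiometry (a union
has no minor-contributor dropout). Consequently, passing tests demonstrate
that the scoring, flagging and reporting machinery is correct on its
defined inputs — they do not measure real-world sensitivity/specificity of
the 80% threshold, which depends on population genetics this generator does
not attempt.

Test problem sizes, chosen as representative rather than exhaustive: 1000
random pairs for oracle agreement and algebraic laws, 100 (A, B, mixture)
triples for contamination recovery, a 25-profile batch for the report
contract, and 1000 profiles for the all-vs-all throughput case.

## Known limitations

* String-equal allele identity means a lab reporting `"13.0"` where another
  reports `"13"` must rely on normalization (which handles exactly this
  case), but no fuzzy matching beyond it exists by design.
* The mixing flag is a heuristic; microsatellite-unstable models can
  trigger it without contamination, and a low-level contaminant below the
  calling threshold will not.
* CLASTR access depends on the remote service's schema; the parser pins the
  recorded schema and fails loudly on drift rather than guessing.
* No probabilistic match statistics; scores should be interpreted with the
  conventional thresholds, not as probabilities.
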