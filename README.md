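# strmatch

Batch comparison of short tandem repeat (STR) genotype profiles for
authenticating human cell lines and patient-derived xenograft (PDX) models.

STR profiling is the standard evidence that a cultured model still is what
its label says. Misidentified and cross-contaminated lines are a documented,
persistent problem, and journals increasingly require authentication — yet
comparing every new profile against every reference profile by hand is slow
and error-prone. `strmatch` is for the labs and repositories that generate
and maintain their own models: it scores thousands of profile pairs in
seconds, flags likely sample mixing, writes ranked audit-friendly reports,
and can query the Cellosaurus CLASTR service for matches against published
cell lines.

## The scores

A profile is, per typed marker (locus), a set of distinct alleles named by
repeat count (`"12"`, microvariant `"13.3"`; amelogenin `X`/`Y`). For a
query *Q* and reference *R*, let *s* be the number of shared alleles summed
over the markers typed in both profiles, and *q*, *r* each profile's allele
count over those markers. `strmatch` reports three similarity percentages:

- **Tanabe** (the Sørensen–Dice coefficient): `100 · 2s / (q + r)` —
  symmetric, the default ranking score;
- **Masters (vs query)**: `100 · s / q`;
- **Masters (vs reference)**: `100 · s / r`.

The two Masters scores are asymmetric and diagnostic for contamination: a
mixed sample contains every allele of each contributor, so it scores 100
against each of them as reference. Amelogenin is excluded from scoring by
default. The default match threshold is 80% for all three algorithms, and a
profile with **three or more alleles at three or more loci** is flagged as
potentially mixed.

## Worked example

```r
library(strmatch)

profs  <- generate_profiles(4, seed = 7)                    # synthetic panel
mixed  <- mix_profiles(profs[["S001"]], profs[["S002"]], "MIX")
res    <- compare_many_to_many(c(unclass(profs), list(mixed)))

score_pair(mixed, profs[["S001"]])
#>   query_id reference_id n_shared n_query n_reference n_markers_used tanabe
#> 1 MIX      S001               27      52          27             15   68.4
#>   masters_query masters_reference
#>            51.9               100

res$summary[, c("sample_id", "mixing_flagged", "top_match_id",
                "top_match_tanabe", "masters_reference_matches")]
#>   sample_id mixing_flagged top_match_id top_match_tanabe masters_reference_matches
#> 1 S001      FALSE          MIX                      68.4 ""
#> 2 S002      FALSE          MIX                      73.2 ""
#> 3 S003      FALSE          MIX                      20   ""
#> 4 S004      FALSE          MIX                      14.8 ""
#> 5 MIX       TRUE           S002                     73.2 "S001 (100.00); S002 (100.00)"
```

Reading the output: `MIX` carries all 27 of S001's alleles
(`masters_reference = 100`) but only half of its own 52 alleles come from
S001 (`masters_query = 51.9`), the signature of a two-source mixture; the
mixing flag fires because many loci now show three or more alleles; and its
Masters-(vs reference) threshold list names both contributors at 100. The
symmetric Tanabe score alone (68.4, below the 80% threshold) would have
missed the relationship — which is exactly why the asymmetric scores exist.

`write_summary_report()` and `write_sample_reports()` serialize these
results (CSV/TSV/XLSX) deterministically; `read_profiles()` /
`write_profiles()` handle wide and long tables. The same workflow is
available from a shell:

```sh
strmatch synth   --n 100 --seed 7 --out profiles.csv
strmatch compare --input profiles.csv --layout wide --out results/
strmatch clastr  --input profiles.csv --out clastr_hits.xlsx   # needs network
```

(The script installs under the package's `exec/` directory; call it via
`Rscript $(Rscript -e 'cat(system.file("exec","strmatch",package="strmatch"))')`
or put that path on your `PATH`.)

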