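# strmatch run configuration template.
# Copy, edit, and pass with --config. Flags override file values; file
# values override these defaults. Unknown keys are fatal.

# Minimum score (percent, 0-100) for a comparison to be listed as a match.
tan_threshold: 80
masters_q_threshold: 80
masters_r_threshold: 80

# Mixing flag: a profile with >= mix_allele_min alleles at
# >= mix_marker_min loci is flagged as potentially mixed.
mix_allele_min: 3
mix_marker_min: 3

# Count amelogenin (sex marker) in scores and mixing? Convention: no.
score_amelogenin: false

# If true, score denominators count each profile's alleles over all its
# typed markers, so loci typed in only one profile depress the score.
# Default scores over the markers typed in both profiles.
penalize_missing: false

# Input table layout: wide (Sample + one column per marker) or
# long (Sample, Marker, Allele columns).
layout: wide

# Report format: csv, tsv or xlsx.
fmt: csv
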