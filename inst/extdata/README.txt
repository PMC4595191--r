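Fixture data (all synthetic or transcribed aggregate counts; no raw field
data were deposited with the study):

site55_mating_table.csv
  The published 2x2 mating-pair counts and single-female counts from the
  sympatric site where the two species were approximately equi-abundant
  (40 AvM-AvF, 4 AvM-AhF, 9 AhM-AvF, 20 AhM-AhF; 9 + 8 single females).
  Population totals were not published, so PTI is unavailable from this
  table.

site55_observations.csv
  SYNTHETIC reconstruction of per-tick observation rows consistent with
  the counts above (female rows reproduce the printed pair/single counts
  exactly; male counts, animal assignment, body regions and clusters are
  invented). Suitable for exercising build_mating_table(), not for
  attachment-site or co-occurrence inference.

coinfestation_observations.csv
  SYNTHETIC reconstruction of the published male co-infestation pattern
  across the five sympatric sites: 61 cattle, of which 36 hosted males of
  both species, 21 only A. variegatum males, 4 only A. hebraeum males.

example_config.yaml
  Example CLI configuration.
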