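seed: 123
output_dir: tickri_out
simulate:
  n_sites: 1
  animals_per_site: 60
summarize:
  observations: tickri_out/observations.csv
  animals: tickri_out/animals.csv
  apply_eligibility: true
overlap:
  observations: tickri_out/observations.csv
cooccur:
  observations: tickri_out/observations.csv
  level: cluster
  nperm: 5000
  null: fixed_fixed
  pairs: all
isolation:
  mating_table: site55_mating_table.csv
  n_bootstrap: 10000
mating_fit:
  observations: tickri_out/observations.csv
detection:
  sites: sites.csv
  prevalence: 0.2
  se_laid: 1.0
  se_corridor: 0.6
  threshold: 0.7
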