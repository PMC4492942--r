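# Drop-in location for the published study's raw data

The paper-number reproduction checks and `scripts/acceptance.R` look here
for the Sardinian white-poplar MSAP supplementary tables, converted from
their published XLSX form to the CSV formats this package reads:

- `s3_msp.csv` — EcoRI-MspI binary band matrix (header = locus ids, first
  column = sample ids)
- `s4_hpa.csv` — EcoRI-HpaII binary band matrix (same layout, same sample
  and locus ids)
- `s1_popmap.csv` — columns `sample,population[,lat,lon,genotype]`

These files are not distributed with the package; without them the
reproduction checks fail and the rest of the pipeline runs on synthetic
data only.
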