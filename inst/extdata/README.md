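# Bundled fixtures

- `lucerne_key.yaml` — the published dichotomous identification key to the
  contemporary whitefish species of Lake Lucerne, as a machine-readable
  couplet list.
- `table13_gillrakers.tsv` — published frequency-of-occurrence rows for
  total gill-raker counts (species with internally consistent printed
  rows only).
- `table12_lateral_line.tsv` — published frequency-of-occurrence rows for
  lateral-line scale counts.
- `holotype_percentages.csv` — printed holotype values (SL and HL in mm,
  other characters as printed percentages of SL or HL) for two described
  species. The `totalGR` column is NOT an individual holotype count (which
  is not printed per specimen): it is the species' modal gill-raker class,
  included so that key traversal examples can be run end to end.
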