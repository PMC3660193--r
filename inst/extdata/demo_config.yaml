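# Demo pipeline configuration: three 120 cM linkage groups, a strongly
# semi-lethal viability locus on LG02 exposed by selfing, and a local
# recombination coldspot (0.25x) on LG03. Sample sizes follow a typical
# SNP-array full-sib study.
seed: 1
map:
  n_lg: 3
  length_cM: 120
  spacing_cM: 4
viability:
  lg: LG02
  pos_cM: 60
  fitness:
    "11": 1.0
    "12": 1.0
    "22": 0.1
modifiers:
  - lg: LG03
    start: 40
    end: 60
    multiplier: 0.25
f2:
  n_offspring: 69
  n_validation: 380
cp:
  n_offspring: 83
noise:
  error_rate: 0.0017
  missing_rate: 0.02
analysis:
  alpha: 0.01
  lod_min: 3
  min_cluster: 3
  max_gap_cM: 10
  coverage_X: 30
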