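# Default multiplex PCR-RFLP assay definition.
# Apparent sizes in bp on a 3500xL-Dx with POP7 / GS-600 LIZ sizing;
# dye channel colours: PET=red, 6-FAM=blue, VIC=green, NED=black.
fragments:
  - {locus: F5, allele: wt, size: 92, dye: red, must_be_absent_after_digestion: false}
  - {locus: F5, allele: variant, size: 129, dye: red, must_be_absent_after_digestion: false}
  - {locus: F5, allele: uncut, size: 289, dye: red, must_be_absent_after_digestion: true}
  - {locus: F2, allele: variant, size: 226, dye: red, must_be_absent_after_digestion: false}
  - {locus: F2, allele: wt, size: 246, dye: red, must_be_absent_after_digestion: false}
  - {locus: HIND_CTRL, allele: control_cut, size: 276, dye: black, must_be_absent_after_digestion: false}
  - {locus: HIND_CTRL, allele: control_uncut, size: 339, dye: black, must_be_absent_after_digestion: true}
str_loci:
  - {locus: FGA, dye: green, repeat_unit: 4, min_repeats: "14", max_repeats: "50.2", size_at_min_repeats: 92}
  - {locus: SE33, dye: blue, repeat_unit: 4, min_repeats: "4.2", max_repeats: "39", size_at_min_repeats: 279}
thresholds:
  allele_call_rfu: 150
  noise_ceiling_rfu: 50
  saturation_rfu: 32000
  stutter_max_fraction: 0.11
  het_ratio_min_f5: 0.49
  het_ratio_min_f2: 0.49
  size_match_tol: 1.0
  str_bin_tol: 0.5
  str_second_allele_min: 0.5
  stutter_k: 2
dyes:
  PET: red
  6-FAM: blue
  VIC: green
  NED: black
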