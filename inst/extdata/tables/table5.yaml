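# SNP peak intensity ratios, assay 067721-477, fully vs semi-ejected
# ascospores; arrows relative to fully ejected ascospores.
name: table5
assay: "067721-477"
reference_sample: ascospore_full
cells:
  - {sample: ascospore_full, numerator: G, denominator: A, decimals: 1,
     printed_ratio: 2.5, printed_num: 7.5, printed_den: 3.0}
  # the printed inputs (6.7 / 3.2 = 2.09) disagree with the printed
  # ratio 2.2; the same sample's G:T row prints G = 6.9, and
  # 6.9 / 3.2 = 2.16 does round to 2.2, so the peak fixture carries
  # G = 6.9. Documented input inconsistency of the source table.
  - {sample: ascospore_semi, numerator: G, denominator: A, decimals: 1,
     printed_ratio: 2.2, printed_num: 6.7, printed_den: 3.2,
     printed_arrow: "↔", known_mismatch: ratio_inputs}
  - {sample: ascospore_full, numerator: G, denominator: C, decimals: 1}
  - {sample: ascospore_semi, numerator: G, denominator: C, decimals: 1}
  - {sample: ascospore_full, numerator: G, denominator: T, decimals: 1,
     printed_ratio: 15.0, printed_num: 7.5, printed_den: 0.5}
  - {sample: ascospore_semi, numerator: G, denominator: T, decimals: 1,
     printed_ratio: 13.8, printed_num: 6.9, printed_den: 0.5,
     printed_arrow: "↔"}
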