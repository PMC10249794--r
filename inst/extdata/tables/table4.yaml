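# SNP peak intensity ratios, assay 067744-324, SFPs; arrows relative to
# the pre-ejection SFP.
name: table4
assay: "067744-324"
reference_sample: SFP_pre
cells:
  - {sample: SFP_pre, numerator: C, denominator: T, decimals: 2,
     printed_ratio: 0.71, printed_num: 41, printed_den: 58}
  - {sample: SFP_post, numerator: C, denominator: T, decimals: 1,
     printed_ratio: 10.6, printed_num: 53, printed_den: 5.0,
     printed_arrow: "↑↑↑↑"}
  - {sample: SFP_failure, numerator: C, denominator: T, decimals: 1,
     printed_ratio: 15.1, printed_num: 68, printed_den: 4.5,
     printed_arrow: "↑↑↑↑"}
  - {sample: SFP_pre, numerator: C, denominator: G, decimals: 1}
  - {sample: SFP_post, numerator: C, denominator: G, decimals: 1,
     printed_ratio: 53.0, printed_num: 53, printed_den: 1.0}
  - {sample: SFP_failure, numerator: C, denominator: G, decimals: 1}
  - {sample: SFP_pre, numerator: C, denominator: A, decimals: 2,
     printed_ratio: 4.56, printed_num: 41, printed_den: 9.0}
  - {sample: SFP_post, numerator: C, denominator: A, decimals: 2,
     printed_ratio: 7.57, printed_num: 53, printed_den: 7.0,
     printed_arrow: "↑"}
  - {sample: SFP_failure, numerator: C, denominator: A, decimals: 2,
     printed_ratio: 8.50, printed_num: 68, printed_den: 8.0,
     printed_arrow: "↑"}
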