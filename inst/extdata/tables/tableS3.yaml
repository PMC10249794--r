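# Supplementary ratios, assay 067721-531, SFPs. Input peak intensities
# were not published; ratio-only entries carried from the text.
name: tableS3
assay: "067721-531"
reference_sample: SFP_pre
ratio_only: true
cells:
  - {sample: SFP_pre, numerator: G, denominator: A, decimals: 2,
     printed_ratio: 1.06}
  - {sample: SFP_post, numerator: G, denominator: A, decimals: 1,
     printed_ratio: 19.3}
  - {sample: SFP_failure, numerator: G, denominator: A, decimals: 1,
     printed_ratio: 13.5}
  - {sample: SFP_pre, numerator: G, denominator: T, decimals: 1,
     printed_ratio: 12.7}
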