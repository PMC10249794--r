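# Supplementary ratios, assay 067740-328, SFPs. Input peak intensities
# were not published; ratio-only entries carried from the text.
name: tableS4
assay: "067740-328"
reference_sample: SFP_pre
ratio_only: true
cells:
  - {sample: SFP_pre, numerator: T, denominator: C, decimals: 1,
     printed_ratio: 14.1}
  - {sample: SFP_pre, numerator: T, denominator: A, decimals: 1,
     printed_ratio: 11.1}
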