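# Supplementary ratios, assay 067740-328, ascospores. Input peak
# intensities were not published; ratio-only entries from the text.
name: tableS6
assay: "067740-328"
reference_sample: ascospore_full
ratio_only: true
cells:
  - {sample: ascospore_full, numerator: T, denominator: A, decimals: 1,
     printed_ratio: 14.0}
  - {sample: ascospore_semi, numerator: T, denominator: A, decimals: 1,
     printed_ratio: 22.0}
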