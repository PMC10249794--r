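# Supplementary table, assay 067721-531, ascospores. The source reports
# "no meaningful change" in the G:A ratio without printing values, so
# this spec carries no numeric cells.
name: tableS5
assay: "067721-531"
reference_sample: ascospore_full
ratio_only: true
cells: []
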