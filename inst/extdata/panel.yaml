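# Two-step assay panel: first-step PCR primer pairs and single-base
# extension primers (sequences as published).
primer_pairs:
  - name: "Hsprp1/3"
    forward_name: Hsprp1
    forward_seq: ATTATCGAGTCACCACTCCCAAACCCCC
    reverse_name: Hsprp3
    reverse_seq: CGAGGTTCTCAGCGAGCTACT
    target_bias: GC_FAVORING
  - name: "Hsprp1/ITS4"
    forward_name: Hsprp1
    forward_seq: ATTATCGAGTCACCACTCCCAAACCCCC
    reverse_name: ITS4
    reverse_seq: TCCTCCGCTTATTGATATGC
    target_bias: GC_FAVORING
  - name: "P1/P2"
    forward_name: P1
    forward_seq: ACGCAGCGAAATACGATAAG
    reverse_name: P2
    reverse_seq: CATGCCCGCTAGAGTGCTA
    target_bias: AT_FAVORING
  - name: "P2/P1"
    forward_name: P1
    forward_seq: ACGCAGCGAAATACGATAAG
    reverse_name: P2
    reverse_seq: CATGCCCGCTAGAGTGCTA
    target_bias: AT_FAVORING
  - name: "P2/P4"
    forward_name: P4
    forward_seq: ACGCAGCGAAATGCAATAAG
    reverse_name: P2
    reverse_seq: CATGCCCGCTAGAGTGCTA
    target_bias: AT_FAVORING
extension_assays:
  - name: "067721-477"
    primer_seq: CGCCGCGGCTCCCCT
    reference_id: AB067721
    snp_position: 477
    orientation: SENSE
    feeding_pairs: ["Hsprp1/3", "Hsprp1/ITS4"]
  - name: "067721-531"
    primer_seq: AGGCGGTCACGCCGT
    reference_id: AB067721
    snp_position: 531
    orientation: SENSE
    feeding_pairs: ["Hsprp1/3", "Hsprp1/ITS4"]
  - name: "067740-324"
    primer_seq: GTAAACTATCGAATCTTTAAACG
    reference_id: AB067740
    snp_position: 324
    orientation: SENSE
    feeding_pairs: ["P1/P2", "P2/P1", "P2/P4"]
  - name: "067744-324"
    primer_seq: GCTAGCGGGCGTAGTAT
    reference_id: AB067744
    snp_position: 324
    orientation: REVERSE_COMPLEMENT
    feeding_pairs: ["P1/P2", "P2/P1", "P2/P4"]
  - name: "067740-328"
    primer_seq: GTGCTAGCGGGCGTA
    reference_id: AB067740
    snp_position: 328
    orientation: REVERSE_COMPLEMENT
    feeding_pairs: ["P1/P2", "P2/P1", "P2/P4"]
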