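# small in-code fixtures shared across tests

tiny_metadata <- function() {
  tibble::tibble(
    genotype_id = c("g1", "g2"),
    accession = c("REF001", "synthetic"),
    clade = c("GC", "AT_CLUSTER_A"))
}

tiny_fasta <- function() {
  c(g1 = "ACGTACGGCCGGAA", g2 = "ACGTATGGTCGGAA")
}

# a frozen registry + panel reused by panel/simulator tests
shared_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- generate_genotype_sequences(seed = 42L)
    reg
  }
})

shared_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- load_paper_panel()
    p
  }
})

peaks_tbl <- function(sample_label, assay_name, intensities,
                      statuses = NULL) {
  statuses <- statuses %||% ifelse(is.na(intensities), "MISSING", "CALLED")
  tibble::tibble(
    sample_label = sample_label, assay_name = assay_name,
    base = names(intensities), mass = NA_real_,
    intensity = unname(intensities), status = statuses)
}
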