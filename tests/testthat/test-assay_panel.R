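test_that("the packaged panel carries the published primer sequences", {
  p <- shared_panel()
  expect_equal(nrow(p$assays), 5)
  a477 <- p$assays[p$assays$name == "067721-477", ]
  expect_equal(a477$primer_seq, "CGCCGCGGCTCCCCT")
  expect_equal(a477$orientation, "SENSE")
  a744 <- p$assays[p$assays$name == "067744-324", ]
  expect_equal(a744$primer_seq, "GCTAGCGGGCGTAGTAT")
  expect_equal(a744$orientation, "REVERSE_COMPLEMENT")
  expect_equal(p$assays$orientation[p$assays$name == "067740-328"],
               "REVERSE_COMPLEMENT")
  expect_equal(p$assays$orientation[p$assays$name == "067740-324"],
               "SENSE")
  p4 <- p$pairs[p$pairs$name == "P2/P4", ]
  expect_equal(p4$forward_seq, "ACGCAGCGAAATGCAATAAG")
  expect_setequal(p$pairs$target_bias[grepl("Hsprp", p$pairs$name)],
                  "GC_FAVORING")
  expect_setequal(p$pairs$target_bias[grepl("^P", p$pairs$name)],
                  "AT_FAVORING")
  # snp_position parses from the assay name
  expect_equal(p$assays$snp_position,
               as.integer(sub(".*-", "", p$assays$name)))
})

test_that("allele prediction reports sense-strand bases and NONE for
           absent sites", {
  reg <- shared_registry()
  p <- shared_panel()
  pred <- function(g, a) {
    predict_extension_allele(get_genotype(reg, g), get_assay_row(p, a))
  }
  get_assay_row <- function(p, a) p$assays[p$assays$name == a, ]
  expect_equal(pred("#1", "067721-477")$allele, "G")
  expect_equal(pred("#5", "067721-477")$allele, "A")
  expect_equal(pred("#5", "067744-324")$allele, "C")
  expect_equal(pred("#4", "067740-328")$allele, "C")
  expect_equal(pred("#6", "067740-328")$allele, "T")
  # extension primers designed on AT-biased sequences do not match the
  # GC-clade stand-ins
  expect_equal(pred("#1", "067740-324")$allele, "NONE")
  expect_equal(pred("#2", "067744-324")$allele, "NONE")
})

test_that("sense-strand reporting is invariant to flipping the
           genotype strand together with assay orientation", {
  reg <- shared_registry()
  p <- shared_panel()
  complement_base_public <- function(b) {
    c(A = "T", C = "G", G = "C", T = "A")[[b]]
  }
  for (an in c("067721-477", "067740-328")) {
    a <- p$assays[p$assays$name == an, ]
    g <- get_genotype(reg, "#5")
    fwd <- predict_extension_allele(g, a)$allele
    g_rc <- g
    g_rc$sequence <- revcomp(g$sequence)
    a_flip <- a
    a_flip$orientation <- setdiff(c("SENSE", "REVERSE_COMPLEMENT"),
                                  a$orientation)
    rev_allele <- predict_extension_allele(g_rc, a_flip)$allele
    # the flipped read reports the same molecule; its sense strand is
    # the original one, so the reported base is the complement of the
    # base read on the flipped coordinate system
    expect_equal(complement_base_public(rev_allele), fwd, label = an)
  }
})

test_that("allele-to-genotype maps match the published sets and
           partition the constrained registry", {
  reg <- shared_registry()
  p <- shared_panel()
  sfp <- c("#1", "#4", "#5", "#6", "#15")
  asco <- c("#1", "#5", "#6", "#16")
  a328 <- p$assays[p$assays$name == "067740-328", ]
  m <- allele_to_genotype_map(a328, reg, sfp)
  expect_setequal(m$C, "#4")
  expect_setequal(m$T, c("#5", "#6", "#15"))
  a324 <- p$assays[p$assays$name == "067740-324", ]
  m2 <- allele_to_genotype_map(a324, reg, asco)
  expect_setequal(m2$C, "#5")
  expect_setequal(m2$T, c("#6", "#16"))
  a477 <- p$assays[p$assays$name == "067721-477", ]
  m3 <- allele_to_genotype_map(a477, reg, sfp)
  expect_setequal(m3$G, "#1")
  expect_setequal(m3$A, c("#4", "#5", "#6", "#15"))
  # single-genotype constraint: every other base maps to the empty set
  m4 <- allele_to_genotype_map(a477, reg, "#1")
  expect_equal(lengths(m4), c(A = 0L, C = 0L, G = 1L, T = 0L))
  # partition: no genotype under two bases
  all_ids <- unlist(m)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, setdiff(sfp, "#1"))  # #1 site-absent here
  expect_error(allele_to_genotype_map(a477, reg, "nope"), "empty")
})

test_that("extension product masses follow the residue-mass table", {
  # 15-mer mass frozen from the elemental-composition oracle
  expect_equal(oracle_oligo_mass("CGCCGCGGCTCCCCT"), 4465.918,
               tolerance = 1e-4)
  expect_equal(oligo_mass("CGCCGCGGCTCCCCT"), 4465.90, tolerance = 0.05)
  expect_equal(oligo_mass("CGCCGCGGCTCCCCT"),
               oracle_oligo_mass("CGCCGCGGCTCCCCT"), tolerance = 0.05)
  # additivity: allelic mass differences equal terminator differences
  d <- extension_product_mass("CGCCGCGGCTCCCCT", "G") -
    extension_product_mass("CGCCGCGGCTCCCCT", "A")
  expect_equal(d, dd_residue_mass("G") - dd_residue_mass("A"))
  # terminator residue ordering ddC < ddT < ddA < ddG
  dd <- vapply(c("C", "T", "A", "G"), dd_residue_mass, numeric(1))
  expect_true(all(diff(dd) > 0))
  p <- shared_panel()
  for (i in seq_len(nrow(p$assays))) {
    masses <- assay_product_masses(p$assays[i, ])
    expect_true(all(masses > oligo_mass(p$assays$primer_seq[i])))
    expect_gte(min(diff(sort(masses))), 9)  # smallest ddNTP gap (A vs T)
  }
  expect_error(oligo_mass("ACGR"), "degenerate")
})
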