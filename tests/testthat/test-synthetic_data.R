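test_that("sequence generation is byte-identical under a fixed seed", {
  r1 <- generate_genotype_sequences(seed = 9)
  r2 <- generate_genotype_sequences(seed = 9)
  expect_identical(r1$sequence, r2$sequence)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  md <- withr::local_tempfile(fileext = ".tsv")
  write_registry(r1, fa1, md)
  write_registry(r2, fa2, md)
  expect_identical(readBin(fa1, "raw", file.size(fa1)),
                   readBin(fa2, "raw", file.size(fa2)))
  r3 <- generate_genotype_sequences(seed = 10)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("generated stand-ins carry the planted per-assay alleles", {
  reg <- shared_registry()
  p <- shared_panel()
  alleles <- predict_panel_alleles(reg, p)
  want <- function(g, a) alleles$allele[alleles$genotype_id == g &
                                          alleles$assay_name == a]
  expect_equal(want("#5", "067744-324"), "C")
  expect_equal(want("#4", "067740-328"), "C")
  for (g in c("#5", "#6", "#15")) {
    expect_equal(want(g, "067740-328"), "T", label = g)
  }
  # GC/AT separation at the GC-marker assays
  for (a in c("067721-477", "067721-531")) {
    expect_equal(want("#1", a), "G")
    for (g in c("#4", "#5", "#6", "#15", "#16", "#17")) {
      expect_equal(want(g, a), "A", label = paste(g, a))
    }
  }
  # unknown-flank transversion stand-ins answer only their own assay
  expect_equal(want("U_477_C", "067721-477"), "C")
  expect_equal(want("U_477_C", "067721-531"), "NONE")
  expect_equal(want("U_740328_A", "067740-328"), "A")
  # the #4 stand-in's own coordinate of its assay site is 324
  a744 <- p$assays[p$assays$name == "067744-324", ]
  expect_equal(locate_assay_site(get_genotype(reg, "#4")$sequence, a744),
               324L)
})

test_that("first-step PCR pool follows abundance x gain, renormalized", {
  mix <- mixture_spec("s", c(a = 0.5, b = 0.5))
  bias_even <- tibble::tibble(pair_name = "P", genotype_id = c("a", "b"),
                              gain = c(1, 1))
  expect_equal(simulate_first_pcr(mix, "P", bias_even),
               c(a = 0.5, b = 0.5))
  bias_4to1 <- tibble::tibble(pair_name = "P", genotype_id = c("a", "b"),
                              gain = c(4, 1))
  expect_equal(simulate_first_pcr(mix, "P", bias_4to1),
               c(a = 0.8, b = 0.2))
  bias_zero <- tibble::tibble(pair_name = "P", genotype_id = c("a", "b"),
                              gain = c(0, 0))
  expect_error(simulate_first_pcr(mix, "P", bias_zero), "no amplifiable")
  expect_error(simulate_first_pcr(mix, "P", bias_even[1, ]),
               "no bias entry")
  # paper-faithful preset favors the GC clade under GC-favoring pairs
  reg <- shared_registry()
  p <- shared_panel()
  bias <- paper_bias_preset(p, reg)
  mix2 <- mixture_spec("s", c("#1" = 0.5, "#5" = 0.5))
  pool <- simulate_first_pcr(mix2, "Hsprp1/3", bias)
  expect_gt(pool[["#1"]], pool[["#5"]])
  pool_at <- simulate_first_pcr(mix2, "P1/P2", bias)
  expect_gt(pool_at[["#5"]], pool_at[["#1"]])
  expect_equal(sum(pool), 1)
  expect_equal(sum(pool_at), 1)
})

test_that("noiseless spectra reproduce the truth peaks exactly", {
  reg <- shared_registry()
  p <- shared_panel()
  a <- p$assays[p$assays$name == "067721-477", ]
  pool <- c("#1" = 1)
  sp <- simulate_extension_spectrum(pool, a, reg,
                                    noise_params(baseline_sd = 0))
  expect_s3_class(sp, "sim_spectrum")
  expect_true(all(sp$intensity >= 0))
  expect_equal(unname(sp$truth["G"]), 10)
  expect_equal(unname(sp$truth[c("A", "C", "T")]), rep(0, 3))
  # raw grid apex equals the truth within grid-resolution tolerance
  apex <- max(sp$intensity)
  expect_equal(apex, 10, tolerance = 1e-4)
  # truth G:A ratio for a two-component pool
  pool2 <- c("#1" = 0.84, "#5" = 0.16)
  sp2 <- simulate_extension_spectrum(pool2, a, reg,
                                     noise_params(baseline_sd = 0))
  expect_equal(unname(sp2$truth["G"] / sp2$truth["A"]), 5.25)
})

test_that("seeded spectra are reproducible and flag merged peaks", {
  reg <- shared_registry()
  p <- shared_panel()
  a <- p$assays[p$assays$name == "067721-477", ]
  pool <- c("#1" = 0.9, "#5" = 0.1)
  s1 <- simulate_extension_spectrum(pool, a, reg, seed = 3)
  s2 <- simulate_extension_spectrum(pool, a, reg, seed = 3)
  expect_identical(s1$intensity, s2$intensity)
  expect_false(s1$merged_warning)
  expect_warning(
    s3 <- simulate_extension_spectrum(pool, a, reg,
                                      noise_params(peak_sigma = 5),
                                      seed = 3),
    "merge")
  expect_true(s3$merged_warning)
})

test_that("pool conservation and monotone peak response hold across
           random mixtures", {
  reg <- shared_registry()
  p <- shared_panel()
  bias <- paper_bias_preset(p, reg)
  a <- p$assays[p$assays$name == "067744-324", ]
  ids <- c("#4", "#5", "#6", "#15")
  set.seed(101)
  for (i in 1:20) {
    w <- rgamma(4, 2) + 0.05
    mix <- mixture_spec("s", setNames(w, ids))
    pool <- simulate_first_pcr(mix, "P1/P2", bias)
    expect_equal(sum(pool), 1)
    sp <- simulate_extension_spectrum(pool, a, reg,
                                      noise_params(baseline_sd = 0))
    # raise #5 and renormalize: its allele share never decreases
    w2 <- w; w2[2] <- w2[2] * 1.5
    pool2 <- simulate_first_pcr(mixture_spec("s", setNames(w2, ids)),
                                "P1/P2", bias)
    sp2 <- simulate_extension_spectrum(pool2, a, reg,
                                       noise_params(baseline_sd = 0))
    share1 <- sp$truth["C"] / sum(sp$truth)
    share2 <- sp2$truth["C"] / sum(sp2$truth)
    expect_gte(share2, share1 - 1e-12)
  }
})
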