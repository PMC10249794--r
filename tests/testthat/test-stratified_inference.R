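test_that("a fully identified system collapses intervals to the allele
           fractions", {
  reg <- shared_registry()
  p <- shared_panel()
  # ascospore context at 067740-324: C -> {#5}, T -> {#6,#16}; with #6
  # alone allowed per allele the system identifies both shares
  pk <- peaks_tbl("s", "067740-324", c(A = NA, C = 6, G = NA, T = 4))
  ctx <- sample_context("s", c("#5", "#6"), list("067740-324" = pk))
  att <- attribute_peaks(ctx, p, reg, attribution_params(constraint_tol = 0))
  g5 <- att$genotypes[att$genotypes$genotype_id == "#5", ]
  expect_equal(g5$lo, 0.6, tolerance = 1e-5)
  expect_equal(g5$hi, 0.6, tolerance = 1e-5)
  g6 <- att$genotypes[att$genotypes$genotype_id == "#6", ]
  expect_equal(g6$lo, 0.4, tolerance = 1e-5)
})

test_that("share intervals agree with the grid-enumeration oracle on
           random small systems", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:12) {
    sys <- random_constraint_system(sample(2:4, 1), sample(1:3, 1))
    tol <- 0.02
    grid <- oracle_grid_bounds(sys$universe, sys$cons, tol)
    expect_false(is.null(grid))
    for (j in seq_along(sys$universe)) {
      lp <- share_bounds_lp(sys$universe[j], sys$universe, sys$cons, tol)
      expect_lte(abs(lp[["lo"]] - grid[j, "lo"]), 0.01 + 1e-9)
      expect_lte(abs(lp[["hi"]] - grid[j, "hi"]), 0.01 + 1e-9)
      # the interval brackets the ground truth
      expect_gte(sys$truth[j], lp[["lo"]] - 1e-9)
      expect_lte(sys$truth[j], lp[["hi"]] + 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 24)
})

test_that("adding an assay never widens intervals; dropping a genotype
           never lowers other lo bounds", {
  reg <- shared_registry()
  p <- shared_panel()
  pk1 <- peaks_tbl("s", "067740-328", c(A = NA, C = 1, G = NA, T = 9))
  pk2 <- peaks_tbl("s", "067744-324", c(A = NA, C = 3, G = NA, T = 7))
  allowed <- c("#4", "#5", "#6", "#15")
  ctx1 <- sample_context("s", allowed, list("067740-328" = pk1))
  ctx12 <- sample_context("s", allowed, list("067740-328" = pk1,
                                             "067744-324" = pk2))
  a1 <- attribute_peaks(ctx1, p, reg)
  a12 <- attribute_peaks(ctx12, p, reg)
  for (g in allowed) {
    r1 <- a1$genotypes[a1$genotypes$genotype_id == g, ]
    r12 <- a12$genotypes[a12$genotypes$genotype_id == g, ]
    expect_gte(r12$lo, r1$lo - 1e-9)
    expect_lte(r12$hi, r1$hi + 1e-9)
  }
  # removing #15 from the allowed set cannot lower #6's lower bound
  ctx_no15 <- sample_context("s", setdiff(allowed, "#15"),
                             list("067740-328" = pk1,
                                  "067744-324" = pk2))
  a_no15 <- attribute_peaks(ctx_no15, p, reg)
  g6_before <- a12$genotypes[a12$genotypes$genotype_id == "#6", ]
  g6_after <- a_no15$genotypes[a_no15$genotypes$genotype_id == "#6", ]
  expect_gte(g6_after$lo, g6_before$lo - 1e-9)
})

test_that("inconsistent allele fractions raise an infeasibility report", {
  reg <- shared_registry()
  p <- shared_panel()
  # both assays constrain #5 directly but disagree wildly
  pk1 <- peaks_tbl("s", "067740-324", c(A = NA, C = 9, G = NA, T = 1))
  pk2 <- peaks_tbl("s", "067744-324", c(A = NA, C = 1, G = NA, T = 9))
  ctx <- sample_context("s", c("#5", "#6"),
                        list("067740-324" = pk1, "067744-324" = pk2))
  expect_error(attribute_peaks(ctx, p, reg), "infeasible.*067740-324")
})

test_that("unexplained intensity is reported per assay", {
  reg <- shared_registry()
  p <- shared_panel()
  # A peak has no allowed genotype behind it at this assay
  pk <- peaks_tbl("s", "067740-328", c(A = 2, C = 1, G = NA, T = 7))
  ctx <- sample_context("s", c("#4", "#5", "#6", "#15"),
                        list("067740-328" = pk))
  att <- attribute_peaks(ctx, p, reg)
  expect_equal(att$residuals$unexplained_fraction, 0.2)
})

test_that("zero-noise simulated stratification recovers true pool
           shares within narrow intervals", {
  reg <- shared_registry()
  p <- shared_panel()
  bias <- paper_bias_preset(p, reg)
  # {#5, #6, #16} is identifiable by the two -324 assays (C separates
  # #5 at one and #6 extends T alone at the other); #6 and #15 share
  # alleles at every assay, so mixtures holding both stay underdetermined
  mix <- mixture_spec("s", c("#5" = 0.4, "#6" = 0.35, "#16" = 0.25))
  plan <- c("067740-324", "067744-324")
  peaks <- list()
  for (an in plan) {
    a <- p$assays[p$assays$name == an, ]
    pool <- simulate_first_pcr(mix, "P1/P2", bias)
    sp <- simulate_extension_spectrum(pool, a, reg,
                                      noise_params(baseline_sd = 0))
    peaks[[an]] <- call_allele_peaks(sp, a, sample_label = "s")
  }
  ctx <- sample_context("s", names(mix$abundances), peaks)
  att <- attribute_peaks(ctx, p, reg,
                         attribution_params(constraint_tol = 0.005))
  for (g in names(mix$abundances)) {
    row <- att$genotypes[att$genotypes$genotype_id == g, ]
    expect_gte(mix$abundances[[g]], row$lo - 1e-6)
    expect_lte(mix$abundances[[g]], row$hi + 1e-6)
    expect_lte(row$hi - row$lo, 0.02 + 1e-6)
  }
})

test_that("the stratification plan splits genotype groups stepwise as
           published", {
  res <- stratify_sample("SFP_pre", "SFP", seed = 7)
  expect_length(res$steps, 2)
  s1 <- res$steps[["067740-328"]]$attribution
  expect_equal(sort(s1$groups$group), c("#15+#5+#6", "#4"))
  expect_equal(group_level(s1, "#4"), "LOW")
  s2 <- res$steps[["067744-324"]]$attribution
  expect_setequal(s2$groups$group, c("#4", "#5", "#15+#6"))
  expect_equal(group_level(s2, "#5"), "HIGH")
  expect_equal(group_level(s2, c("#6", "#15")), "HIGH")
  # ascospore plan ends with {#5} vs {#6,#16}
  res_a <- stratify_sample("ascospore_full", "ascospore", seed = 7)
  fin <- res_a$final
  expect_setequal(fin$groups$group, c("#16+#6", "#5"))
  # empty plan gives an empty narrative
  reg <- shared_registry()
  ctx <- sample_context("s", "#5", list())
  empty <- stratify(character(0), ctx, shared_panel(), reg)
  expect_length(empty$narrative, 0)
  # a plan assay without peaks is skipped with a warning
  pk <- peaks_tbl("s", "067740-328", c(A = NA, C = 1, G = NA, T = 9))
  ctx2 <- sample_context("s", c("#4", "#5"), list("067740-328" = pk))
  expect_warning(
    out <- stratify(c("067740-328", "067744-324"), ctx2, shared_panel(),
                    reg),
    "skipped")
  expect_length(out$steps, 1)
})
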