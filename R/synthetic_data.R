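# Synthetic study data: genotype marker sequences with the mutation
# structure of the real ITS genotypes, genotype mixtures, biased two-step
# amplification, and MALDI-TOF-like extension spectra.
#
# Sequences live on a 600-column master template. The Genotype #1
# stand-in (the GC-biased reference) is column-identical to the template;
# AT-biased stand-ins derive from it by transition-only point mutations,
# GC-clade relatives by a few transversions. The five extension-assay
# sites sit at fixed template columns chosen so that primer footprints do
# not overlap:
#   067721-477 -> col 477   067721-531 -> col 531   (GC-marker assays)
#   067740-324 -> col 324   067740-328 -> col 328
#   067744-324 -> col 360 (the #4 stand-in carries a 36-nt deletion
#                          upstream, so its own coordinate there is 324)
# Extension primers for the AT-marker assays were designed on AT-biased
# sequences; the #1 stand-in carries transition-mutated footprint
# variants there, so exact-match primer search correctly reports those
# sites absent in the GC clade.

SITE_COLS <- c("067721-477" = 477L, "067721-531" = 531L,
               "067740-324" = 324L, "067740-328" = 328L,
               "067744-324" = 360L)

AT_ASSAYS <- c("067740-324", "067740-328", "067744-324")
GC_ASSAYS <- c("067721-477", "067721-531")

# sense-strand base of each genotype at each assay's template column;
# GC-clade genotypes carry the reference base everywhere
SITE_ALLELES <- list(
  GC     = c("067721-477" = "G", "067721-531" = "G",
             "067740-324" = "C", "067740-328" = "C", "067744-324" = "C"),
  "#4"   = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "T", "067740-328" = "C", "067744-324" = "T"),
  "#5"   = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "C", "067740-328" = "T", "067744-324" = "C"),
  "#6"   = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "T", "067740-328" = "T", "067744-324" = "T"),
  "#15"  = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "T", "067740-328" = "T", "067744-324" = "T"),
  "#16"  = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "T", "067740-328" = "T", "067744-324" = "C"),
  "#17"  = c("067721-477" = "A", "067721-531" = "A",
             "067740-324" = "C", "067740-328" = "T", "067744-324" = "C")
)

AT_GENOTYPES <- c("#4", "#5", "#6", "#15", "#16", "#17")
GC_GENOTYPES <- paste0("#", c(1:3, 7:14))

# unknown-flank transversion stand-ins observed as low side peaks
UNKNOWN_SPECS <- data.frame(
  genotype_id = c("U_477_C", "U_477_T", "U_531_T",
                  "U_740324_A", "U_740324_G",
                  "U_744324_A", "U_744324_G",
                  "U_740328_A", "U_740328_G"),
  assay = c("067721-477", "067721-477", "067721-531",
            "067740-324", "067740-324", "067744-324", "067744-324",
            "067740-328", "067740-328"),
  allele = c("C", "T", "T", "A", "G", "A", "G", "A", "G")
)

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_OF <- c(A = "C", C = "A", G = "T", T = "G")

DEL_REGION <- 101:136       # 36-nt deletion planted in the #4 stand-in
TRUNC_5 <- 1:20             # terminal truncations planted in the #6
TRUNC_3 <- 581:600          # stand-in (its real sequence is short)

#' @noRd
assay_footprint_cols <- function(assay) {
  col <- SITE_COLS[[assay$name]]
  len <- nchar(assay$primer_seq)
  if (assay$orientation == "SENSE") {
    list(cols = (col - len):(col - 1L), seq = assay$primer_seq)
  } else {
    list(cols = (col + 1L):(col + len), seq = revcomp(assay$primer_seq))
  }
}

#' Generate the stand-in genotype registry
#'
#' Builds one GC-biased reference carrying all primer footprints and the
#' planted SNP alleles, AT-biased genotypes derived by transition-only
#' mutation (plus the coordinate-shifting deletion in #4 and terminal
#' truncations in #6), GC-clade relatives with a few transversions, and
#' optional unknown-flank transversion stand-ins. Reproducible under a
#' fixed seed; planted transition counts are recorded in the
#' `planted_transitions` attribute.
#'
#' @param length template length in nt (>= 540; default 600).
#' @param gc_ref GC fraction of the reference outside fixed features.
#' @param n_transitions random transitions planted per AT genotype in
#'   addition to the deterministic site/footprint changes.
#' @param n_transversions_gc transversions per GC-clade relative.
#' @param seed integer RNG seed.
#' @param include_unknowns also generate the unknown-flank transversion
#'   records (ids `U_*`).
#' @param retries regeneration attempts if a random draw corrupts a
#'   primer site.
#' @return a `genotype_registry` (with attribute `planted_transitions`).
#' @export
generate_genotype_sequences <- function(length = 600L, gc_ref = 0.62,
                                        n_transitions = 30L,
                                        n_transversions_gc = 3L,
                                        seed = 1L,
                                        include_unknowns = TRUE,
                                        retries = 5L) {
  stopifnot(length >= 540L, gc_ref > 0, gc_ref < 1, n_transitions >= 0L,
            n_transversions_gc >= 0L)
  panel <- load_paper_panel()
  for (attempt in seq_len(retries)) {
    reg <- withr::with_seed(seed + (attempt - 1L) * 7919L, {
      try(build_registry_once(length, gc_ref, n_transitions,
                              n_transversions_gc, include_unknowns, panel),
          silent = TRUE)
    })
    if (!inherits(reg, "try-error")) return(reg)
  }
  stop("genotype generation failed after ", retries, " attempts: ",
       attr(reg, "condition")$message, call. = FALSE)
}

#' @noRd
build_registry_once <- function(length, gc_ref, n_transitions,
                                n_transversions_gc, include_unknowns,
                                panel) {
  assays <- panel$assays
  # reference template
  p_gc <- gc_ref
  master <- sample(DNA_BASES, length, replace = TRUE,
                   prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2,
                            (1 - p_gc) / 2))
  fixed <- integer(0)
  at_fp <- list()
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    fp <- assay_footprint_cols(a)
    fp_seq <- seq_chars(fp$seq)
    if (a$name %in% GC_ASSAYS) {
      master[fp$cols] <- fp_seq
    } else {
      # transition-mutated variant in the GC reference
      broken <- fp_seq
      off <- seq(2L, length(fp_seq), by = 5L)
      broken[off] <- TRANSITION_OF[fp_seq[off]]
      master[fp$cols] <- broken
      at_fp[[a$name]] <- list(cols = fp$cols, seq = fp_seq,
                              n_repair = base::length(off))
    }
    master[SITE_COLS[[a$name]]] <- SITE_ALLELES$GC[[a$name]]
    fixed <- c(fixed, fp$cols, SITE_COLS[[a$name]])
  }
  free <- setdiff(seq_len(length), c(fixed, DEL_REGION, TRUNC_5, TRUNC_3))

  seqs <- list(); planted <- c()
  seqs[["#1"]] <- master
  planted["#1"] <- 0L
  for (g in setdiff(GC_GENOTYPES, "#1")) {
    s <- master
    pos <- sample(free, n_transversions_gc)
    s[pos] <- TRANSVERSION_OF[s[pos]]
    seqs[[g]] <- s
    planted[g] <- 0L
  }
  for (g in AT_GENOTYPES) {
    s <- master
    n_pl <- 0L
    for (fp in at_fp) {                       # restore exact AT footprints
      n_pl <- n_pl + sum(s[fp$cols] != fp$seq)
      s[fp$cols] <- fp$seq
    }
    for (an in names(SITE_COLS)) {            # planted SNP alleles
      want <- SITE_ALLELES[[g]][[an]]
      col <- SITE_COLS[[an]]
      if (s[col] != want) {
        if (TRANSITION_OF[s[col]] != want) {
          stop("non-transition allele plant for ", g, " at ", an)
        }
        s[col] <- want
        n_pl <- n_pl + 1L
      }
    }
    elig <- free[s[free] %in% c("C", "G")]    # scattered C->T / G->A
    pos <- sample(elig, n_transitions)
    s[pos] <- TRANSITION_OF[s[pos]]
    n_pl <- n_pl + n_transitions
    if (g == "#4") s <- s[-DEL_REGION]
    if (g == "#6") s <- s[-c(TRUNC_5, TRUNC_3)]
    seqs[[g]] <- s
    planted[g] <- n_pl
  }
  if (include_unknowns) {
    for (k in seq_len(nrow(UNKNOWN_SPECS))) {
      u <- UNKNOWN_SPECS[k, ]
      a <- assays[assays$name == u$assay, ]
      flank <- sample(DNA_BASES, 450L, replace = TRUE)
      len <- nchar(a$primer_seq)
      if (a$orientation == "SENSE") {
        flank[200:(199L + len)] <- seq_chars(a$primer_seq)
        flank[200L + len] <- u$allele
      } else {
        flank[200L] <- u$allele
        flank[201:(200L + len)] <- seq_chars(revcomp(a$primer_seq))
      }
      seqs[[u$genotype_id]] <- flank
      planted[u$genotype_id] <- 0L
    }
  }

  meta <- paper_genotype_metadata()
  if (include_unknowns) {
    meta <- bind_rows(meta, tibble(genotype_id = UNKNOWN_SPECS$genotype_id,
                                   accession = "synthetic",
                                   clade = "UNKNOWN_TRANSVERSION"))
  }
  fasta <- vapply(seqs, chars_seq, character(1))
  reg <- load_genotypes(fasta, meta)
  verify_planted_alleles(reg, panel)
  attr(reg, "planted_transitions") <- planted
  reg
}

#' The published genotype/clade metadata table
#'
#' Seventeen ITS genotypes: the GC-biased clade, AT-biased Cluster-A
#' (#5, #6, #16, #17) and AT-biased Cluster-B (#4, #15). Accessions are
#' kept for the five marker reference sequences; all generated sequences
#' are synthetic stand-ins.
#'
#' @return tibble with genotype_id, accession, clade.
#' @export
paper_genotype_metadata <- function() {
  ids <- paste0("#", 1:17)
  acc <- setNames(rep("synthetic", 17L), ids)
  acc[c("#1", "#4", "#5", "#6", "#16")] <-
    c("AB067721", "AB067744", "AB067740", "EU555436", "KT232019")
  clade <- setNames(rep("GC", 17L), ids)
  clade[c("#5", "#6", "#16", "#17")] <- "AT_CLUSTER_A"
  clade[c("#4", "#15")] <- "AT_CLUSTER_B"
  tibble(genotype_id = ids, accession = unname(acc), clade = unname(clade))
}

#' @noRd
verify_planted_alleles <- function(registry, panel) {
  for (i in seq_len(nrow(panel$assays))) {
    a <- panel$assays[i, ]
    for (j in seq_len(nrow(registry))) {
      rec <- registry[j, ]
      got <- predict_extension_allele(rec, a)$allele
      want <- intended_allele(rec$genotype_id, a$name)
      if (!identical(got, want)) {
        stop(sprintf("planted allele check failed: %s at %s is %s, not %s",
                     rec$genotype_id, a$name, got, want))
      }
    }
  }
  invisible(TRUE)
}

#' @noRd
intended_allele <- function(genotype_id, assay_name) {
  if (genotype_id %in% UNKNOWN_SPECS$genotype_id) {
    u <- UNKNOWN_SPECS[UNKNOWN_SPECS$genotype_id == genotype_id, ]
    return(if (u$assay == assay_name) u$allele else "NONE")
  }
  if (genotype_id %in% AT_GENOTYPES) {
    return(SITE_ALLELES[[genotype_id]][[assay_name]])
  }
  if (assay_name %in% GC_ASSAYS) SITE_ALLELES$GC[[assay_name]] else "NONE"
}

#' Build a mixture specification
#'
#' @param sample_label label such as `"SFP_pre"`.
#' @param abundances named non-negative numeric vector of relative
#'   template fractions; normalized to sum to 1.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(sample_label, abundances) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)),
            all(abundances >= 0))
  tot <- sum(abundances)
  if (tot <= 0) stop("mixture has no template", call. = FALSE)
  structure(list(sample_label = sample_label,
                 abundances = abundances / tot),
            class = "mixture_spec")
}

#' Paper-faithful amplification-bias preset
#'
#' GC-favoring first-step pairs amplify GC-clade templates with a 4:1
#' gain advantage; AT-favoring pairs the reverse. Unknown-flank
#' transversion templates amplify with gain 1 under either pair class.
#' Only the direction of bias is asserted by the underlying study; the
#' 4:1 magnitude is the package's preset.
#'
#' @param panel an `assay_panel`.
#' @param registry a `genotype_registry`.
#' @return tibble pair_name x genotype_id -> gain.
#' @export
paper_bias_preset <- function(panel, registry) {
  grid <- expand.grid(pair_name = panel$pairs$name,
                      genotype_id = registry$genotype_id,
                      stringsAsFactors = FALSE)
  grid <- as_tibble(grid) %>%
    left_join(registry[, c("genotype_id", "clade")], by = "genotype_id") %>%
    left_join(panel$pairs[, c("name", "target_bias")],
              by = c(pair_name = "name"))
  grid$gain <- ifelse(
    grid$clade == "UNKNOWN_TRANSVERSION", 1,
    ifelse(grid$clade == "GC",
           ifelse(grid$target_bias == "GC_FAVORING", 4, 1),
           ifelse(grid$target_bias == "GC_FAVORING", 1, 4)))
  grid[, c("pair_name", "genotype_id", "gain")]
}

#' Simulate the first-step PCR as a biased amplicon pool
#'
#' Pool fraction is proportional to template abundance times the pair's
#' multiplicative gain for that genotype, renormalized. Genotypes whose
#' priming sites the pair cannot use carry gain 0 in the bias table.
#'
#' @param mixture a `mixture_spec`.
#' @param pair one-row tibble from `panel$pairs` (or a pair name plus
#'   `panel`).
#' @param bias gain tibble as from [paper_bias_preset()].
#' @return named numeric vector of amplicon pool fractions (sums to 1).
#' @export
simulate_first_pcr <- function(mixture, pair, bias) {
  pair_name <- if (is.character(pair)) pair else pair$name
  b <- bias[bias$pair_name == pair_name, ]
  ab <- mixture$abundances
  missing_gain <- setdiff(names(ab), b$genotype_id)
  if (length(missing_gain) > 0) {
    stop("no bias entry for genotype ", missing_gain[1], " under pair ",
         pair_name, call. = FALSE)
  }
  gains <- setNames(b$gain, b$genotype_id)[names(ab)]
  pool <- ab * gains
  if (sum(pool) <= 0) {
    stop("no amplifiable template under pair ", pair_name, call. = FALSE)
  }
  pool / sum(pool)
}

#' Default spectrum noise / rendering parameters
#'
#' @param intensity_scale arbitrary intensity units of a full-pool peak.
#' @param peak_sigma Gaussian peak width (Da); allelic products are >= 9
#'   Da apart, so the default keeps them resolvable.
#' @param baseline_sd baseline noise sd; default 1% of intensity_scale.
#' @param mz_step m/z grid step (Da).
#' @return parameter list.
#' @export
noise_params <- function(intensity_scale = 10, peak_sigma = 2,
                         baseline_sd = NULL, mz_step = 0.02) {
  list(intensity_scale = intensity_scale, peak_sigma = peak_sigma,
       baseline_sd = baseline_sd %||% (0.01 * intensity_scale),
       mz_step = mz_step)
}

#' Simulate a single-base-extension MALDI-TOF spectrum
#'
#' Noiseless intensity of each allele peak equals the summed pool
#' fractions of the genotypes predicted to extend that base, times
#' `intensity_scale`; peaks are rendered as Gaussians at the extension
#' product masses plus baseline noise. Ground truth is recorded.
#'
#' @param pool named amplicon pool fractions from [simulate_first_pcr()].
#' @param assay one-row assay tibble.
#' @param registry a `genotype_registry` (for allele prediction).
#' @param noise parameter list from [noise_params()].
#' @param seed integer seed for the baseline noise.
#' @return a `sim_spectrum` list: `mz`, `intensity`, `truth`, `masses`,
#'   `assay_name`, `peak_sigma`, `intensity_scale`, `seed`, and a
#'   `merged_warning` flag set when peaks are closer than 3 sigma.
#' @export
simulate_extension_spectrum <- function(pool, assay, registry,
                                        noise = noise_params(), seed = 1L) {
  stopifnot(abs(sum(pool) - 1) < 1e-9)
  preds <- predict_panel_alleles(registry[registry$genotype_id %in%
                                            names(pool), ],
                                 structure(list(assays = assay),
                                           class = "assay_panel"))
  truth <- vapply(DNA_BASES, function(b) {
    ids <- preds$genotype_id[preds$allele == b]
    sum(pool[ids]) * noise$intensity_scale
  }, numeric(1))
  masses <- assay_product_masses(assay)
  mz <- seq(min(masses) - 25, max(masses) + 25, by = noise$mz_step)
  signal <- rep(0, length(mz))
  for (b in DNA_BASES) {
    signal <- signal +
      truth[[b]] * exp(-((mz - masses[[b]])^2) / (2 * noise$peak_sigma^2))
  }
  trace <- if (noise$baseline_sd > 0) {
    withr::with_seed(seed, pmax(0, signal +
                                  rnorm(length(mz), 0, noise$baseline_sd)))
  } else {
    signal
  }
  merged <- min(diff(sort(masses))) < 3 * noise$peak_sigma
  if (merged) {
    warning("allelic peaks closer than 3*peak_sigma; apexes may merge",
            call. = FALSE)
  }
  structure(list(mz = mz, intensity = trace, truth = truth,
                 masses = masses, assay_name = assay$name,
                 peak_sigma = noise$peak_sigma,
                 intensity_scale = noise$intensity_scale, seed = seed,
                 merged_warning = merged),
            class = "sim_spectrum")
}
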