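# Two-step assay panel: first-step PCR primer pairs and single-base
# extension assays, with per-genotype allele prediction.
#
# A panel is a list with class "assay_panel":
#   $pairs  tibble: name, forward_seq, reverse_seq, target_bias
#   $assays tibble: name, primer_seq, reference_id, snp_position,
#                   orientation, feeding_pairs (list-column)
#
# Alleles are always reported on the sense strand: for a
# REVERSE_COMPLEMENT assay the physically extended base is the complement
# of the sense-strand base at the SNP.

#' Load an assay panel from a YAML definition
#'
#' @param path panel YAML (defaults to the packaged panel).
#' @return an `assay_panel` object.
#' @export
load_panel <- function(path = snpms_extdata("panel.yaml")) {
  y <- yaml::yaml.load_file(path)
  pairs <- bind_rows(lapply(y$primer_pairs, function(p) {
    tibble(name = p$name, forward_name = p$forward_name,
           forward_seq = toupper(p$forward_seq),
           reverse_name = p$reverse_name,
           reverse_seq = toupper(p$reverse_seq),
           target_bias = p$target_bias)
  }))
  assays <- bind_rows(lapply(y$extension_assays, function(a) {
    tibble(name = a$name, primer_seq = toupper(a$primer_seq),
           reference_id = a$reference_id,
           snp_position = as.integer(a$snp_position),
           orientation = a$orientation,
           feeding_pairs = list(unlist(a$feeding_pairs)))
  }))
  stopifnot(all(pairs$target_bias %in% c("GC_FAVORING", "AT_FAVORING")),
            all(assays$orientation %in% c("SENSE", "REVERSE_COMPLEMENT")))
  for (i in seq_len(nrow(assays))) {
    pos_in_name <- as.integer(sub(".*-", "", assays$name[i]))
    if (!identical(pos_in_name, assays$snp_position[i])) {
      stop("assay name does not encode snp_position: ", assays$name[i],
           call. = FALSE)
    }
  }
  structure(list(pairs = pairs, assays = assays), class = "assay_panel")
}

#' Load the published five-assay panel
#'
#' Six first-step primers forming the pairs Hsprp1/3, Hsprp1/ITS4 (favoring
#' the GC-biased marker) and P1/P2, P2/P1, P2/P4 (favoring AT-biased
#' markers), plus five extension assays named reference-position
#' (e.g. "067721-477").
#'
#' @return an `assay_panel` object.
#' @export
load_paper_panel <- function() {
  load_panel(snpms_extdata("panel.yaml"))
}

#' @noRd
get_assay <- function(panel, assay_name) {
  row <- panel$assays[panel$assays$name == assay_name, ]
  if (nrow(row) != 1L) stop("unknown assay: ", assay_name, call. = FALSE)
  row
}

#' Locate an assay's SNP site in a genotype sequence
#'
#' The extension primer footprint is located by exact-match search (0
#' mismatches); the site is the position immediately 3' of the primer on
#' the template being read. Returns NA when the footprint is absent.
#'
#' @param sequence genotype DNA string.
#' @param assay one-row assay tibble.
#' @return 1-based sense-strand site position, or NA.
#' @export
locate_assay_site <- function(sequence, assay) {
  primer <- assay$primer_seq
  if (assay$orientation == "SENSE") {
    hits <- gregexpr(primer, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NA_integer_)
    if (length(hits) > 1L) stop("ambiguous primer site for ", assay$name,
                                call. = FALSE)
    site <- hits[1] + nchar(primer)
    if (site > nchar(sequence)) return(NA_integer_)
  } else {
    fp <- revcomp(primer)  # footprint on the sense strand, 3' of the SNP
    hits <- gregexpr(fp, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NA_integer_)
    if (length(hits) > 1L) stop("ambiguous primer site for ", assay$name,
                                call. = FALSE)
    site <- hits[1] - 1L
    if (site < 1L) return(NA_integer_)
  }
  as.integer(site)
}

#' Predict the extended allele of one genotype at one assay
#'
#' The reported allele is the genotype's sense-strand base at the SNP site
#' (for REVERSE_COMPLEMENT assays the physically extended terminator is
#' its complement). `"NONE"` marks a genotype whose primer site is absent.
#'
#' @param genotype one-row genotype record.
#' @param assay one-row assay tibble (from an `assay_panel`).
#' @param site_map optional integer position overriding the exact-match
#'   search (e.g. from an alignment); NA means site absent.
#' @return tibble: assay_name, genotype_id, allele, allele_is_sense_strand.
#' @export
predict_extension_allele <- function(genotype, assay, site_map = NULL) {
  site <- if (!is.null(site_map)) {
    site_map
  } else {
    locate_assay_site(genotype$sequence, assay)
  }
  allele <- if (is.na(site)) {
    "NONE"
  } else {
    if (site < 1L || site > nchar(genotype$sequence)) {
      stop("unmapped site without absent-flag for ", genotype$genotype_id,
           " at ", assay$name, call. = FALSE)
    }
    substr(genotype$sequence, site, site)
  }
  tibble(assay_name = assay$name, genotype_id = genotype$genotype_id,
         allele = allele, allele_is_sense_strand = TRUE)
}

#' Predict alleles for every genotype in a registry
#'
#' @param registry a `genotype_registry`.
#' @param panel an `assay_panel`.
#' @param assays optional character vector restricting the assays.
#' @return tibble of allele predictions (one row per assay x genotype).
#' @export
predict_panel_alleles <- function(registry, panel, assays = NULL) {
  assay_tbl <- panel$assays
  if (!is.null(assays)) assay_tbl <- assay_tbl[assay_tbl$name %in% assays, ]
  out <- list()
  for (i in seq_len(nrow(assay_tbl))) {
    a <- assay_tbl[i, ]
    for (j in seq_len(nrow(registry))) {
      out[[length(out) + 1L]] <- predict_extension_allele(registry[j, ], a)
    }
  }
  bind_rows(out)
}

#' Map each allele of an assay to its genotype set under constraints
#'
#' @param assay one-row assay tibble.
#' @param registry a `genotype_registry`.
#' @param constraints character vector of genotype ids assumed present in
#'   the sample context (presence constraints are config input, never
#'   hard-coded).
#' @return named list base -> character vector of genotype ids; bases
#'   with no constrained genotype map to an empty set. Site-absent
#'   genotypes are excluded.
#' @export
allele_to_genotype_map <- function(assay, registry, constraints) {
  keep <- registry[registry$genotype_id %in% constraints, ]
  if (nrow(keep) == 0L) stop("empty constrained registry", call. = FALSE)
  preds <- bind_rows(lapply(seq_len(nrow(keep)), function(j) {
    predict_extension_allele(keep[j, ], assay)
  }))
  preds <- preds[preds$allele != "NONE", ]
  m <- lapply(DNA_BASES, function(b) preds$genotype_id[preds$allele == b])
  setNames(m, DNA_BASES)
}

#' Expected extension-product masses of an assay
#'
#' Keyed by the reported sense-strand allele; for REVERSE_COMPLEMENT
#' assays the physically extended terminator is the complement of the
#' reported base.
#'
#' @param assay one-row assay tibble.
#' @return named numeric vector (A/C/G/T) of daltons.
#' @export
assay_product_masses <- function(assay) {
  phys <- if (assay$orientation == "REVERSE_COMPLEMENT") {
    complement_base(DNA_BASES)
  } else {
    DNA_BASES
  }
  m <- vapply(phys, function(b) extension_product_mass(assay$primer_seq, b),
              numeric(1))
  setNames(unname(m), DNA_BASES)
}
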