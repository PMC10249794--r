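# Genotype registry: marker sequences plus clade/bias metadata.
#
# A registry is a tibble with one row per genotype:
#   genotype_id, accession, clade, sequence, gc_fraction
# Clades: "GC" (GC-biased), "AT_CLUSTER_A", "AT_CLUSTER_B",
# "UNKNOWN_TRANSVERSION" (transversion alleles of unknown flanking
# sequence, carried as first-class records).

GENOTYPE_CLADES <- c("GC", "AT_CLUSTER_A", "AT_CLUSTER_B",
                     "UNKNOWN_TRANSVERSION")

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @return proportion in \[0, 1\].
#' @export
#' @examples
#' gc_content("GGCC") # 1
#' gc_content("ATAT") # 0
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence: GC content undefined",
                                  call. = FALSE)
  assert_bases(sequence)
  ch <- seq_chars(sequence)
  n_acgt <- sum(ch %in% DNA_BASES)
  if (n_acgt == 0L) stop("all-N sequence: GC content undefined",
                         call. = FALSE)
  sum(ch %in% c("G", "C")) / n_acgt
}

#' Build a genotype registry from sequences and clade metadata
#'
#' @param fasta_source path to a multi-record FASTA file, or a named
#'   character vector of sequences.
#' @param metadata data frame with columns `genotype_id`, `accession`,
#'   `clade`, or a path to a TSV file with those columns.
#' @param allow_unlisted if `TRUE`, sequences absent from `metadata` are
#'   admitted with clade `"UNKNOWN_TRANSVERSION"`; otherwise they are an
#'   error.
#' @return a `genotype_registry` tibble.
#' @export
load_genotypes <- function(fasta_source, metadata, allow_unlisted = FALSE) {
  seqs <- read_fasta(fasta_source)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate genotype id in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)
  }
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read.delim(metadata, sep = "\t", stringsAsFactors = FALSE)
  }
  metadata <- as_tibble(metadata)
  stopifnot(all(c("genotype_id", "accession", "clade") %in% names(metadata)))
  bad_clade <- setdiff(unique(metadata$clade), GENOTYPE_CLADES)
  if (length(bad_clade) > 0) {
    stop("unknown clade label: ", bad_clade[1], call. = FALSE)
  }
  missing_seq <- setdiff(metadata$genotype_id, names(seqs))
  if (length(missing_seq) > 0) {
    stop("metadata genotype absent from FASTA: ", missing_seq[1],
         call. = FALSE)
  }
  unlisted <- setdiff(names(seqs), metadata$genotype_id)
  if (length(unlisted) > 0 && !allow_unlisted) {
    stop("FASTA record not in metadata (set allow_unlisted = TRUE to keep ",
         "as UNKNOWN_TRANSVERSION): ", unlisted[1], call. = FALSE)
  }
  for (id in names(seqs)) assert_bases(seqs[[id]], what = id)
  meta_all <- bind_rows(
    metadata,
    tibble(genotype_id = unlisted,
           accession = rep("synthetic", length(unlisted)),
           clade = rep("UNKNOWN_TRANSVERSION", length(unlisted)))
  )
  reg <- meta_all %>%
    mutate(sequence = unname(seqs[genotype_id]),
           gc_fraction = vapply(sequence, gc_content, numeric(1),
                                USE.NAMES = FALSE)) %>%
    select(genotype_id, accession, clade, sequence, gc_fraction)
  class(reg) <- c("genotype_registry", class(reg))
  reg
}

#' @noRd
read_fasta <- function(fasta_source) {
  if (is.character(fasta_source) && length(fasta_source) == 1L &&
      file.exists(fasta_source)) {
    ss <- Biostrings::readDNAStringSet(fasta_source)
    seqs <- setNames(as.character(ss), names(ss))
  } else if (is.character(fasta_source) && !is.null(names(fasta_source))) {
    seqs <- fasta_source
  } else {
    stop("fasta_source must be a file path or a named character vector",
         call. = FALSE)
  }
  # drop description text after first whitespace in FASTA headers
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

#' Write a registry to FASTA plus a clade metadata TSV
#'
#' @param registry a `genotype_registry`.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_registry <- function(registry, fasta_path, metadata_path) {
  ss <- Biostrings::DNAStringSet(setNames(registry$sequence,
                                          registry$genotype_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  write.table(registry[, c("genotype_id", "accession", "clade")],
              metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Fetch one genotype record
#'
#' @param registry a `genotype_registry`.
#' @param genotype_id id such as `"#5"`.
#' @return one-row tibble.
#' @export
get_genotype <- function(registry, genotype_id) {
  row <- registry[registry$genotype_id == genotype_id, ]
  if (nrow(row) != 1L) stop("genotype not in registry: ", genotype_id,
                            call. = FALSE)
  row
}

#' Pairwise global alignment coordinate map
#'
#' Global (Needleman-Wunsch) alignment of `alt` against `ref` with match 1,
#' mismatch -1, gap -2, returning the coordinate map used by
#' [mutation_profile()].
#'
#' @param ref,alt DNA strings.
#' @return tibble with columns `ref_pos`, `alt_pos` (NA marks a gap) and
#'   `ref_base`, `alt_base`.
#' @export
align_pair <- function(ref, alt) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(alt), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  pat <- seq_chars(as.character(Biostrings::alignedPattern(al)))  # alt
  sub <- seq_chars(as.character(Biostrings::alignedSubject(al)))  # ref
  ref_pos <- cumsum(sub != "-")
  alt_pos <- cumsum(pat != "-")
  tibble(
    ref_pos = ifelse(sub == "-", NA_integer_, ref_pos),
    alt_pos = ifelse(pat == "-", NA_integer_, alt_pos),
    ref_base = sub, alt_base = pat
  )
}

#' Count transitions, transversions and indels between two genotypes
#'
#' Substitutions are classified as transitions (A<->G, C<->T) or
#' transversions; each maximal gap run counts as one indel event.
#'
#' @param ref,alt one-row genotype records (or DNA strings).
#' @param alignment optional coordinate map from [align_pair()]; computed
#'   if omitted. Out-of-range coordinates are an error.
#' @return tibble with `n_transitions`, `n_transversions`, `n_indels`.
#' @export
mutation_profile <- function(ref, alt, alignment = NULL) {
  ref_seq <- if (is.character(ref)) ref else ref$sequence
  alt_seq <- if (is.character(alt)) alt else alt$sequence
  if (is.null(alignment)) alignment <- align_pair(ref_seq, alt_seq)
  stopifnot(all(c("ref_pos", "alt_pos") %in% names(alignment)))
  rp <- alignment$ref_pos
  ap <- alignment$alt_pos
  if (any(rp > nchar(ref_seq), na.rm = TRUE) ||
      any(ap > nchar(alt_seq), na.rm = TRUE) ||
      any(rp < 1L, na.rm = TRUE) || any(ap < 1L, na.rm = TRUE)) {
    stop("alignment references out-of-range positions", call. = FALSE)
  }
  rb <- ifelse(is.na(rp), "-", seq_chars(ref_seq)[ifelse(is.na(rp), 1L, rp)])
  ab <- ifelse(is.na(ap), "-", seq_chars(alt_seq)[ifelse(is.na(ap), 1L, ap)])
  sub <- rb != "-" & ab != "-" & rb != ab & rb != "N" & ab != "N"
  n_ts <- sum(sub & is_transition(rb, ab))
  n_tv <- sum(sub & !is_transition(rb, ab))
  gap <- rb == "-" | ab == "-"
  n_indel <- sum(gap & !c(FALSE, gap[-length(gap)]))  # gap-run starts
  tibble(n_transitions = n_ts, n_transversions = n_tv, n_indels = n_indel)
}

#' Classify a genotype as AT-biased relative to a reference record
#'
#' A record counts as AT-biased when its GC fraction falls more than
#' `threshold` below the reference genotype's (bias is defined relative to
#' the GC-biased Genotype #1 marker throughout).
#'
#' @param registry a `genotype_registry`.
#' @param reference_id reference genotype id (default `"#1"`).
#' @param threshold GC-fraction deficit defining bias (default 0.03).
#' @return registry with a logical `at_biased` column.
#' @export
classify_bias <- function(registry, reference_id = "#1", threshold = 0.03) {
  ref_gc <- get_genotype(registry, reference_id)$gc_fraction
  mutate(registry, at_biased = ref_gc - gc_fraction > threshold)
}
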