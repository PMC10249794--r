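# Internal-reference intensity ratios and fold-change arrow calls.
#
# Within one spectrum, the intensity of one allele peak serves as the
# internal reference for another, giving a semi-quantitative ratio that
# is comparable across spectra of the same assay. Between-sample fold
# changes are binned into the arrow classes used in the source tables:
# "no change" within a 20% band, then less-than-two-fold, two-to-three-
# fold, three-to-four-fold, and greater-than-four-fold increases (and
# their decrease mirrors).

ARROW_LEVELS <- c("NO_CHANGE", "UP_LT2", "UP_2TO3", "UP_3TO4", "UP_GT4",
                  "DOWN_LT2", "DOWN_2TO3", "DOWN_3TO4", "DOWN_GT4",
                  "NOT_COMPUTABLE")

ARROW_GLYPHS <- c(NO_CHANGE = "↔", UP_LT2 = "↑",
                  UP_2TO3 = "↑↑", UP_3TO4 = "↑↑↑",
                  UP_GT4 = "↑↑↑↑",
                  DOWN_LT2 = "↓", DOWN_2TO3 = "↓↓",
                  DOWN_3TO4 = "↓↓↓",
                  DOWN_GT4 = "↓↓↓↓",
                  NOT_COMPUTABLE = "―")

#' Intensity ratio of two allele peaks
#'
#' The exact quotient of the recorded intensities. NEGLIGIBLE peaks
#' participate; a MISSING peak on either side makes the ratio MISSING
#' (NA). Input intensities are stored for audit.
#'
#' @param peaks allele-peak tibble for one sample and assay.
#' @param numerator,denominator allele bases.
#' @return one-row `ratio_record` tibble.
#' @export
intensity_ratio <- function(peaks, numerator, denominator) {
  stopifnot(numerator %in% DNA_BASES, denominator %in% DNA_BASES)
  if (length(unique(peaks$assay_name)) != 1L ||
      length(unique(peaks$sample_label)) != 1L) {
    stop("peaks must come from a single sample and assay", call. = FALSE)
  }
  num <- peaks[peaks$base == numerator, ]
  den <- peaks[peaks$base == denominator, ]
  if (nrow(num) != 1L || nrow(den) != 1L) {
    stop("numerator/denominator base not present in peak set",
         call. = FALSE)
  }
  if (den$status == "CALLED" && !is.na(den$intensity) &&
      den$intensity == 0) {
    stop("CALLED denominator peak with zero intensity (corrupt table)",
         call. = FALSE)
  }
  missing <- num$status == "MISSING" || den$status == "MISSING"
  tibble(sample_label = peaks$sample_label[1],
         assay_name = peaks$assay_name[1],
         numerator_base = numerator, denominator_base = denominator,
         numerator_intensity = num$intensity,
         denominator_intensity = den$intensity,
         ratio = if (missing) NA_real_ else num$intensity / den$intensity)
}

#' Classify the fold change between two ratio records
#'
#' fold = current ratio / reference ratio. Within a symmetric 20% band
#' of 1 the call is NO_CHANGE; otherwise the fold magnitude is binned at
#' thresholds 2, 3 and 4 (half-open; `[2, 3)` is the two-to-three-fold
#' bin), upward or downward. A MISSING ratio on either side gives
#' NOT_COMPUTABLE.
#'
#' @param current,reference one-row `ratio_record` tibbles (same assay
#'   and allele pair).
#' @param no_change_band half-width of the no-change band (default 0.20).
#' @return one-row tibble with `fold`, `arrow`, `glyph`.
#' @export
classify_change <- function(current, reference, no_change_band = 0.20) {
  if (!identical(current$assay_name, reference$assay_name) ||
      !identical(current$numerator_base, reference$numerator_base) ||
      !identical(current$denominator_base, reference$denominator_base)) {
    stop("change classification requires the same assay and allele pair",
         call. = FALSE)
  }
  if (is.na(current$ratio) || is.na(reference$ratio)) {
    fold <- NA_real_
    arrow <- "NOT_COMPUTABLE"
  } else {
    fold <- current$ratio / reference$ratio
    arrow <- classify_fold(fold, no_change_band)
  }
  tibble(sample_label = current$sample_label,
         reference_sample = reference$sample_label,
         assay_name = current$assay_name,
         numerator_base = current$numerator_base,
         denominator_base = current$denominator_base,
         fold = fold, arrow = arrow, glyph = ARROW_GLYPHS[[arrow]])
}

#' Map a positive fold change to its arrow bin
#'
#' @param fold positive fold change.
#' @param no_change_band half-width of the no-change band.
#' @return arrow class label.
#' @export
classify_fold <- function(fold, no_change_band = 0.20) {
  stopifnot(is.finite(fold), fold > 0)
  if (abs(fold - 1) <= no_change_band) return("NO_CHANGE")
  up <- fold > 1
  m <- if (up) fold else 1 / fold
  bin <- if (m < 2) "LT2" else if (m < 3) "2TO3" else if (m < 4) "3TO4"
         else "GT4"
  paste0(if (up) "UP_" else "DOWN_", bin)
}

#' Load a ratio-table specification fixture
#'
#' @param path YAML table spec (see `inst/extdata/tables/`).
#' @return list with table metadata and a `cells` tibble.
#' @export
load_table_spec <- function(path) {
  y <- yaml::yaml.load_file(path)
  cells <- bind_rows(lapply(y$cells, function(cl) {
    tibble(sample = cl$sample,
           numerator = cl$numerator, denominator = cl$denominator,
           decimals = as.integer(cl$decimals %||% 1L),
           printed_ratio = as.numeric(cl$printed_ratio %||% NA),
           printed_num = as.numeric(cl$printed_num %||% NA),
           printed_den = as.numeric(cl$printed_den %||% NA),
           printed_arrow = as.character(cl$printed_arrow %||% NA),
           known_mismatch = as.character(cl$known_mismatch %||% "none"))
  }))
  list(name = y$name, assay = y$assay,
       reference_sample = y$reference_sample %||% NA_character_,
       ratio_only = isTRUE(y$ratio_only), cells = cells)
}

#' Build one published-style ratio table from a peak fixture
#'
#' One row per specified cell with the full-precision recomputed ratio,
#' its printed-precision rendering, and the arrow call against the
#' table's reference sample. For ratio-only specs (input intensities
#' unpublished) the printed ratio itself is used for the arrow
#' computation.
#'
#' @param peaks allele-peak tibble covering the referenced samples.
#' @param table_spec list from [load_table_spec()].
#' @param no_change_band arrow band half-width.
#' @return tibble, one row per cell.
#' @export
build_ratio_table <- function(peaks, table_spec, no_change_band = 0.20) {
  cells <- table_spec$cells
  if (is.null(cells) || nrow(cells) == 0L) {
    return(tibble(sample = character(), assay = character(),
                  numerator = character(), denominator = character(),
                  ratio = numeric(), rendered = character(),
                  arrow = character()))
  }
  ratio_for <- function(smp, num, den) {
    if (table_spec$ratio_only) {
      i <- which(cells$sample == smp & cells$numerator == num &
                   cells$denominator == den)
      r <- if (length(i) == 1L) cells$printed_ratio[i] else NA_real_
      return(tibble(sample_label = smp, assay_name = table_spec$assay,
                    numerator_base = num, denominator_base = den,
                    numerator_intensity = NA_real_,
                    denominator_intensity = NA_real_, ratio = r))
    }
    sub <- peaks[peaks$sample_label == smp &
                   peaks$assay_name == table_spec$assay, ]
    if (nrow(sub) == 0L) {
      stop("peak fixture lacks sample/assay: ", smp, " / ",
           table_spec$assay, call. = FALSE)
    }
    intensity_ratio(sub, num, den)
  }
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    rec <- ratio_for(cl$sample, cl$numerator, cl$denominator)
    arrow <- glyph <- fold <- NA
    if (!is.na(table_spec$reference_sample) &&
        cl$sample != table_spec$reference_sample) {
      ref <- ratio_for(table_spec$reference_sample, cl$numerator,
                       cl$denominator)
      ch <- classify_change(rec, ref, no_change_band)
      arrow <- ch$arrow; glyph <- ch$glyph; fold <- ch$fold
    }
    ulp <- 0.5 * 10^(-cl$decimals)
    out[[i]] <- tibble(
      table = table_spec$name, sample = cl$sample,
      assay = table_spec$assay,
      numerator = cl$numerator, denominator = cl$denominator,
      numerator_intensity = rec$numerator_intensity,
      denominator_intensity = rec$denominator_intensity,
      ratio = rec$ratio,
      rendered = ifelse(is.na(rec$ratio), "―",
                        formatC(round(rec$ratio, cl$decimals),
                                format = "f", digits = cl$decimals)),
      fold = as.numeric(fold), arrow = as.character(arrow),
      glyph = as.character(glyph),
      printed_ratio = cl$printed_ratio,
      printed_arrow = cl$printed_arrow,
      known_mismatch = cl$known_mismatch,
      matches_printed =
        if (is.na(cl$printed_ratio)) is.na(rec$ratio)
        else !is.na(rec$ratio) &&
          abs(rec$ratio - cl$printed_ratio) <= ulp,
      inputs_consistent =
        if (is.na(cl$printed_num) || is.na(cl$printed_den) ||
            is.na(cl$printed_ratio)) NA
        else abs(cl$printed_num / cl$printed_den - cl$printed_ratio) <= ulp,
      arrow_matches_printed =
        if (is.na(cl$printed_arrow) || all(is.na(arrow))) NA
        else identical(unname(ARROW_GLYPHS[[arrow]]), cl$printed_arrow)
    )
  }
  bind_rows(out)
}
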