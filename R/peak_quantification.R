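# Allele-peak quantification with explicit missing-peak semantics.
#
# An allele-peak table is a tibble with columns
#   sample_label, assay_name, base, mass, intensity, status
# status: "CALLED", "NEGLIGIBLE" (low but ratio-eligible), "MISSING"
# (no peak; never divided downstream; intensity recorded as NA).

PEAK_STATUSES <- c("CALLED", "NEGLIGIBLE", "MISSING")

#' Peak-calling parameters
#'
#' @param mass_tolerance half-width (Da) of the window around each
#'   expected product mass; windows of different alleles must not
#'   overlap.
#' @param detection_threshold fraction of the strongest peak below which
#'   a peak is MISSING (spectra only).
#' @param negligible_threshold fraction below which a detected peak is
#'   NEGLIGIBLE rather than CALLED.
#' @return parameter list.
#' @export
peak_params <- function(mass_tolerance = 4, detection_threshold = 0.02,
                        negligible_threshold = 0.05) {
  stopifnot(mass_tolerance > 0,
            detection_threshold >= 0,
            negligible_threshold >= detection_threshold)
  list(mass_tolerance = mass_tolerance,
       detection_threshold = detection_threshold,
       negligible_threshold = negligible_threshold)
}

#' Call the four allele peaks of one assay from a spectrum
#'
#' Peak heights are recovered by unmixing the trace against the known
#' Gaussian peak shape at the expected product masses (least squares over
#' the grid points within 4 sigma of any expected mass). This removes
#' both grid discretisation and the small cross-contribution of
#' neighbouring peaks, so a noiseless simulated spectrum is recovered
#' exactly. Statuses are assigned relative to the strongest recovered
#' peak.
#'
#' @param spectrum a `sim_spectrum`.
#' @param assay one-row assay tibble (names the output).
#' @param expected_masses named numeric vector base -> Da (defaults to
#'   the assay's product masses).
#' @param params from [peak_params()].
#' @param sample_label label stored on the output rows.
#' @return allele-peak tibble (4 rows).
#' @export
call_allele_peaks <- function(spectrum, assay,
                              expected_masses = NULL,
                              params = peak_params(),
                              sample_label = NA_character_) {
  stopifnot(inherits(spectrum, "sim_spectrum"))
  masses <- expected_masses %||% spectrum$masses
  stopifnot(setequal(names(masses), DNA_BASES))
  masses <- masses[DNA_BASES]
  if (min(diff(sort(masses))) <= 2 * params$mass_tolerance) {
    stop("mass windows overlap: expected masses must be separated by ",
         "more than 2*mass_tolerance", call. = FALSE)
  }
  sigma <- spectrum$peak_sigma
  keep <- Reduce(`|`, lapply(masses, function(m) {
    abs(spectrum$mz - m) <= 4 * sigma
  }))
  X <- vapply(masses, function(m) {
    exp(-((spectrum$mz[keep] - m)^2) / (2 * sigma^2))
  }, numeric(sum(keep)))
  h <- stats::lsfit(X, spectrum$intensity[keep], intercept = FALSE)$coef
  h <- pmax(unname(h), 0)
  status <- peak_status(h, max(h),
                        params$detection_threshold,
                        params$negligible_threshold)
  tibble(sample_label = sample_label, assay_name = assay$name,
         base = DNA_BASES, mass = unname(masses),
         intensity = ifelse(status == "MISSING", NA_real_, h),
         status = status)
}

#' @noRd
peak_status <- function(h, ref, detect, negligible) {
  ifelse(h < detect * ref, "MISSING",
         ifelse(h < negligible * ref, "NEGLIGIBLE", "CALLED"))
}

#' Read an external allele-peak table (CSV)
#'
#' Columns: `sample`, `assay`, `base`, `intensity`. An intensity of
#' `"―"` (or `"-"`/empty) parses to MISSING. Numeric intensities are
#' CALLED, or NEGLIGIBLE when below `negligible_threshold` of the
#' strongest peak of the same sample and assay; instrument tables never
#' yield MISSING from a numeric value.
#'
#' @param csv_source path to a CSV file.
#' @param params from [peak_params()].
#' @return allele-peak tibble.
#' @export
read_peak_table <- function(csv_source, params = peak_params()) {
  df <- read.csv(csv_source, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty peak table: ", csv_source, call. = FALSE)
    return(tibble(sample_label = character(), assay_name = character(),
                  base = character(), mass = numeric(),
                  intensity = numeric(), status = character()))
  }
  stopifnot(all(c("sample", "assay", "base", "intensity") %in% names(df)))
  bad <- which(!(df$base %in% DNA_BASES))
  if (length(bad) > 0) {
    stop(sprintf("unknown base symbol '%s' in peak table row %d",
                 df$base[bad[1]], bad[1]), call. = FALSE)
  }
  missing_mark <- df$intensity %in% c("―", "-", "—", "", "NA")
  val <- suppressWarnings(as.numeric(df$intensity))
  bad_num <- which(!missing_mark & is.na(val))
  if (length(bad_num) > 0) {
    stop(sprintf("non-numeric intensity '%s' in peak table row %d",
                 df$intensity[bad_num[1]], bad_num[1]), call. = FALSE)
  }
  out <- tibble(sample_label = df$sample, assay_name = df$assay,
                base = df$base, mass = NA_real_, intensity = val)
  out %>%
    group_by(sample_label, assay_name) %>%
    mutate(status = ifelse(
      is.na(intensity), "MISSING",
      ifelse(intensity < params$negligible_threshold *
               max(intensity, na.rm = TRUE), "NEGLIGIBLE", "CALLED"))) %>%
    ungroup()
}

#' Packaged table of the published allele-peak intensities
#'
#' All printed per-peak intensities from the source tables ship as the
#' fixture `paper_peaks.csv` (samples: SFP pre/post ejection, SFP of
#' developmental failure, fully/semi-ejected ascospores).
#'
#' @inheritParams read_peak_table
#' @return allele-peak tibble.
#' @export
paper_peaks <- function(params = peak_params()) {
  read_peak_table(snpms_extdata("paper_peaks.csv"), params)
}
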