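# Configuration, pipeline drivers and the reproduce-tables entry point.

#' Load the packaged defaults (simulator presets, thresholds, contexts)
#'
#' @param path YAML file (defaults to the packaged `defaults.yaml`).
#' @return nested list.
#' @export
load_defaults <- function(path = snpms_extdata("defaults.yaml")) {
  yaml::yaml.load_file(path)
}

#' Validate and load a run configuration
#'
#' @param path YAML run config. Fields: `panel`, `peak_fixture`,
#'   `table_specs`, `seed`, `output_dir`, plus optional `defaults`
#'   overrides. All referenced paths must resolve.
#' @return validated config list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::yaml.load_file(path)
  cfg$panel <- cfg$panel %||% snpms_extdata("panel.yaml")
  cfg$peak_fixture <- cfg$peak_fixture %||% snpms_extdata("paper_peaks.csv")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed) || cfg$seed < 0L) {
    stop("config field 'seed' must be an integer >= 0", call. = FALSE)
  }
  for (f in c("panel", "peak_fixture")) {
    if (!file.exists(cfg[[f]])) {
      stop("config field '", f, "' does not resolve: ", cfg[[f]],
           call. = FALSE)
    }
  }
  cfg
}

#' @noRd
log_event <- function(event, data = list(), file = NULL) {
  if (is.null(file)) return(invisible(NULL))
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), data)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file, append = TRUE)
  invisible(NULL)
}

#' Table-spec fixture paths for the published ratio tables
#'
#' @param supplementary include the ratio-only supplementary specs.
#' @return named character vector of YAML paths.
#' @export
paper_table_specs <- function(supplementary = TRUE) {
  main <- paste0("table", 3:6, ".yaml")
  supp <- paste0("tableS", 3:6, ".yaml")
  files <- if (supplementary) c(main, supp) else main
  setNames(vapply(files, function(f) snpms_extdata("tables", f),
                  character(1)),
           sub("\\.yaml$", "", files))
}

#' Recompute every published intensity ratio and arrow call
#'
#' Rebuilds the published ratio tables from the packaged peak fixture
#' and table specs, comparing each computed ratio with the printed value
#' at its printed precision and each computed arrow with the printed
#' arrow. Cells flagged `known_mismatch` in the fixtures are the
#' documented internal inconsistencies of the source tables and are
#' counted separately, never silently overridden.
#'
#' @param strict_arrows if `TRUE`, attach the arrow-discrepancy rows.
#' @param peaks optional allele-peak tibble overriding the fixture.
#' @return list: `cells` (all rows), `summary` (counts), and optionally
#'   `arrow_discrepancies`.
#' @export
reproduce_tables <- function(strict_arrows = FALSE, peaks = NULL) {
  peaks <- peaks %||% paper_peaks()
  specs <- lapply(paper_table_specs(), load_table_spec)
  cells <- bind_rows(lapply(specs, function(sp) {
    build_ratio_table(peaks, sp)
  }))
  computable <- cells[!is.na(cells$printed_ratio), ]
  ok_ratio <- computable$known_mismatch != "ratio_inputs"
  n_match <- sum(computable$matches_printed[ok_ratio])
  arrows <- cells[!is.na(cells$printed_arrow) & !is.na(cells$arrow), ]
  ok_arrow <- arrows$known_mismatch != "arrow"
  summary <- tibble(
    n_cells = nrow(cells),
    n_computable = nrow(computable),
    n_ratio_checked = sum(ok_ratio),
    n_ratio_matched = n_match,
    n_known_ratio_mismatch = sum(!ok_ratio),
    n_known_ratio_mismatch_confirmed =
      sum(!computable$inputs_consistent[!ok_ratio], na.rm = TRUE),
    n_arrow_checked = sum(ok_arrow),
    n_arrow_matched = sum(arrows$arrow_matches_printed[ok_arrow],
                          na.rm = TRUE),
    n_known_arrow_mismatch = sum(!ok_arrow),
    all_matched = n_match == sum(ok_ratio))
  out <- list(cells = cells, summary = summary)
  if (strict_arrows) {
    out$arrow_discrepancies <-
      arrows[!arrows$arrow_matches_printed %in% TRUE, ]
  }
  out
}

#' Per-genotype allele sheet for a panel
#'
#' One row per (assay, genotype) with the predicted sense-strand allele
#' and the extension-product mass.
#'
#' @param registry a `genotype_registry`.
#' @param panel an `assay_panel`.
#' @return tibble.
#' @export
design_panel_sheet <- function(registry, panel) {
  preds <- predict_panel_alleles(registry, panel)
  preds$mass <- NA_real_
  for (i in seq_len(nrow(preds))) {
    if (preds$allele[i] == "NONE") next
    assay <- get_assay(panel, preds$assay_name[i])
    preds$mass[i] <- assay_product_masses(assay)[[preds$allele[i]]]
  }
  preds
}

#' Simulate one sample through the full two-step pipeline
#'
#' For each requested assay: first-step PCR under the assay's feeding
#' primer pair and the bias preset, extension-spectrum rendering, and
#' allele-peak calling.
#'
#' @param sample_label name of a mixture preset in the defaults (or
#'   supply `mixture`).
#' @param assays assay names to run (default: all five).
#' @param seed integer seed.
#' @param registry optional pre-built registry (rebuilt from the
#'   defaults generator settings otherwise).
#' @param mixture optional `mixture_spec` overriding the preset.
#' @param defaults list from [load_defaults()].
#' @param noise optional [noise_params()] override.
#' @param log_file optional JSON-lines log path.
#' @return list: `peaks` (named by assay), `spectra`, `pools`, `truth`,
#'   `registry`, `mixture`.
#' @export
simulate_sample <- function(sample_label, assays = NULL, seed = 1L,
                            registry = NULL, mixture = NULL,
                            defaults = load_defaults(), noise = NULL,
                            log_file = NULL) {
  panel <- load_paper_panel()
  assays <- assays %||% panel$assays$name
  gen <- defaults$generator
  if (is.null(registry)) {
    registry <- generate_genotype_sequences(
      length = gen$length, gc_ref = gen$gc_ref,
      n_transitions = gen$n_transitions,
      n_transversions_gc = gen$n_transversions_gc, seed = seed)
  }
  if (is.null(mixture)) {
    ab <- defaults$mixtures[[sample_label]]
    if (is.null(ab)) stop("no mixture preset named ", sample_label,
                          call. = FALSE)
    mixture <- mixture_spec(sample_label, unlist(ab))
  }
  noise <- noise %||% noise_params(
    intensity_scale = defaults$noise$intensity_scale,
    peak_sigma = defaults$noise$peak_sigma,
    baseline_sd = defaults$noise$baseline_sd_frac *
      defaults$noise$intensity_scale,
    mz_step = defaults$noise$mz_step)
  bias <- paper_bias_preset(panel, registry)
  pparams <- peak_params(
    mass_tolerance = defaults$noise$mass_tolerance,
    detection_threshold = defaults$thresholds$detection_frac,
    negligible_threshold = defaults$thresholds$negligible_frac)
  log_event("simulate_sample_start",
            list(sample = sample_label, seed = seed,
                 thresholds = defaults$thresholds), file = log_file)
  pools <- spectra <- peaks <- truth <- list()
  for (an in assays) {
    assay <- get_assay(panel, an)
    pair <- assay$feeding_pairs[[1]][1]
    pool <- simulate_first_pcr(mixture, pair, bias)
    spec <- suppressWarnings(simulate_extension_spectrum(
      pool, assay, registry, noise,
      seed = seed + match(an, panel$assays$name)))
    pk <- call_allele_peaks(spec, assay, params = pparams,
                            sample_label = sample_label)
    pools[[an]] <- pool; spectra[[an]] <- spec; peaks[[an]] <- pk
    truth[[an]] <- spec$truth
    log_event("assay_done", list(assay = an, pair = pair), file = log_file)
  }
  list(sample_label = sample_label, peaks = peaks, spectra = spectra,
       pools = pools, truth = truth, registry = registry,
       mixture = mixture)
}

#' Stratified inference on a simulated sample context
#'
#' Convenience wrapper binding [simulate_sample()] output to the
#' context's presence constraints and stratification plan from the
#' packaged defaults.
#'
#' @param sample_label mixture preset name.
#' @param context_name `"SFP"` or `"ascospore"` (keys of the defaults'
#'   `contexts`).
#' @param seed integer seed.
#' @param defaults list from [load_defaults()].
#' @param sim optional pre-computed [simulate_sample()] result.
#' @return [stratify()] result plus the simulation under `$sim`.
#' @export
stratify_sample <- function(sample_label, context_name, seed = 1L,
                            defaults = load_defaults(), sim = NULL) {
  ctx_def <- defaults$contexts[[context_name]]
  if (is.null(ctx_def)) stop("unknown context: ", context_name,
                             call. = FALSE)
  plan <- unlist(ctx_def$plan)
  sim <- sim %||% simulate_sample(sample_label, assays = plan,
                                  seed = seed, defaults = defaults)
  ctx <- sample_context(sample_label, unlist(ctx_def$allowed),
                        sim$peaks[plan])
  params <- attribution_params(
    constraint_tol = defaults$thresholds$constraint_tol,
    absent_cutoff = defaults$thresholds$absent_cutoff,
    high_cutoff = defaults$thresholds$high_cutoff)
  res <- stratify(plan, ctx, load_paper_panel(), sim$registry, params)
  res$sim <- sim
  res
}

#' Truth intensity ratio of two alleles in a simulated assay
#'
#' @param sim result of [simulate_sample()].
#' @param assay_name assay.
#' @param numerator,denominator bases.
#' @return numeric ratio (NA when the denominator truth is zero).
#' @export
truth_ratio <- function(sim, assay_name, numerator, denominator) {
  tr <- sim$truth[[assay_name]]
  if (is.null(tr) || tr[[denominator]] == 0) return(NA_real_)
  tr[[numerator]] / tr[[denominator]]
}
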