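# Stratified genotype attribution.
#
# Each assay's called allele peaks, normalized within-assay, constrain
# the genotype shares of the amplicon pool linearly: the fraction of an
# allele peak equals the summed shares of the genotypes mapping to it.
# The system is typically underdetermined (alleles are shared by
# genotype sets), so each genotype group's contribution is reported as
# an exact share interval [lo, hi] over the feasible polytope, computed
# by linear programming, rather than as a point estimate.

#' Attribution parameters
#'
#' @param constraint_tol allowed deviation between an observed allele
#'   fraction and the summed genotype shares (measurement slack).
#' @param infeasible_tol deviation beyond which the constraint system is
#'   reported as inconsistent.
#' @param absent_cutoff,high_cutoff qualitative level cutoffs applied to
#'   the upper bound: hi < absent_cutoff is ABSENT, hi < high_cutoff is
#'   LOW, otherwise HIGH. Verbal levels in the source study carry no
#'   numbers; these are package defaults and config-overridable.
#' @return parameter list.
#' @export
attribution_params <- function(constraint_tol = 0.02,
                               infeasible_tol = 0.10,
                               absent_cutoff = 0.05,
                               high_cutoff = 0.25) {
  stopifnot(constraint_tol >= 0, infeasible_tol >= constraint_tol,
            absent_cutoff < high_cutoff)
  list(constraint_tol = constraint_tol, infeasible_tol = infeasible_tol,
       absent_cutoff = absent_cutoff, high_cutoff = high_cutoff)
}

#' Build a sample context
#'
#' @param sample_label sample name.
#' @param allowed_genotypes genotype ids assumed present (presence
#'   constraints from companion qualitative evidence; config input).
#' @param assay_peaks named list assay_name -> allele-peak tibble.
#' @return `sample_context` list.
#' @export
sample_context <- function(sample_label, allowed_genotypes, assay_peaks) {
  stopifnot(length(allowed_genotypes) > 0, is.list(assay_peaks))
  structure(list(sample_label = sample_label,
                 allowed_genotypes = allowed_genotypes,
                 assay_peaks = assay_peaks),
            class = "sample_context")
}

#' @noRd
assay_constraints <- function(context, panel, registry) {
  cons <- list()
  residuals <- list()
  for (an in names(context$assay_peaks)) {
    assay <- get_assay(panel, an)
    peaks <- context$assay_peaks[[an]]
    map <- allele_to_genotype_map(assay, registry,
                                  context$allowed_genotypes)
    nonmissing <- peaks[peaks$status != "MISSING", ]
    explained <- nonmissing[vapply(nonmissing$base,
                                   function(b) length(map[[b]]) > 0,
                                   logical(1)), ]
    tot_all <- sum(nonmissing$intensity)
    tot <- sum(explained$intensity)
    residuals[[an]] <- tibble(
      assay_name = an,
      unexplained_fraction = if (tot_all > 0) 1 - tot / tot_all else NA_real_)
    if (nrow(explained) == 0L || tot <= 0) next
    for (i in seq_len(nrow(explained))) {
      b <- explained$base[i]
      cons[[length(cons) + 1L]] <- list(
        assay_name = an, base = b, members = map[[b]],
        fraction = explained$intensity[i] / tot)
    }
  }
  list(constraints = cons, residuals = bind_rows(residuals))
}

#' @noRd
share_bounds_lp <- function(objective_members, universe, cons, tol) {
  n <- length(universe)
  tol <- max(tol, 1e-7)  # exact equalities degenerate the simplex tableau
  a <- as.numeric(universe %in% objective_members)
  # a constraint spanning the whole universe duplicates the simplex
  # equality (fractions sum to 1) and degenerates the LP; drop it
  cons <- Filter(function(cn) !setequal(cn$members, universe), cons)
  if (length(cons) == 0L) {
    lo <- if (setequal(objective_members, universe)) 1 else 0
    return(c(lo = lo, hi = if (length(objective_members) > 0) 1 else 0))
  }
  A1 <- NULL; b1 <- NULL  # <=
  A2 <- NULL; b2 <- NULL  # >=
  for (cn in cons) {
    row <- as.numeric(universe %in% cn$members)
    A1 <- rbind(A1, row); b1 <- c(b1, min(1, cn$fraction + tol))
    A2 <- rbind(A2, row); b2 <- c(b2, max(0, cn$fraction - tol))
  }
  A3 <- matrix(1, 1, n); b3 <- 1
  res_lo <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                          A3 = A3, b3 = b3, maxi = FALSE)
  res_hi <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                          A3 = A3, b3 = b3, maxi = TRUE)
  if (res_lo$solved < 0 || res_hi$solved < 0) return(NULL)
  c(lo = max(0, res_lo$value), hi = min(1, res_hi$value))
}

#' Attribute allele peaks to genotype groups with share intervals
#'
#' Treats each assay's allele fractions as linear constraints on the
#' genotype shares of the amplicon pool (restricted to the context's
#' allowed genotypes), and reports for every distinguishable genotype
#' group the exact interval of shares compatible with all assays, plus a
#' qualitative level (ABSENT / LOW / HIGH) from the interval's upper
#' bound. Genotypes with identical allele patterns across all assays are
#' merged into one group. Peaks mapping to no allowed genotype (e.g.
#' unknown-flank transversion alleles outside the context) are reported
#' as per-assay unexplained intensity.
#'
#' @param context a `sample_context`.
#' @param panel an `assay_panel`.
#' @param registry a `genotype_registry`.
#' @param params from [attribution_params()].
#' @return list with `groups`, `genotypes` and `residuals` tibbles, plus
#'   the `universe` of constrained genotype ids.
#' @export
attribute_peaks <- function(context, panel, registry,
                            params = attribution_params()) {
  built <- assay_constraints(context, panel, registry)
  cons <- built$constraints
  if (length(cons) == 0L) {
    stop("no usable allele constraints in context ", context$sample_label,
         call. = FALSE)
  }
  universe <- sort(unique(unlist(lapply(cons, `[[`, "members"))))
  # feasibility at the reporting tolerance, then at the infeasibility cap
  if (is.null(share_bounds_lp(universe, universe, cons,
                              params$constraint_tol))) {
    if (is.null(share_bounds_lp(universe, universe, cons,
                                params$infeasible_tol))) {
      stop("infeasible constraint system (beyond tolerance ",
           params$infeasible_tol, ") across assays: ",
           paste(unique(vapply(cons, `[[`, character(1), "assay_name")),
                 collapse = ", "), call. = FALSE)
    }
    warning("constraints satisfiable only beyond constraint_tol; ",
            "intervals computed at infeasible_tol", call. = FALSE)
    params$constraint_tol <- params$infeasible_tol
  }
  # group genotypes by identical membership signature
  sig <- vapply(universe, function(g) {
    paste(vapply(cons, function(cn) g %in% cn$members, logical(1)),
          collapse = "")
  }, character(1))
  groups <- split(universe, sig)
  level_of <- function(hi) {
    if (hi < params$absent_cutoff) "ABSENT"
    else if (hi < params$high_cutoff) "LOW" else "HIGH"
  }
  group_rows <- list(); geno_rows <- list()
  for (members in groups) {
    b <- share_bounds_lp(members, universe, cons, params$constraint_tol)
    group_rows[[length(group_rows) + 1L]] <- tibble(
      group = paste(members, collapse = "+"),
      members = list(members), lo = b[["lo"]], hi = b[["hi"]],
      level = level_of(b[["hi"]]))
  }
  for (g in universe) {
    b <- share_bounds_lp(g, universe, cons, params$constraint_tol)
    geno_rows[[length(geno_rows) + 1L]] <- tibble(
      genotype_id = g, lo = b[["lo"]], hi = b[["hi"]],
      level = level_of(b[["hi"]]))
  }
  list(sample_label = context$sample_label,
       universe = universe,
       groups = bind_rows(group_rows) %>% arrange(group),
       genotypes = bind_rows(geno_rows),
       residuals = built$residuals)
}

#' Run an ordered stratification plan
#'
#' Applies the assays of the plan cumulatively, re-attributing after
#' each step and recording how each step splits the allele-sharing
#' genotype groups (group sizes before/after). Assays without peaks in
#' the sample are skipped with a warning.
#'
#' @param plan character vector of assay names, in assay order.
#' @param context a `sample_context` (peaks for all plan assays).
#' @param panel an `assay_panel`.
#' @param registry a `genotype_registry`.
#' @param params from [attribution_params()].
#' @return list with per-step results (`steps`), the final attribution
#'   (`final`), and a character `narrative`.
#' @export
stratify <- function(plan, context, panel, registry,
                     params = attribution_params()) {
  steps <- list()
  narrative <- character(0)
  used <- character(0)
  if (length(plan) == 0L) {
    return(list(steps = list(), final = NULL, narrative = character(0)))
  }
  prev_groups <- NULL
  for (an in plan) {
    if (is.null(context$assay_peaks[[an]])) {
      warning("plan assay ", an, " has no peaks in sample ",
              context$sample_label, "; step skipped", call. = FALSE)
      next
    }
    used <- c(used, an)
    sub_ctx <- sample_context(context$sample_label,
                              context$allowed_genotypes,
                              context$assay_peaks[used])
    att <- attribute_peaks(sub_ctx, panel, registry, params)
    n_groups_before <- if (is.null(prev_groups)) 1L else nrow(prev_groups)
    narrative <- c(narrative, sprintf(
      "step %d (%s): %d genotype group(s): %s", length(used), an,
      nrow(att$groups),
      paste(sprintf("%s %s [%.2f, %.2f]", att$groups$group,
                    att$groups$level, att$groups$lo, att$groups$hi),
            collapse = "; ")))
    steps[[an]] <- list(assay = an, attribution = att,
                        n_groups_before = n_groups_before,
                        n_groups_after = nrow(att$groups))
    prev_groups <- att$groups
  }
  if (length(used) == 0L) {
    return(list(steps = list(), final = NULL, narrative = character(0)))
  }
  list(steps = steps, final = steps[[length(steps)]]$attribution,
       narrative = narrative)
}

#' Level of a genotype group in an attribution result
#'
#' @param attribution result of [attribute_peaks()].
#' @param members genotype ids making up the group (order-free).
#' @return the group's qualitative level, or NA if no such group.
#' @export
group_level <- function(attribution, members) {
  hit <- vapply(attribution$groups$members, setequal, logical(1),
                y = members)
  if (!any(hit)) return(NA_character_)
  attribution$groups$level[hit][1]
}
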