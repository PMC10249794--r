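# Independent oracles used to freeze expected values.

# Elemental-composition oligo mass oracle: average masses of the free
# deoxynucleoside monophosphates from IUPAC atomic weights, condensation
# water removed per bond, 5'-phosphate replaced by hydroxyl (- HPO3).
oracle_oligo_mass <- function(sequence) {
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)
  formula <- list(  # free dNMP molecular formulas
    A = c(C = 10, H = 14, N = 5, O = 6, P = 1),
    C = c(C = 9,  H = 14, N = 3, O = 7, P = 1),
    G = c(C = 10, H = 14, N = 5, O = 7, P = 1),
    T = c(C = 10, H = 15, N = 2, O = 8, P = 1)
  )
  dnmp <- vapply(formula, function(f) sum(f * aw[names(f)]), numeric(1))
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  h2o <- sum(c(H = 2, O = 1) * aw[c("H", "O")])
  hpo3 <- sum(c(H = 1, P = 1, O = 3) * aw[c("H", "P", "O")])
  sum(dnmp[ch]) - (n - 1) * h2o - hpo3
}

# brute-force per-base GC count
oracle_gc <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  ch <- ch[ch != "N"]
  n_gc <- 0
  for (b in ch) if (b == "G" || b == "C") n_gc <- n_gc + 1
  n_gc / length(ch)
}

# exhaustive grid enumeration oracle for share intervals: all
# compositions of `step_n` grid steps over n genotypes, filtered by the
# allele-fraction constraints, min/max per genotype.
oracle_grid_bounds <- function(universe, cons, tol, step = 0.01) {
  n <- length(universe)
  step_n <- round(1 / step)
  if (n == 1) {
    grid <- matrix(step_n, ncol = 1)
  } else {
    free <- do.call(expand.grid, rep(list(0:step_n), n - 1))
    free <- as.matrix(free[rowSums(free) <= step_n, , drop = FALSE])
    grid <- cbind(free, step_n - rowSums(free))
  }
  keep <- rep(TRUE, nrow(grid))
  for (cn in cons) {
    idx <- match(cn$members, universe)
    s <- if (length(idx) == 1) grid[, idx] else rowSums(grid[, idx,
                                                             drop = FALSE])
    keep <- keep & abs(s / step_n - cn$fraction) <= tol + 1e-9
  }
  feas <- grid[keep, , drop = FALSE]
  if (nrow(feas) == 0) return(NULL)
  t(vapply(seq_len(n), function(j) {
    c(lo = min(feas[, j]) / step_n, hi = max(feas[, j]) / step_n)
  }, numeric(2)))
}

# random small constraint system built from an on-grid ground truth
random_constraint_system <- function(n_genotypes, n_assays) {
  universe <- paste0("g", seq_len(n_genotypes))
  w <- rgamma(n_genotypes, 2) + 0.2
  truth <- drop(rmultinom(1, 100, w / sum(w))) / 100
  cons <- list()
  for (a in seq_len(n_assays)) {
    k <- sample(2:min(4, n_genotypes), 1)
    blocks <- split(universe, sample(rep_len(seq_len(k), n_genotypes)))
    for (b in blocks) {
      cons[[length(cons) + 1]] <- list(
        assay_name = paste0("a", a), base = "X", members = b,
        fraction = sum(truth[match(b, universe)]))
    }
  }
  list(universe = universe, truth = truth, cons = cons)
}
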