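---
title: "Methods: semi-quantitative SNP mass-spectrometry genotyping of mixed ITS genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative SNP mass-spectrometry genotyping of mixed ITS genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpms)
```

## The measurement model

Natural *Cordyceps sinensis* compartments harbour several coexisting
ITS1-5.8S-ITS2 genotypes of *Ophiocordyceps sinensis*: a GC-biased clade
(Genotype #1, *H. sinensis*, and relatives) and AT-biased genotypes that
differ from it by many scattered transition point mutations, falling into
two phylogenetic clusters (Cluster-A: #5, #6, #16, #17; Cluster-B: #4,
#15). `snpms` models the iPLEX-style two-step assay used to profile such
mixtures semi-quantitatively:

1. **First-step PCR.** A primer pair amplifies the ITS region from the
   metagenomic template. Pairs are *biased*: the Hsprp pairs favour
   GC-biased templates, the P pairs favour AT-biased templates. We model
   this as a single multiplicative gain per (pair, genotype-clade):
   amplicon pool fraction ∝ template fraction × gain, renormalized. The
   underlying study asserts only the *direction* of the bias; the default
   4:1 magnitude is a package preset, stored in `defaults.yaml`.
2. **Single-base extension.** An extension primer anneals immediately
   adjacent to a diagnostic SNP and is extended by exactly one
   chain-terminating ddNTP; the incorporated terminator identifies the
   template's allele and the extension product's mass identifies the
   terminator in a MALDI-TOF spectrum. The noiseless intensity of each
   allele peak is the summed pool fraction of the genotypes carrying that
   allele (times an arbitrary intensity scale). Alleles are always
   reported on the sense strand: for the two reverse-complement assays the
   physically extended base is the complement of the reported one.
3. **Internal-reference ratios.** Absolute intensities are not
   comparable across spectra, but within one spectrum the ratio of two
   allele peaks is a meaningful semi-quantitative statistic. Ratios for
   the same assay and allele pair are then compared *across* samples as a
   fold change, binned with the arrow convention: no change within a
   symmetric 20% band of 1, then <2-fold, 2–3-fold, 3–4-fold and >4-fold
   (half-open bins `[2,3)` etc.), upward or downward. Every positive fold
   maps to exactly one bin.

The five packaged extension assays are named
`<reference accession>-<1-based SNP position>`: `067721-477` and
`067721-531` separate the GC clade (extended G) from all AT-biased
genotypes (extended A, a G→A transition); `067740-328` splits off
Cluster-B Genotype #4 (C vs T); `067744-324` then separates Genotype #5
(C) from #4/#6/#15 (T); `067740-324` separates #5/#17 (C) from
#4/#6/#15/#16 (T). Side peaks at the remaining bases are transversion
alleles from templates of unknown flanking sequence; the package carries
them as first-class `UNKNOWN_TRANSVERSION` registry records.

One published orientation ambiguity had to be resolved: `067740-324` is
listed without a reverse-complement tag and its spectra are described as
direct extension, so the package models it as a sense assay.

## Extension-product masses

Only *relative* separations matter for peak identity, so the package uses
the standard neutral average-mass convention for a 5'-OH oligo: the sum of
per-base residue masses (dA 313.21, dC 289.18, dG 329.21, dT 304.20 Da)
minus 61.96 Da, with a dideoxy terminator residue weighing 16.00 Da less
than the deoxy residue. The unit tests check this against an independent
elemental-composition oracle (free-dNMP formulas and IUPAC atomic
weights, condensation water removed per bond). Terminator increments
order ddC < ddT < ddA < ddG and the closest allelic products (ddA vs ddT)
sit 9.0 Da apart, which fixes the resolvability requirements below.
Commercial terminator cocktails carry proprietary mass tags that are not
modelled; masses here are internal bookkeeping, never reported results.

## The synthetic registry

No raw sequences or spectra were published, so the `synthetic_data`
module generates stand-ins that preserve exactly the structure the
analysis depends on:

* a 600-nt GC-biased reference (default 62% GC, the Genotype #1 stand-in)
  carrying all five extension-primer footprints and the reference alleles
  at fixed template columns (477, 531, 324, 328, and 360);
* AT-biased stand-ins derived from it by **transition-only** point
  mutations: the deterministic allele plants (e.g. G→A at 477), repairs
  of the AT-assay primer footprints (the extension primers for the AT
  markers were designed on AT-biased sequences, so the GC reference
  carries transition-mutated variants of those footprints and correctly
  reports "site absent" under exact-match primer search), plus 30
  scattered random C→T/G→A transitions per genotype. This drops their GC
  content by roughly 7 percentage points, comfortably beyond the 0.03
  GC-deficit used by `classify_bias()` (a package stand-in for the
  study's verbal GC/AT-bias labels, defined relative to Genotype #1);
* indel structure where coordinates require it: the #4 stand-in carries a
  36-nt deletion upstream of its assay site so that the master column 360
  is position 324 in its own 1-based coordinates (mirroring how indels
  shift coordinates between the real reference accessions), and the #6
  stand-in is terminally truncated (its real sequence is short at both
  ends);
* GC-clade relatives (#2, #3, #7–#14) with a few transversions, matching
  the observation that GC-biased variants differ by indels and
  transversions rather than transitions;
* unknown-flank transversion templates: random 450-nt flanks carrying one
  assay's footprint and a transversion allele at its site only.

Generation is deterministic under a fixed seed, verifies every planted
allele against the intended per-assay table (with a retry budget in case
a random draw corrupts a footprint), and records the planted transition
counts so that `mutation_profile()` can be tested against generator
bookkeeping. Pairwise coordinate maps come from global
`Biostrings::pairwiseAlignment` (match 1, mismatch −1, gap −2).

What the generator does *not* emulate: polymerase error, chimeras,
per-cycle exponential amplification, adduct/salt peaks, well effects, and
per-assay extension efficiency. Passing tests therefore demonstrate the
correctness of the analysis pipeline on data with the study's structure,
not instrument-level realism.

## Spectrum simulation and peak quantification

Spectra are rendered as Gaussians of width `peak_sigma` (default 2 Da) at
the four product masses on an m/z grid (default step 0.02 Da), plus
i.i.d. Gaussian baseline noise (default sd 1% of the intensity scale),
clamped at zero. Peaks closer than 3σ raise a merged-peak warning.

Quantification recovers the four peak heights by **linear unmixing**: a
least-squares fit of the trace (grid points within 4σ of any expected
mass) against the known Gaussian shapes at the expected masses. This is
preferred over reading the raw grid apex because it removes both grid
discretisation error and the small cross-contribution of neighbouring
peaks (about 4×10⁻⁵ of a neighbour at 9 Da separation with σ = 2), making
the zero-noise closed loop exact to machine precision and the noisy
recovery nearly efficient: the standard error of a recovered height is
baseline_sd / ‖g‖ ≈ 0.075% of the intensity scale at the default grid.
Relative error therefore scales inversely with peak height — peaks near
the detection limit carry proportionally larger ratio errors, which is
why the recovery property is exercised on mixtures whose components stay
well above it.

Statuses follow a three-way rule relative to the strongest peak:
below 2% → `MISSING` (never divided downstream), 2–5% → `NEGLIGIBLE`
(low but ratio-eligible — the published tables divide by peaks as small
as 0.4 and 0.5), otherwise `CALLED`. External instrument peak tables are
taken as-is (apex values, no baseline subtraction): `"―"` parses to
`MISSING`, and numeric values are never demoted to `MISSING`.

## Reproducing the published ratio tables

All printed per-peak intensities ship in `paper_peaks.csv`, and each
published table is described by a YAML spec holding the printed ratio,
inputs, decimal precision and arrow per cell. `reproduce_tables()`
recomputes every cell and compares at printed precision (|computed −
printed| ≤ 0.5 ulp of the printed decimals). Three cells are internally
inconsistent in the source and are flagged `known_mismatch` rather than
absorbed:

* the semi-ejected ascospore G:A cell prints ratio 2.2 with inputs
  6.7÷3.2 = 2.09; the same sample's G:T row prints G = 6.9 and
  6.9÷3.2 = 2.16 *does* round to 2.2, so the peak fixture carries 6.9 and
  the printed 6.7 input is treated as the typo;
* two cells print an increase arrow ("↑") although their folds (~1.17
  and ~1.19) lie inside the stated 20% no-change band. The package
  applies the stated rule and reports the discrepancy
  (`strict_arrows = TRUE`), never silently overriding either side.

Supplementary tables whose input intensities were never published are
carried as ratio-only specs.

## Stratified attribution

Presence constraints (which genotypes can occur in a sample type) come
from companion qualitative evidence and are always config input — e.g.
Cluster-A #16/#17 absent in stromal fertile portions (SFPs), Cluster-B
#4/#15 absent in ascospores. Within a context, each assay's called peak
intensities are normalized within-assay (different first-step pairs feed
different assays, so cross-assay intensities are not commensurable) and
interpreted as linear constraints: allele fraction = Σ shares of the
genotypes mapping to that allele, within a slack `constraint_tol`
(default 0.02). Peaks mapping to no allowed genotype (the unknown-flank
transversion alleles) are reported as per-assay unexplained intensity.

Because allele sets overlap, the system is usually underdetermined. The
package reports, for every distinguishable genotype group, the exact
interval of shares compatible with all constraints. The bounds are
computed as minimum/maximum of the group share over the feasible polytope
by linear programming (`boot::simplex`), which gives the same honest
"identifiability interval" semantics as iterative interval propagation
but is exact for overlapping systems; tests compare the bounds against a
brute-force grid-enumeration oracle at step 0.01. Grid enumeration is
combinatorially infeasible above four genotypes at that step (~10⁸ grid
points at six), so oracle comparisons use systems of two to four
genotypes and up to four assays; larger systems are covered by
property-based checks (adding assays never widens intervals, intervals
bracket ground truth). Qualitative levels derive from the interval's
upper bound: ABSENT below 0.05, LOW below 0.25, HIGH otherwise — package
cutoffs standing in for the study's verbal levels, overridable in config.

A structural caveat: Genotypes #6 and #15 carry identical alleles at all
five assays, so no plan can separate them; they are reported as a merged
group (exactly how the source discusses its "Peak T" component), and the
width-≤-2×tol interval guarantee applies only to identifiable groups.
`stratify()` applies an ordered assay plan cumulatively — for SFPs,
`067740-328` first isolates #4, then `067744-324` splits #5 from
{#6, #15}; for ascospores, `067740-324` splits #5 from {#6, #16} — and
records how each step refines the grouping.

## Mixture presets

Template abundances per sample were never published (the study explicitly
cautions that intensities do not reflect copy numbers), so the packaged
presets in `defaults.yaml` were derived once, algebraically, from the
published intensity ratios under the 4:1 bias preset: e.g. for the
pre-ejection SFP, C:T = 0.71 at `067744-324` and T:C = 14.1 at
`067740-328` fix the AT-pool proportions of #4, #5 and {#6 + #15}. They
are illustrative stand-ins, not estimates. Because per-assay extension
efficiency is not modelled, one mixture cannot reproduce both the
`067721-477` G:A ratio (3.3) and the `067721-531` G:A ratio (1.06); the
presets follow the assays the stratified analysis uses.

## Numerical choices and problem sizes

* m/z grid step 0.02 Da over the product-mass range ± 25 Da (a few
  thousand points per spectrum); Gaussian σ 2 Da; mass-tolerance windows
  4 Da (must not overlap: expected masses are ≥ 9 Da apart).
* Negative unmixed heights are clamped to zero; ties in status
  classification resolve upward (a peak exactly at a threshold takes the
  higher status).
* LP bounds: constraint tolerances below 10⁻⁷ are floored to avoid a
  degenerate simplex tableau; constraints spanning the entire genotype
  universe duplicate the simplex-sum equality and are dropped.
* Infeasibility beyond tolerance 0.1 raises a report naming the
  conflicting assays; between `constraint_tol` and 0.1 the intervals are
  computed at the relaxed tolerance with a warning.
* Test/acceptance problem sizes: 100 seeded noisy replicates for ratio
  recovery (three AT assays each), 50 random constraint systems against
  the grid oracle, full five-assay zero-noise closed loops, and the five
  packaged sample presets for the stratification contrasts; the whole
  suite runs in well under a minute of CPU.

## Known limitations

* Semi-quantitative by design: shares refer to the biased amplicon pool,
  not organismal biomass; the bias preset magnitude is conventional.
* GC-clade Genotypes #13–#14 (segmentally recombinant ITS) are outside
  the assay system's reach, as in the source study, and no assay here
  addresses them.
* External spectra (vendor formats) are not parsed; external data enter
  as peak tables.
* Attribution intervals reflect identifiability only, not statistical
  uncertainty from peak noise.
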