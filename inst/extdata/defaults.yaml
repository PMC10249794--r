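# Package defaults: synthetic-sequence generator settings, spectrum
# noise/rendering, peak/attribution thresholds, amplification-bias
# preset magnitudes, sample presence contexts with their stratification
# plans, and illustrative template-mixture presets.
#
# Template abundances per sample were never published (peak intensities
# do not reflect copy numbers); the mixture presets below were derived
# algebraically from the published intensity ratios under the 4:1 bias
# preset and are illustrative study-condition stand-ins, not estimates.
# Weights are relative; the package normalizes them to fractions.

generator:
  length: 600
  gc_ref: 0.62
  n_transitions: 30
  n_transversions_gc: 3
  unknown_flank_length: 450

noise:
  intensity_scale: 10.0
  peak_sigma: 2.0          # Da; allelic products are >= 9 Da apart
  baseline_sd_frac: 0.01   # of intensity_scale
  mz_step: 0.02            # Da
  mass_tolerance: 4.0      # Da peak-window half-width

thresholds:
  detection_frac: 0.02     # of strongest peak: below -> MISSING
  negligible_frac: 0.05    # below -> NEGLIGIBLE (still ratio-eligible)
  constraint_tol: 0.02     # allele-fraction slack in attribution
  absent_cutoff: 0.05      # interval hi below -> ABSENT
  high_cutoff: 0.25        # interval hi at/above -> HIGH
  no_change_band: 0.20     # arrow "no change" half-width

bias_preset:               # multiplicative first-PCR gains by clade
  gc_favoring: {GC: 4, AT: 1, UNKNOWN: 1}
  at_favoring: {GC: 1, AT: 4, UNKNOWN: 1}

contexts:
  SFP:                     # Cluster-A #16-#17 absent in SFPs
    allowed: ["#1", "#4", "#5", "#6", "#15"]
    plan: ["067740-328", "067744-324"]
  ascospore:               # Cluster-B #4/#15 and #17 absent in ascospores
    allowed: ["#1", "#5", "#6", "#16"]
    plan: ["067740-328", "067740-324"]

mixtures:
  SFP_pre:
    "#1": 0.825
    "#4": 0.066
    "#5": 0.293
    "#6": 0.330
    "#15": 0.310
    U_477_C: 0.750
    U_477_T: 1.000
    U_531_T: 0.200
    U_740324_A: 0.050
    U_740324_G: 0.030
    U_744324_A: 0.257
    U_744324_G: 0.000
    U_740328_A: 0.336
    U_740328_G: 0.100
  SFP_post:
    "#1": 0.821
    "#4": 0.0684
    "#5": 1.000
    "#6": 0.013
    "#15": 0.013
    U_477_C: 0.156
    U_477_T: 0.353
    U_531_T: 0.000
    U_740324_A: 0.050
    U_740324_G: 0.030
    U_744324_A: 0.528
    U_744324_G: 0.0755
    U_740328_A: 0.164
    U_740328_G: 0.050
  SFP_failure:
    "#1": 1.039
    "#4": 0.0627
    "#5": 1.000
    "#6": 0.0017
    "#15": 0.0017
    U_477_C: 0.000
    U_477_T: 0.416
    U_531_T: 0.000
    U_740324_A: 0.050
    U_740324_G: 0.030
    U_744324_A: 0.471
    U_744324_G: 0.000
    U_740328_A: 0.200
    U_740328_G: 0.000
  ascospore_full:
    "#1": 0.625
    "#5": 0.408
    "#6": 0.350
    "#16": 0.242
    U_477_C: 0.000
    U_477_T: 0.167
    U_531_T: 0.000
    U_740324_A: 0.180
    U_740324_G: 0.106
    U_744324_A: 0.050
    U_744324_G: 0.000
    U_740328_A: 0.286
    U_740328_G: 0.020
  ascospore_semi:
    "#1": 0.550
    "#5": 0.565
    "#6": 0.260
    "#16": 0.175
    U_477_C: 0.000
    U_477_T: 0.159
    U_531_T: 0.000
    U_740324_A: 0.156
    U_740324_G: 0.124
    U_744324_A: 0.050
    U_744324_G: 0.000
    U_740328_A: 0.182
    U_740328_G: 0.020
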