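#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated list.
#' Defaults follow the published analysis protocol: variants kept when seen in
#' fewer than 10% of samples, read-support thresholds of 10 (both callers) /
#' 20 (single caller), population minor allele frequency below 1% in all three
#' databases, a 15% minimum group size for every survival dichotomization,
#' two-sided alpha 0.05, 5-voxel mask dilation, isotropic 2 mm analysis grid
#' (4 mm available), 32-bin fixed-bin-number discretization, and 100-fold
#' Monte Carlo cross-validation with an 80:20 split against overall-survival
#' targets at 24 months, the cohort median, and 36 months.
#'
#' @param cohort_freq_max Variants carried by at least this fraction of
#'   samples are removed (strict "less than" keeps a variant).
#' @param reads_both_callers_min Variant reads must exceed this when both
#'   callers agree (strict).
#' @param reads_single_caller_min Variant reads must exceed this when only one
#'   caller reports the variant (strict).
#' @param maf_max Population minor allele frequency must be below this in all
#'   three databases (strict).
#' @param min_group_frac Minimum fraction of the cohort required in each group
#'   of any survival dichotomization.
#' @param alpha Two-sided significance level.
#' @param resample_mm Isotropic grid spacings (mm) the pipeline can resample
#'   to; the first entry is the analysis grid.
#' @param dilation_voxels Chebyshev radius (voxels) for lesion-mask dilation.
#' @param n_bins Fixed bin number for intensity discretization.
#' @param min_voxels Minimum lesion size (voxels) for feature extraction.
#' @param n_folds,train_frac Monte Carlo cross-validation settings.
#' @param os_thresholds_months Overall-survival classification thresholds in
#'   months; `NA` means the cohort median.
#' @param n_trees,ga_pop,ga_gens Ensemble settings: trees in the bagged
#'   forest, population size and generations of the genetic feature selector.
#' @param seed Base RNG seed for every stochastic step.
#'
#' @return A list of class `radgen_config`.
#' @export
#' @examples
#' cfg <- radgen_config(seed = 7)
#' cfg$maf_max
radgen_config <- function(cohort_freq_max = 0.10,
                          reads_both_callers_min = 10,
                          reads_single_caller_min = 20,
                          maf_max = 0.01,
                          min_group_frac = 0.15,
                          alpha = 0.05,
                          resample_mm = c(2, 4),
                          dilation_voxels = 5,
                          n_bins = 32,
                          min_voxels = 64,
                          n_folds = 100,
                          train_frac = 0.8,
                          os_thresholds_months = c(24, NA, 36),
                          n_trees = 50,
                          ga_pop = 20,
                          ga_gens = 10,
                          seed = 1L) {
  assert_that(min_group_frac > 0 && min_group_frac < 0.5,
              "min_group_frac must be in (0, 0.5)")
  assert_that(train_frac > 0 && train_frac < 1, "train_frac must be in (0,1)")
  assert_that(n_folds >= 1, "n_folds must be >= 1")
  assert_that(all(resample_mm > 0), "resample_mm must be positive")
  structure(list(
    cohort_freq_max = cohort_freq_max,
    reads_both_callers_min = reads_both_callers_min,
    reads_single_caller_min = reads_single_caller_min,
    maf_max = maf_max,
    min_group_frac = min_group_frac,
    alpha = alpha,
    resample_mm = resample_mm,
    dilation_voxels = dilation_voxels,
    n_bins = n_bins,
    min_voxels = min_voxels,
    n_folds = n_folds,
    train_frac = train_frac,
    os_thresholds_months = os_thresholds_months,
    n_trees = n_trees,
    ga_pop = ga_pop,
    ga_gens = ga_gens,
    seed = as.integer(seed)
  ), class = "radgen_config")
}

#' @export
print.radgen_config <- function(x, ...) {
  cat("<radgen_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", paste(format(x[[nm]]), collapse = ", "), "\n")
  invisible(x)
}
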