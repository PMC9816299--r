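# Tumor-only somatic variant filtering.
#
# Four conjunctive rules, applied to an annotated variant table:
#   1. cohort frequency: keep variants seen in < 10% of samples,
#   2. caller evidence: both callers with > 10 variant reads, or a single
#      caller with > 20 variant reads,
#   3. population allele frequency: < 1% in all three population databases
#      (a missing AF counts as 0: absence from a database is evidence of
#      rarity),
#   4. ClinVar: records classified benign / likely benign are removed.
# The retained set is the intersection of the four single-rule pass sets, so
# rule order only affects the removal attribution, not the result.

#' Cohort carrier frequency per variant
#'
#' Fraction of samples carrying each variant key; a sample counts once per
#' variant regardless of multiplicity. Computed on the raw input table,
#' before any other filter.
#'
#' @param variants Variant tibble (needs `sample`, `variant_key`).
#' @param n_samples Number of samples in the cohort (>= 1); defaults to the
#'   number of distinct samples in `variants`, but should be the full cohort
#'   size when some samples have no variants.
#' @return A tibble with `variant_key` and `cohort_freq`.
#' @export
cohort_frequency <- function(variants, n_samples = dplyr::n_distinct(variants$sample)) {
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  variants |>
    distinct(.data$variant_key, .data$sample) |>
    dplyr::count(.data$variant_key, name = "n_carriers") |>
    mutate(cohort_freq = .data$n_carriers / n_samples)
}

#' Single filtering rules
#'
#' Vectorized predicates for the four somatic filtering rules; all
#' comparisons are strict per the filtering protocol.
#'
#' @param fraction Cohort carrier fraction in \[0,1\].
#' @param max_frac Maximum allowed carrier fraction (exclusive).
#' @return Logical vector: `TRUE` when the variant passes the rule.
#' @export
passes_cohort_frequency <- function(fraction, max_frac = 0.10) {
  fraction < max_frac
}

#' @rdname passes_cohort_frequency
#' @param n_callers Number of callers reporting the variant (1 or 2).
#' @param alt_reads Variant-supporting read count.
#' @param both_min,single_min Strict read-count thresholds for two-caller and
#'   single-caller variants.
#' @export
passes_caller_evidence <- function(n_callers, alt_reads,
                                   both_min = 10, single_min = 20) {
  assert_that(all(n_callers >= 1), "called_by must be non-empty")
  ifelse(n_callers >= 2, alt_reads > both_min, alt_reads > single_min)
}

#' @rdname passes_cohort_frequency
#' @param af_db1,af_db2,af_db3 Population allele frequencies (NA = variant
#'   absent from the database, treated as frequency 0).
#' @param maf_max Strict minor-allele-frequency bound.
#' @export
passes_population_af <- function(af_db1, af_db2, af_db3, maf_max = 0.01) {
  af1 <- ifelse(is.na(af_db1), 0, af_db1)
  af2 <- ifelse(is.na(af_db2), 0, af_db2)
  af3 <- ifelse(is.na(af_db3), 0, af_db3)
  af1 < maf_max & af2 < maf_max & af3 < maf_max
}

#' @rdname passes_cohort_frequency
#' @param clinvar ClinVar significance (`benign`, `likely_benign`, `other`,
#'   `none`).
#' @export
passes_clinvar <- function(clinvar) {
  !(clinvar %in% c("benign", "likely_benign"))
}

#' Apply the somatic filter cascade
#'
#' Runs the four rules and returns the retained variants together with a
#' removal report. Each removed variant is attributed to the first failing
#' rule in the fixed order frequency, evidence, population AF, ClinVar; the
#' retained set itself is order-invariant (rules are conjunctive).
#'
#' @param variants Validated variant tibble (see [read_variant_table()]).
#' @param n_samples Cohort size used for the frequency rule.
#' @param config A [radgen_config()].
#' @return A list of class `filter_report`: `retained` (tibble), `removals`
#'   (tibble of per-rule counts), `n_samples`, `n_input`.
#' @export
filter_somatic <- function(variants, n_samples, config = radgen_config()) {
  if (!"n_callers" %in% names(variants)) variants <- validate_variants(variants)
  freq <- cohort_frequency(variants, n_samples)
  v <- left_join(variants, freq, by = "variant_key")
  pass_freq <- passes_cohort_frequency(v$cohort_freq, config$cohort_freq_max)
  pass_ev <- passes_caller_evidence(v$n_callers, v$alt_reads,
                                    config$reads_both_callers_min,
                                    config$reads_single_caller_min)
  pass_af <- passes_population_af(v$af_db1, v$af_db2, v$af_db3, config$maf_max)
  pass_cv <- passes_clinvar(v$clinvar)

  first_fail <- rep(NA_character_, nrow(v))
  first_fail[!pass_cv] <- "clinvar"
  first_fail[!pass_af] <- "population_af"
  first_fail[!pass_ev] <- "caller_evidence"
  first_fail[!pass_freq] <- "cohort_frequency"

  retained <- v[is.na(first_fail), , drop = FALSE]
  removals <- tibble(
    rule = c("cohort_frequency", "caller_evidence", "population_af", "clinvar"),
    removed = c(sum(first_fail == "cohort_frequency", na.rm = TRUE),
                sum(first_fail == "caller_evidence", na.rm = TRUE),
                sum(first_fail == "population_af", na.rm = TRUE),
                sum(first_fail == "clinvar", na.rm = TRUE))
  )
  structure(list(retained = as_tibble(retained), removals = removals,
                 n_samples = n_samples, n_input = nrow(v)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d variants in, %d retained (%d samples)\n",
              x$n_input, nrow(x$retained), x$n_samples))
  print(x$removals)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) x$removals

#' @exportS3Method generics::glance
glance.filter_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_retained = nrow(x$retained),
         n_removed = x$n_input - nrow(x$retained), n_samples = x$n_samples)
}
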