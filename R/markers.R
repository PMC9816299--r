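# Construction and evaluation of combinatorial radiogenomic markers: each
# marker is the conjunction of a binary pathway state (functional/disrupted)
# and a dichotomized radiomic feature level (high/low). For each
# (pathway, feature) pair the four state/level combinations partition the
# cohort.

#' Univariate optimized-cutoff survival screen
#'
#' Runs [optimize_cutoff()] for every feature column and returns one row per
#' feature with the optimal cutoff, logrank statistic/p, group sizes, and the
#' per-patient high/low level at the optimum. Bonferroni-adjusted p-values
#' use the number of screened features as family size.
#'
#' @param features Tibble with `patient_id` and numeric feature columns.
#' @param cohort Cohort tibble (`patient_id`, `os_months`, `event`).
#' @param min_group_frac Minimum group fraction for admissible cutoffs.
#' @return A list: `summary` (tibble, one row per feature, ordered by p) and
#'   `levels` (long tibble `patient_id`, `feature`, `level`).
#' @export
univariate_survival <- function(features, cohort, min_group_frac = 0.15) {
  fcols <- setdiff(names(features), "patient_id")
  m <- features[match(cohort$patient_id, features$patient_id), , drop = FALSE]
  res <- map(fcols, function(fc) {
    optimize_cutoff(m[[fc]], cohort$os_months, cohort$event,
                    min_group_frac = min_group_frac, feature = fc)
  })
  summary <- bind_rows(map(res, tidy))
  summary$p_adj <- bonferroni(summary$p, m = sum(!is.na(summary$p)))
  levels <- bind_rows(map(res, function(r) {
    tibble(patient_id = cohort$patient_id, feature = r$feature,
           level = r$group)
  }))
  list(summary = arrange(summary, .data$p), levels = levels)
}

#' Select prognostic pathways and radiomic features
#'
#' Items with raw optimized-cutoff logrank p below `alpha` on each side; the
#' raw (not Bonferroni-adjusted) p is used for marker construction, with the
#' corrected p reported alongside.
#'
#' @param pathway_summary Per-pathway tibble with `pathway_id` and `p`.
#' @param feature_summary Per-feature tibble with `feature` and `p`.
#' @param alpha Selection threshold.
#' @return A list with `pathways` and `features` (character vectors).
#' @export
select_prognostic <- function(pathway_summary, feature_summary, alpha = 0.05) {
  pws <- pathway_summary$pathway_id[!is.na(pathway_summary$p) &
                                      pathway_summary$p < alpha]
  fts <- feature_summary$feature[!is.na(feature_summary$p) &
                                   feature_summary$p < alpha]
  if (length(pws) == 0 || length(fts) == 0) {
    warn("no prognostic pathways and/or features; markers stage will be empty")
  }
  list(pathways = pws, features = fts)
}

#' Build candidate radiogenomic markers
#'
#' For every selected (pathway, feature) pair, creates the four binary
#' markers (disrupted/high, disrupted/low, functional/high, functional/low).
#' A marker is present for a patient iff the patient's pathway state equals
#' the marker's required state AND the feature level equals the required
#' level. Patients with a missing state or level are excluded from that
#' marker (counted in `n_missing`).
#'
#' @param states Long tibble `sample`, `pathway_id`, `state`.
#' @param levels Long tibble `patient_id`, `feature`, `level` (from
#'   [univariate_survival()]).
#' @param pathways_selected,features_selected Character vectors of selected
#'   pathway ids / feature names.
#' @return A marker tibble: `marker_id`, `pathway_id`, `pathway_state`,
#'   `feature`, `feature_level`, `n_present`, `n_absent`, `n_missing`, and a
#'   list-column `presence` (tibble `patient_id`, `present`).
#' @export
build_candidates <- function(states, levels, pathways_selected,
                             features_selected) {
  grid <- tidyr::expand_grid(
    pathway_id = pathways_selected, feature = features_selected,
    pathway_state = c("disrupted", "functional"),
    feature_level = c("high", "low"))
  # align everything on one patient vector so presence is pure vector work
  pats <- unique(c(states$sample, levels$patient_id))
  st_vecs <- lapply(stats::setNames(nm = pathways_selected), function(pw) {
    s <- states[states$pathway_id == pw, ]
    s$state[match(pats, s$sample)]
  })
  lv_vecs <- lapply(stats::setNames(nm = features_selected), function(ft) {
    l <- levels[levels$feature == ft, ]
    l$level[match(pats, l$patient_id)]
  })
  rows <- pmap(grid, function(pathway_id, feature, pathway_state,
                              feature_level) {
    st <- st_vecs[[pathway_id]]
    lv <- lv_vecs[[feature]]
    complete <- !is.na(st) & !is.na(lv)
    present <- st == pathway_state & lv == feature_level
    present[!complete] <- NA
    list(marker_id = sprintf("%s(%s)-%s(%s)", pathway_id, pathway_state,
                             feature, feature_level),
         pathway_id = pathway_id, pathway_state = pathway_state,
         feature = feature, feature_level = feature_level,
         n_present = sum(present, na.rm = TRUE),
         n_absent = sum(!present, na.rm = TRUE),
         n_missing = sum(!complete),
         presence = list(tibble(patient_id = pats, present = present)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(marker_id = character(), pathway_id = character(),
                  pathway_state = character(), feature = character(),
                  feature_level = character(), n_present = integer(),
                  n_absent = integer(), n_missing = integer(),
                  presence = list())
  }
  out
}

#' Filter markers by subgroup size
#'
#' Keeps markers with at least `min_frac` of the evaluable cohort in both the
#' present and absent group.
#'
#' @param markers Marker tibble from [build_candidates()].
#' @param min_frac Minimum fraction.
#' @return The retained subset of `markers`.
#' @export
subgroup_filter <- function(markers, min_frac = 0.15) {
  if (nrow(markers) == 0) return(markers)
  n_eval <- markers$n_present + markers$n_absent
  keep <- pmin(markers$n_present, markers$n_absent) / n_eval >= min_frac
  markers[keep, , drop = FALSE]
}

#' Evaluate retained radiogenomic markers
#'
#' Two-sided logrank of present vs absent (the groups are fixed by the
#' marker definition; no second cutoff search), Bonferroni correction within
#' the retained-marker family, ranked ascending by p.
#'
#' @param markers Retained marker tibble.
#' @param cohort Cohort tibble.
#' @return The marker tibble with `statistic`, `p`, `p_adj`, `rank` columns,
#'   ordered by p.
#' @export
evaluate_markers <- function(markers, cohort) {
  if (nrow(markers) == 0) {
    return(bind_cols(markers, tibble(statistic = numeric(0), p = numeric(0),
                                     p_adj = numeric(0), rank = integer(0))))
  }
  # all presence vectors share one patient alignment; precompute the risk-set
  # structure once and reuse it for every complete-data marker
  pats <- markers$presence[[1]]$patient_id
  ord <- match(pats, cohort$patient_id)
  tt <- cohort$os_months[ord]; ee <- cohort$event[ord]
  pre <- if (!anyNA(tt)) logrank_precompute(tt, ee)
  stats_tbl <- map(markers$presence, function(pr) {
    if (!is.null(pre) && !anyNA(pr$present) &&
        identical(pr$patient_id, pats)) {
      lr <- logrank_core(pre, pr$present)
    } else {
      j <- inner_join(pr, cohort, by = "patient_id")
      j <- j[!is.na(j$present), ]
      lr <- logrank_test(j$os_months, j$event, j$present)
    }
    tibble(statistic = lr$statistic, p = lr$p)
  }) |> bind_rows()
  out <- bind_cols(markers, stats_tbl)
  out$p_adj <- bonferroni(out$p, m = nrow(out))
  out <- arrange(out, .data$p, .data$marker_id)
  out$rank <- seq_len(nrow(out))
  out
}
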