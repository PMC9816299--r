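# End-to-end orchestration: somatic filtering -> pathway scoring ->
# radiomics -> univariate survival -> association -> radiogenomic markers ->
# (optional) cross-validated ML. Patients must be linkable by exact id across
# all inputs; mismatches are dropped with a logged census, never imputed.

#' Radiomic-pathway association stage
#'
#' Mann-Whitney U association between every dichotomizable pathway state and
#' every radiomic feature, Bonferroni-corrected within the full
#' pathways x features family.
#'
#' @param states Long tibble `sample`, `pathway_id`, `state`.
#' @param features Tibble with `patient_id` and feature columns.
#' @return A tibble `pathway_id`, `feature`, `u`, `p`, `p_adj`, ordered by p.
#' @export
associate_features <- function(states, features) {
  pw_ids <- unique(states$pathway_id)
  fcols <- setdiff(names(features), "patient_id")
  pw_v <- character(0); ft_v <- character(0)
  u_v <- numeric(0); p_v <- numeric(0); n1_v <- integer(0); n2_v <- integer(0)
  for (pw in pw_ids) {
    st <- states[states$pathway_id == pw, ]
    st <- st[match(features$patient_id, st$sample), ]
    if (length(unique(na.omit(st$state))) < 2) next
    for (fc in fcols) {
      ok <- !is.na(st$state) & !is.na(features[[fc]])
      mw <- mw_stat(st$state[ok], features[[fc]][ok])
      k <- length(pw_v) + 1
      pw_v[k] <- pw; ft_v[k] <- fc
      u_v[k] <- mw$u; p_v[k] <- mw$p; n1_v[k] <- mw$n1; n2_v[k] <- mw$n2
    }
  }
  if (length(pw_v) == 0) {
    return(tibble(pathway_id = character(), feature = character(),
                  u = numeric(), p = numeric(), p_adj = numeric()))
  }
  out <- tibble(pathway_id = pw_v, feature = ft_v, u = u_v, p = p_v,
                n1 = n1_v, n2 = n2_v)
  out$p_adj <- bonferroni(out$p, m = nrow(out))
  arrange(out, .data$p)
}

#' Redundancy removal across radiomic features
#'
#' Collapses redundant features before the univariate survival screen: from
#' every pair with |Spearman| above the cutoff, the member with the larger
#' mean absolute correlation to all remaining features is dropped (the same
#' rule the ML preprocessing applies per training split, here applied once on
#' the whole cohort as in the published analysis, which reduced 104 features
#' to 14 before univariate survival).
#'
#' @param features Tibble with `patient_id` and numeric feature columns.
#' @param redundancy_cut Absolute Spearman threshold (pairs above it are
#'   collapsed).
#' @return The reduced feature tibble; dropped names in attribute `dropped`.
#' @export
reduce_features <- function(features, redundancy_cut = 0.9) {
  fcols <- setdiff(names(features), "patient_id")
  x <- as.matrix(features[, fcols, drop = FALSE])
  keep <- fcols[apply(x, 2, function(v) stats::sd(v) > 0)]
  dropped <- setdiff(fcols, keep)
  if (length(keep) > 1) {
    rho <- suppressWarnings(cor(x[, keep, drop = FALSE], method = "spearman"))
    repeat {
      diag(rho) <- 0
      mx <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
      if (abs(rho[mx[1], mx[2]]) <= redundancy_cut) break
      mean_abs <- rowMeans(abs(rho))
      drop_i <- if (mean_abs[mx[1]] >= mean_abs[mx[2]]) mx[1] else mx[2]
      dropped <- c(dropped, colnames(rho)[drop_i])
      rho <- rho[-drop_i, -drop_i, drop = FALSE]
      if (nrow(rho) < 2) break
    }
    keep <- setdiff(keep, dropped)
  }
  out <- features[, c("patient_id", keep), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# census of patient ids across inputs; returns ids present everywhere and
# warns about the rest
link_patients <- function(cohort_ids, ...) {
  others <- list(...)
  keep <- cohort_ids
  for (ids in others) keep <- intersect(keep, ids)
  dropped <- setdiff(unique(c(cohort_ids, unlist(others))), keep)
  if (length(dropped) > 0) {
    warn(paste0("patients not present in all inputs, excluded: ",
                paste(sort(dropped), collapse = ", ")))
  }
  keep
}

#' Run the full radiogenomic analysis
#'
#' Executes all stages in order on a cohort, a variant table, pathway
#' definitions, and either per-patient PET/CT volumes or a precomputed
#' radiomic feature table. Fully reproducible given `config$seed`.
#'
#' @param cohort Cohort tibble (see [read_clinical_table()]).
#' @param variants Annotated variant tibble (see [read_variant_table()]).
#' @param pathways Pathway tibble (default [default_pathway_sets()]).
#' @param images Named list (by patient id) of `list(pet =, ct =)` [voi()]
#'   pairs, or `NULL` when `features` is given.
#' @param features Precomputed radiomic feature tibble with `patient_id`
#'   (used when `images` is `NULL`).
#' @param config A [radgen_config()].
#' @param run_ml Run the Monte Carlo cross-validated classification stage
#'   (the most expensive stage).
#' @return An object of class `radgen_report` with per-stage tables:
#'   `filter`, `pathway` (scores/states/summary), `features`,
#'   `univariate_features`, `univariate_pathways`, `associations`,
#'   `selection`, `markers`, `ml` (or NULL), `config`, `patients`.
#' @export
run_full_analysis <- function(cohort, variants, pathways = default_pathway_sets(),
                              images = NULL, features = NULL,
                              config = radgen_config(), run_ml = TRUE) {
  cohort <- validate_cohort(cohort)

  # radiomics stage (or adopt precomputed features)
  if (is.null(features)) {
    assert_that(!is.null(images), "provide images or a feature table")
    features <- bind_rows(imap(images, function(pair, pid) {
      bind_cols(tibble(patient_id = pid),
                extract_features(pair$pet, pair$ct, config))
    }))
  }

  ids <- link_patients(cohort$patient_id,
                       unique(variants$sample), features$patient_id)
  cohort <- cohort[cohort$patient_id %in% ids, ]
  features <- features[features$patient_id %in% ids, ]
  variants <- variants[variants$sample %in% ids, ]

  # 1. somatic filtering
  filt <- filter_somatic(variants, n_samples = nrow(cohort), config = config)

  # 2. pathway scores and survival-derived states
  pw <- pathway_state_table(filt$retained, pathways, cohort,
                            min_group_frac = config$min_group_frac)

  # 3. redundancy removal, then univariate optimized-cutoff survival
  features_red <- reduce_features(features, redundancy_cut = 0.9)
  uni_f <- univariate_survival(features_red, cohort,
                               min_group_frac = config$min_group_frac)
  uni_p <- pw$summary |> rename(feature = "pathway_id")

  # 4. association of (non-redundant) radiomic features with pathway states
  assoc <- associate_features(pw$states, features_red)

  # 5. radiogenomic markers
  sel <- select_prognostic(
    pw$summary |> filter(.data$admissible),
    uni_f$summary |> filter(.data$admissible),
    alpha = config$alpha)
  cand <- build_candidates(pw$states, uni_f$levels, sel$pathways, sel$features)
  retained <- subgroup_filter(cand, min_frac = config$min_group_frac)
  markers <- evaluate_markers(retained, cohort)
  if (nrow(markers) == 0) warn("markers stage empty")

  # 6. cross-validated ML on the top prognostic features of all families
  ml <- NULL
  if (run_ml && nrow(markers) > 0) {
    ml_feats <- ml_feature_table(cohort, features, pw, uni_f, markers,
                                 n_features = 20)
    targets <- make_targets(cohort, config$os_thresholds_months)
    if (nrow(targets) > 0) ml <- monte_carlo_cv(ml_feats, targets, config)
  }

  structure(list(filter = filt, pathway = pw, features = features,
                 features_reduced = features_red,
                 univariate_features = uni_f$summary,
                 univariate_pathways = uni_p,
                 feature_levels = uni_f$levels,
                 associations = assoc, selection = sel, markers = markers,
                 ml = ml, config = config, patients = ids),
            class = "radgen_report")
}

# assemble the <=20-column ML feature table: the most prognostic
# radiogenomic markers (binary presence), pathway scores (genomic family),
# and radiomic features, each family ranked by univariate p
ml_feature_table <- function(cohort, features, pw, uni_f, markers,
                             n_features = 20) {
  n_rg <- min(nrow(markers), ceiling(n_features / 3))
  rg <- map(seq_len(n_rg), function(i) {
    pr <- markers$presence[[i]]
    v <- as.integer(pr$present[match(cohort$patient_id, pr$patient_id)])
    tibble(!!paste0("rg.", markers$marker_id[i]) := v)
  })
  pw_wide <- pw$scores |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "score",
                       names_prefix = "gen.")
  pw_wide <- pw_wide[match(cohort$patient_id, pw_wide$sample), , drop = FALSE]
  pw_ord <- pw$summary |> filter(!is.na(.data$p)) |> arrange(.data$p)
  n_pw <- min(nrow(pw_ord), ceiling(n_features / 3))
  pw_cols <- intersect(paste0("gen.", head(pw_ord$pathway_id, n_pw)),
                       names(pw_wide))
  n_rad <- max(0, n_features - n_rg - length(pw_cols))
  rad_ord <- uni_f$summary |> filter(!is.na(.data$p)) |> arrange(.data$p)
  rad_cols <- head(rad_ord$feature, n_rad)
  rad <- features[match(cohort$patient_id, features$patient_id),
                  rad_cols, drop = FALSE]
  names(rad) <- paste0("rad.", names(rad))
  bind_cols(tibble(patient_id = cohort$patient_id),
            if (n_rg > 0) bind_cols(rg) else NULL,
            pw_wide[, pw_cols, drop = FALSE],
            rad)
}

#' @export
print.radgen_report <- function(x, ...) {
  cat("<radgen_report>\n")
  cat(sprintf("  patients: %d\n", length(x$patients)))
  cat(sprintf("  variants: %d in, %d retained\n", x$filter$n_input,
              nrow(x$filter$retained)))
  cat(sprintf("  pathways dichotomizable: %d/%d\n",
              sum(x$univariate_pathways$admissible),
              nrow(x$univariate_pathways)))
  cat(sprintf("  markers: %d evaluated\n", nrow(x$markers)))
  if (!is.null(x$ml)) print(x$ml$summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.radgen_report <- function(x, ...) {
  tibble(n_patients = length(x$patients),
         n_variants_retained = nrow(x$filter$retained),
         n_markers = nrow(x$markers),
         best_marker_p = if (nrow(x$markers) > 0) x$markers$p[1] else NA_real_)
}

#' Write the per-stage tables of a report to a directory
#'
#' @param report A `radgen_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(dir, f), progress = FALSE)
  w(report$filter$removals, "filter_removals.csv")
  w(report$pathway$states, "pathway_states.csv")
  w(report$univariate_features, "univariate_features.csv")
  w(report$univariate_pathways, "univariate_pathways.csv")
  w(report$associations, "associations.csv")
  w(report$markers |> select(-"presence"), "markers.csv")
  if (!is.null(report$ml)) {
    w(report$ml$summary, "ml_summary.csv")
    w(report$ml$importance, "ml_importance.csv")
  }
  invisible(dir)
}
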