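# Pathway-level CADD disruption scoring: mutation-level CADD PHRED scores are
# summed to gene level, gene scores are summed over pathway gene sets, and
# each pathway score is dichotomized into functional/disrupted at its own
# survival-derived cutoff.

#' Default pathway roster
#'
#' Nine KEGG-style gene sets: six related to cell growth and death (cell
#' cycle, apoptosis, p53 signaling, cellular senescence, ferroptosis,
#' necroptosis) and three to energy metabolism (oxidative phosphorylation,
#' nitrogen metabolism, sulfur metabolism). The gene lists are representative
#' core members, not full KEGG rosters, and are fully user-replaceable via
#' [read_gene_sets()]. Genes may belong to several pathways (e.g. TP53).
#'
#' @return A pathway tibble (`pathway_id`, `display_name`, `category`,
#'   list-column `genes`).
#' @export
default_pathway_sets <- function() {
  cg <- "cell_growth_and_death"; em <- "energy_metabolism"
  defs <- list(
    cell_cycle = list(cg, c("TP53", "CDK4", "CDK6", "CCND1", "CCNE1", "CDC20",
                            "CDC25A", "PLK1", "BUB1", "MAD2L1", "RB1",
                            "E2F1")),
    apoptosis = list(cg, c("TP53", "CASP3", "CASP9", "BAX", "BCL2", "BID",
                           "APAF1", "FAS", "FADD", "TNFSF10", "XIAP",
                           "DIABLO")),
    p53_signaling = list(cg, c("TP53", "MDM2", "MDM4", "CDKN1A", "CCNG1",
                               "GADD45A", "CHEK1", "CHEK2", "ATR", "ATM",
                               "RRM2B", "SESN1")),
    cellular_senescence = list(cg, c("TP53", "CDKN2A", "MAPK14", "TGFB1",
                                     "MYC", "NFKB1", "SQSTM1", "SERPINE1",
                                     "GLB1", "LMNB1", "IL6", "ETS1")),
    ferroptosis = list(cg, c("TP53", "GPX4", "SLC7A11", "ACSL4", "FTH1",
                             "TFRC", "ALOX15", "NCOA4", "SLC3A2", "HMOX1")),
    necroptosis = list(cg, c("RIPK1", "RIPK3", "MLKL", "TNF", "TLR4", "ZBP1",
                             "PGAM5", "CASP8")),
    oxidative_phosphorylation = list(em, c("NDUFA1", "NDUFS1", "SDHA", "SDHB",
                                           "UQCRC1", "CYC1", "COX4I1",
                                           "COX5A", "ATP5F1A", "ATP5F1B")),
    nitrogen_metabolism = list(em, c("GLS", "GLS2", "GLUL", "CPS1", "ASNS",
                                     "CA2", "CA9", "GLUD1")),
    sulfur_metabolism = list(em, c("CTH", "CBS", "SQOR", "TST", "MPST",
                                   "SUOX", "PAPSS1", "SELENBP1"))
  )
  tibble(pathway_id = names(defs),
         display_name = gsub("_", " ", names(defs)),
         category = unname(map_chr(defs, 1)),
         genes = map(defs, 2))
}

#' Gene-level CADD scores
#'
#' Sums CADD PHRED scores over each sample's retained variants per gene.
#' (Sample, gene) pairs with no variants are implicit zeros.
#'
#' @param variants Retained variant tibble (needs `sample`, `gene`,
#'   `cadd_phred`).
#' @return A tibble with `sample`, `gene`, `gene_cadd`.
#' @export
gene_scores <- function(variants) {
  variants |>
    group_by(.data$sample, .data$gene) |>
    summarise(gene_cadd = sum(.data$cadd_phred), .groups = "drop")
}

#' Pathway-level CADD scores
#'
#' Sums gene-level scores over each pathway's gene set, per sample. A gene
#' belonging to several pathways contributes fully to each. Samples without
#' variants in a pathway score 0; a pathway whose gene set does not intersect
#' the data's gene space scores 0 everywhere with a warning.
#'
#' @param gene_table Output of [gene_scores()].
#' @param pathways Pathway tibble ([default_pathway_sets()] or
#'   [read_gene_sets()]).
#' @param samples Character vector of all sample ids (so zero-score samples
#'   are represented); defaults to the samples present in `gene_table`.
#' @return A tibble with `sample`, `pathway_id`, `score`.
#' @export
pathway_scores <- function(gene_table, pathways,
                           samples = unique(gene_table$sample)) {
  long <- pathways |>
    select("pathway_id", "genes") |>
    tidyr::unnest("genes") |>
    rename(gene = "genes")
  empty <- setdiff(pathways$pathway_id, unique(
    inner_join(long, distinct(gene_table, .data$gene), by = "gene")$pathway_id))
  if (length(empty) > 0) {
    warn(paste0("pathway(s) with no genes present in data (score 0): ",
                paste(empty, collapse = ", ")))
  }
  scored <- inner_join(long, gene_table, by = "gene",
                       relationship = "many-to-many") |>
    group_by(.data$sample, .data$pathway_id) |>
    summarise(score = sum(.data$gene_cadd), .groups = "drop")
  tidyr::expand_grid(sample = samples, pathway_id = pathways$pathway_id) |>
    left_join(scored, by = c("sample", "pathway_id")) |>
    mutate(score = ifelse(is.na(.data$score), 0, .data$score))
}

#' Dichotomize a pathway score into functional/disrupted
#'
#' Delegates to [optimize_cutoff()]: the cutoff minimizing the logrank p
#' under the minimum-group-size constraint defines the binary pathway state,
#' disrupted iff score > cutoff (strict). Constant scores (or no admissible
#' cutoff) flag the pathway non-dichotomizable.
#'
#' @param score_vector Pathway scores aligned with `cohort` rows.
#' @param cohort Cohort tibble with `os_months`, `event`.
#' @param min_group_frac Minimum group fraction.
#' @param pathway_id Name carried into the result.
#' @return A list of class `pathway_state`: the `dichotomization` fields plus
#'   `state` (`"functional"`/`"disrupted"` per patient).
#' @export
dichotomize_pathway <- function(score_vector, cohort, min_group_frac = 0.15,
                                pathway_id = "pathway") {
  d <- optimize_cutoff(score_vector, cohort$os_months, cohort$event,
                       min_group_frac = min_group_frac, feature = pathway_id)
  state <- if (d$admissible) {
    ifelse(score_vector > d$cutoff, "disrupted", "functional")
  } else rep(NA_character_, length(score_vector))
  out <- c(d[setdiff(names(d), "group")], list(state = state))
  class(out) <- c("pathway_state", "dichotomization")
  out
}

#' Score and dichotomize all pathways for a cohort
#'
#' Convenience stage runner: gene scores, pathway scores, and per-pathway
#' survival-derived states for every pathway in the roster.
#'
#' @param retained_variants Retained (filtered) variant tibble.
#' @param pathways Pathway tibble.
#' @param cohort Cohort tibble (defines the sample universe and survival).
#' @param min_group_frac Minimum group fraction for dichotomization.
#' @return A list with `scores` (sample x pathway tibble), `states` (tibble
#'   `sample`, `pathway_id`, `score`, `state`), and `summary` (per-pathway
#'   cutoff, logrank p, admissibility).
#' @export
pathway_state_table <- function(retained_variants, pathways, cohort,
                                min_group_frac = 0.15) {
  gt <- gene_scores(retained_variants)
  ps <- pathway_scores(gt, pathways, samples = cohort$patient_id)
  per_pw <- map(pathways$pathway_id, function(pw) {
    sv <- ps |> filter(.data$pathway_id == pw)
    sv <- sv[match(cohort$patient_id, sv$sample), ]
    dp <- dichotomize_pathway(sv$score, cohort, min_group_frac, pathway_id = pw)
    list(states = tibble(sample = cohort$patient_id, pathway_id = pw,
                         score = sv$score, state = dp$state),
         summary = tidy(dp) |> rename(pathway_id = "feature"))
  })
  list(scores = ps,
       states = bind_rows(map(per_pw, "states")),
       summary = bind_rows(map(per_pw, "summary")))
}
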