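# Truth with mutation machinery off: fast cohorts for survival-only checks
survival_only_truth <- function(...) {
  simulation_truth(gene_rate = 0, extra_deleterious = 0,
                   contaminant_rate = 0, n_recurrent = 0, ...)
}

test_that("same seed reproduces the study exactly; seeds differ otherwise", {
  a <- simulate_study(25, seed = 3, level = "feature")
  b <- simulate_study(25, seed = 3, level = "feature")
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$variants, b$variants)
  expect_identical(a$features, b$features)
  c <- simulate_study(25, seed = 4, level = "feature")
  expect_false(identical(a$cohort$os_months, c$cohort$os_months))
})

test_that("marker hazard shifts Kaplan-Meier medians by the Weibull ratio", {
  tr <- survival_only_truth(hazard_ratio = 3)
  st <- simulate_study(2000, tr, seed = 17, level = "feature")
  km <- km_curve(st$cohort$os_months, st$cohort$event,
                 ifelse(st$truth_tbl$marker_present, "present", "absent"))
  med_of <- function(g) {
    k <- km[km$group == g, ]
    k$time[which(k$surv <= 0.5)[1]]
  }
  ratio <- med_of("present") / med_of("absent")
  # closed form: HR^(-1/shape) = 3^(-1/1.2) ~ 0.40
  expect_equal(ratio, 3^(-1 / 1.2), tolerance = 0.15)
})

test_that("null marker gives uniform logrank p over replicates", {
  tr <- survival_only_truth(hazard_ratio = 1)
  ps <- vapply(1:200, function(r) {
    st <- simulate_study(60, tr, seed = 7000 + r, level = "feature")
    pres <- st$truth_tbl$marker_present
    if (length(unique(pres)) < 2) return(NA_real_)
    logrank_test(st$cohort$os_months, st$cohort$event, pres)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variant generator plants pathway burden and removable germline", {
  st <- simulate_study(40, seed = 23, level = "feature")
  v <- st$variants
  expect_true(all(c("somatic", "contaminant") %in% v$truth_class))

  # contaminants carry high population AFs and are removed by the cascade
  rep <- filter_somatic(v, 40)
  cont_keys <- v$variant_key[v$truth_class == "contaminant"]
  removed_frac <- 1 - sum(rep$retained$variant_key %in% cont_keys) /
    length(cont_keys)
  expect_gte(removed_frac, 0.95)

  # recurrent artifact keys exceed the 10% carrier rule and are removed
  art <- v[v$truth_class == "artifact", ]
  if (nrow(art) > 0) {
    expect_false(any(rep$retained$variant_key %in% art$variant_key))
  }

  # disrupted patients have the higher planted-pathway CADD burden
  gt <- gene_scores(rep$retained)
  ps <- pathway_scores(gt, default_pathway_sets(),
                       samples = st$cohort$patient_id)
  cs <- ps[ps$pathway_id == "cellular_senescence", ]
  cs <- cs[match(st$cohort$patient_id, cs$sample), ]
  truth_state <- st$truth_tbl[, "state.cellular_senescence", drop = TRUE]
  expect_gt(mean(cs$score[truth_state == "disrupted"]),
            mean(cs$score[truth_state == "functional"]))
})

test_that("mutation rate zero produces no variants", {
  st <- simulate_study(20, survival_only_truth(), seed = 2, level = "feature")
  expect_equal(nrow(st$variants), 0)
})

test_that("lesion generator couples size to stat.sum and heterogeneity to texture", {
  small <- generate_lesion_image(1000, 1, 2, seed = 31, modality = "PET")
  large <- generate_lesion_image(8000, 1, 2, seed = 31, modality = "PET")
  expect_gt(stat_sum(large), stat_sum(small))

  # zero heterogeneity: lesion intensities constant -> one occupied bin
  flat <- generate_lesion_image(3000, 0, 2, seed = 5, modality = "PET")
  d <- discretize(flat)
  expect_equal(length(unique(d$levels[flat$mask])), 1)

  # reproducibility at the voxel level
  a <- generate_lesion_image(3000, 1, 2, seed = 9, modality = "CT")
  b <- generate_lesion_image(3000, 1, 2, seed = 9, modality = "CT")
  expect_identical(a$intensity, b$intensity)

  # sub-64-voxel request is flagged
  tiny <- generate_lesion_image(100, 1, 4, seed = 1, modality = "PET")
  expect_true(isTRUE(attr(tiny, "too_small")))
  expect_error(generate_lesion_image(-5, 1, 2), "volume")
})

test_that("image-level studies carry consistent ids and reference regions", {
  st <- simulate_study(20, survival_only_truth(), seed = 13)
  expect_setequal(names(st$images), st$cohort$patient_id)
  one <- st$images[[1]]
  expect_equal(one$pet$modality, "PET")
  expect_equal(one$ct$modality, "CT")
  expect_false(is.null(one$pet$reference))
  expect_false(any(one$pet$reference & dilate_mask(one$pet$mask, 5)))
})
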