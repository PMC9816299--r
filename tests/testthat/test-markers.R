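# small fixtures: states/levels for 6 patients, 2 pathways, 2 features
toy_states <- function() {
  tidyr::expand_grid(sample = sprintf("P%d", 1:6),
                     pathway_id = c("pwA", "pwB")) |>
    dplyr::mutate(state = rep(c("disrupted", "functional"), 6))
}
toy_levels <- function() {
  tidyr::expand_grid(patient_id = sprintf("P%d", 1:6),
                     feature = c("f1", "f2")) |>
    dplyr::mutate(level = rep(c("high", "high", "low", "low"), 3))
}

test_that("selection filters on raw p below alpha", {
  pws <- tibble::tibble(pathway_id = paste0("pw", 1:5),
                        p = c(0.001, 0.03, 0.04, 0.2, NA))
  fts <- tibble::tibble(feature = paste0("f", 1:9),
                        p = c(rep(0.01, 7), 0.6, 0.051))
  sel <- select_prognostic(pws, fts)
  expect_length(sel$pathways, 3)
  expect_length(sel$features, 7)
  expect_warning(sel0 <- select_prognostic(pws, fts, alpha = 1e-6), "empty")
  expect_length(sel0$features, 0)
  sel1 <- select_prognostic(pws, fts, alpha = 1)
  expect_length(sel1$pathways, 4)   # NA p never selected
  expect_length(sel1$features, 9)
})

test_that("candidate construction gives 4 markers per pair, partitioning", {
  cand <- build_candidates(toy_states(), toy_levels(), c("pwA", "pwB"),
                           c("f1", "f2"))
  expect_equal(nrow(cand), 4 * 2 * 2)
  # per (pathway, feature) pair the four presence vectors partition patients
  for (pw in c("pwA", "pwB")) {
    for (ft in c("f1", "f2")) {
      grp <- cand[cand$pathway_id == pw & cand$feature == ft, ]
      tot <- Reduce(`+`, lapply(grp$presence, function(p) as.integer(p$present)))
      expect_equal(tot, rep(1L, 6))
    }
  }
  # presence is the conjunction of the two required conditions per patient
  m <- cand[cand$pathway_id == "pwA" & cand$feature == "f1" &
              cand$pathway_state == "disrupted" &
              cand$feature_level == "high", ]
  pr <- m$presence[[1]]
  st <- toy_states(); lv <- toy_levels()
  for (i in seq_len(nrow(pr))) {
    s <- st$state[st$sample == pr$patient_id[i] & st$pathway_id == "pwA"]
    l <- lv$level[lv$patient_id == pr$patient_id[i] & lv$feature == "f1"]
    expect_equal(pr$present[i], s == "disrupted" && l == "high")
  }
  # 3 pathways x 7 features would give 84 candidates (the study's count law)
  st7 <- tidyr::expand_grid(sample = sprintf("P%d", 1:6),
                            pathway_id = paste0("pw", 1:3)) |>
    dplyr::mutate(state = "functional")
  lv7 <- tidyr::expand_grid(patient_id = sprintf("P%d", 1:6),
                            feature = paste0("f", 1:7)) |>
    dplyr::mutate(level = "low")
  expect_equal(nrow(build_candidates(st7, lv7, paste0("pw", 1:3),
                                     paste0("f", 1:7))), 84)
})

test_that("missing states exclude patients from a marker, counted", {
  st <- toy_states()
  st$state[st$sample == "P1" & st$pathway_id == "pwA"] <- NA
  cand <- build_candidates(st, toy_levels(), "pwA", "f1")
  expect_true(all(cand$n_missing == 1))
  expect_true(all(is.na(cand$presence[[1]]$present[
    cand$presence[[1]]$patient_id == "P1"])))
})

test_that("subgroup filter applies the 15% boundary arithmetic", {
  mk <- tibble::tibble(
    marker_id = c("a", "b", "c"),
    n_present = c(9L, 10L, 62L), n_absent = c(53L, 52L, 0L),
    n_missing = 0L,
    presence = list(tibble::tibble(patient_id = "x", present = TRUE)))
  kept <- subgroup_filter(mk, 0.15)
  expect_equal(kept$marker_id, "b")     # 9/62 = 14.5% out, 10/62 = 16.1% in
  expect_equal(nrow(subgroup_filter(mk, 0)), 3)
})

test_that("marker evaluation is a fixed-group logrank, ranked and adjusted", {
  set.seed(19)
  n <- 40
  ids <- sprintf("P%03d", 1:n)
  pres <- rbinom(n, 1, 0.4) == 1
  t <- 30 * (rexp(n) / ifelse(pres, 4, 1))^(1 / 1.2)
  coh <- tibble::tibble(patient_id = ids, os_months = t, event = 1L)
  mk <- tibble::tibble(
    marker_id = c("signal", "noise"),
    pathway_id = "pw", pathway_state = "disrupted",
    feature = "f", feature_level = c("high", "low"),
    n_present = c(sum(pres), 20L), n_absent = c(sum(!pres), 20L),
    n_missing = 0L,
    presence = list(tibble::tibble(patient_id = ids, present = pres),
                    tibble::tibble(patient_id = ids,
                                   present = rep(c(TRUE, FALSE), 20))))
  ev <- evaluate_markers(mk, coh)
  expect_equal(ev$marker_id[1], "signal")
  expect_equal(ev$rank, 1:2)
  expect_equal(as.numeric(ev$p_adj), pmin(1, 2 * ev$p))
  # deterministic given states and levels
  ev2 <- evaluate_markers(mk, coh)
  expect_identical(ev$p, ev2$p)
  # matches a direct logrank on the presence grouping
  lr <- logrank_test(coh$os_months, coh$event, pres)
  expect_equal(ev$p[ev$marker_id == "signal"], lr$p)
  # single retained marker gives a one-row table
  ev1 <- evaluate_markers(mk[1, ], coh)
  expect_equal(nrow(ev1), 1)
})

test_that("permuted survival calibrates marker discoveries", {
  # marker definitions frozen, survival permuted: adjusted discoveries rare
  st <- simulate_study(62, simulation_truth(hazard_ratio = 1,
                                            texture_shift = 0),
                       seed = 77, level = "feature")
  rep <- suppress_radgen_warnings(
    run_full_analysis(st$cohort, st$variants, features = st$features,
                      run_ml = FALSE, config = radgen_config(seed = 77)))
  mk <- dplyr::select(rep$markers, -"statistic", -"p", -"p_adj", -"rank")
  fracs <- vapply(1:30, function(i) {
    set.seed(i)
    perm <- tibble::tibble(patient_id = st$cohort$patient_id,
                           os_months = sample(st$cohort$os_months),
                           event = sample(st$cohort$event))
    mean(evaluate_markers(mk, perm)$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
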