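# Synthetic-study generator. Emulates the statistical structure the analysis
# assumes: ~62-patient cohorts with Weibull overall survival (median ~25
# months, administrative censoring), somatic mutations with CADD-distributed
# deleteriousness plus germline-like contaminants, and ellipsoidal PET/CT
# lesions whose size/texture are coupled to latent pathway states and whose
# presence in a planted (pathway state, radiomic level) conjunction
# multiplies the hazard.

#' Ground-truth specification for a synthetic study
#'
#' @param pathways Pathway roster tibble.
#' @param disruption_prev Per-pathway probability of the "disrupted" latent
#'   state.
#' @param marker_pathway,marker_state,marker_feature,marker_level The planted
#'   prognostic radiogenomic marker: patients whose latent pathway state
#'   matches `marker_state` and whose latent size/texture driver is in the
#'   `marker_level` half experience `hazard_ratio` times the baseline hazard.
#' @param hazard_ratio Hazard multiplier of marker presence (> 0; 1 = null).
#' @param weibull_shape,weibull_median_months Baseline Weibull survival:
#'   shape 1.2 (curved KM), scale tuned so the baseline median is 25 months.
#' @param censor_max_months Administrative censoring time ~ U(0, max).
#' @param texture_shift Standardized mean difference of the coupled latent
#'   feature driver between disrupted and functional patients (SD units).
#' @param gene_rate Expected background somatic variants per patient.
#' @param extra_deleterious Expected extra deleterious variants per disrupted
#'   pathway.
#' @param contaminant_rate Expected germline-like contaminants per patient as
#'   a fraction of the background somatic count.
#' @param frac_fail_evidence Fraction of somatic records drawn to fail the
#'   caller-evidence rule.
#' @param n_recurrent Number of recurrent artifact variant keys carried by
#'   >10% of samples (removed by the cohort-frequency rule).
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(pathways = default_pathway_sets(),
                             disruption_prev = 0.4,
                             marker_pathway = "cellular_senescence",
                             marker_state = "disrupted",
                             marker_feature = "PET.stat.sum",
                             marker_level = "high",
                             hazard_ratio = 3,
                             weibull_shape = 1.2,
                             weibull_median_months = 25,
                             censor_max_months = 130,
                             texture_shift = 1.5,
                             gene_rate = 8,
                             extra_deleterious = 4,
                             contaminant_rate = 0.3,
                             frac_fail_evidence = 0.08,
                             n_recurrent = 2) {
  assert_that(hazard_ratio > 0, "hazard_ratio must be > 0")
  assert_that(censor_max_months > 0, "censor_max_months must be > 0")
  structure(list(
    pathways = pathways, disruption_prev = disruption_prev,
    marker_pathway = marker_pathway, marker_state = marker_state,
    marker_feature = marker_feature, marker_level = marker_level,
    hazard_ratio = hazard_ratio, weibull_shape = weibull_shape,
    weibull_scale = weibull_median_months / log(2)^(1 / weibull_shape),
    censor_max_months = censor_max_months, texture_shift = texture_shift,
    gene_rate = gene_rate, extra_deleterious = extra_deleterious,
    contaminant_rate = contaminant_rate,
    frac_fail_evidence = frac_fail_evidence, n_recurrent = n_recurrent
  ), class = "simulation_truth")
}

#' Generate a synthetic study
#'
#' Draws latent pathway states, couples a latent lesion-size/texture driver
#' to the planted pathway (standardized shift `texture_shift`), assigns
#' Weibull survival with the planted marker's hazard ratio and uniform
#' administrative censoring, and generates the variant table and (optionally)
#' PET/CT volumes. All draws flow from one base seed; per-patient substreams
#' are derived by stable hashing of the patient id.
#'
#' @param n_patients Number of patients (>= 20; a warning is recorded when
#'   the 15% minimum group size leaves < 3 patients per group).
#' @param truth A [simulation_truth()].
#' @param seed Base RNG seed.
#' @param level `"image"` renders PET/CT volumes per patient (features are
#'   then extracted by the radiomics stage); `"feature"` skips image
#'   rendering and draws the radiomic feature matrix directly from a small
#'   latent-factor model (factor 1 is the driver; features load ~0.97 on one
#'   factor each, mirroring the redundancy of same-image radiomics) — used
#'   for statistical-calibration studies where rendering thousands of
#'   volumes would only add cost, not information.
#' @param spacing_mm Voxel spacing for image rendering.
#' @return A list of class `synthetic_study`: `cohort`, `variants`, `images`
#'   (or NULL), `features` (feature-level mode), `truth_tbl` (per-patient
#'   latent states and marker presence), `truth`.
#' @export
simulate_study <- function(n_patients, truth = simulation_truth(), seed = 1L,
                           level = c("image", "feature"), spacing_mm = 2) {
  level <- match.arg(level)
  assert_that(n_patients >= 20, "n_patients must be >= 20")
  if (ceiling(0.15 * n_patients) < 3) {
    warn("cohort too small for a stable 15% minimum group size")
  }
  ids <- sprintf("P%03d", seq_len(n_patients))
  pw_ids <- truth$pathways$pathway_id

  states <- with_seed(derive_seed(seed, "states"), {
    m <- matrix(rbinom(n_patients * length(pw_ids), 1, truth$disruption_prev),
                nrow = n_patients,
                dimnames = list(ids, pw_ids))
    ifelse(m == 1, "disrupted", "functional")
  })

  # latent driver of lesion size/texture, shifted for the planted pathway
  z <- with_seed(derive_seed(seed, "driver"), rnorm(n_patients))
  coupled <- unname(states[, truth$marker_pathway] == "disrupted")
  z <- z + ifelse(coupled, truth$texture_shift, 0)
  lvl_high <- z > stats::qnorm(0.5, mean = truth$texture_shift *
                                 truth$disruption_prev)
  marker_present <- unname(states[, truth$marker_pathway] == truth$marker_state) &
    (if (truth$marker_level == "high") lvl_high else !lvl_high)

  cohort <- with_seed(derive_seed(seed, "survival"), {
    hr <- ifelse(marker_present, truth$hazard_ratio, 1)
    t_event <- truth$weibull_scale *
      (stats::rexp(n_patients) / hr)^(1 / truth$weibull_shape)
    cens <- runif(n_patients, 0, truth$censor_max_months)
    tibble(
      patient_id = ids,
      os_months = pmin(t_event, cens),
      event = as.integer(t_event <= cens),
      age_years = round(pmin(pmax(rnorm(n_patients, 60, 10), 35), 85)),
      sex = sample(c("m", "f"), n_patients, replace = TRUE,
                   prob = c(0.73, 0.27)),
      stage = sample(c("I", "II", "III", "IVA", "IVB", "IVC"), n_patients,
                     replace = TRUE,
                     prob = c(0.06, 0.08, 0.06, 0.62, 0.05, 0.13))
    )
  })

  variants <- generate_variants(states, truth$pathways, truth, seed)

  images <- NULL; features <- NULL
  if (level == "image") {
    images <- setNames(map(seq_len(n_patients), function(i) {
      generate_patient_images(z[i], spacing_mm,
                              derive_seed(seed, paste0("img_", ids[i])))
    }), ids)
  } else {
    features <- with_seed(derive_seed(seed, "features"), {
      # Radiomic features are massively redundant in practice (they all
      # derive from the same image): emulate that with a small latent-factor
      # structure. Factor 1 is the size/uptake driver z; the rest are
      # independent image factors. Each feature loads ~0.9 on one factor
      # round-robin, plus idiosyncratic noise. The coupled feature carries
      # the driver itself so its standardized shift between pathway states
      # is exactly texture_shift, as specified.
      nm <- radiomic_feature_names()
      n_factors <- 5
      fac <- cbind(scale(z)[, 1],
                   matrix(rnorm(n_patients * (n_factors - 1)),
                          nrow = n_patients))
      assign_f <- rep_len(seq_len(n_factors), length(nm))
      # within-family correlation ~0.95, matching observed redundancy of
      # same-image radiomic features (collapsed by the 0.9 redundancy cut)
      s_idio <- sqrt(0.05)
      fm <- vapply(seq_along(nm), function(j) {
        sqrt(1 - s_idio^2) * fac[, assign_f[j]] + s_idio * rnorm(n_patients)
      }, numeric(n_patients))
      colnames(fm) <- nm
      fm[, truth$marker_feature] <- z
      bind_cols(tibble(patient_id = ids), as_tibble(fm))
    })
  }

  truth_tbl <- bind_cols(
    tibble(patient_id = ids, latent_driver = z,
           marker_present = marker_present),
    as_tibble(states) |> setNames(paste0("state.", pw_ids))
  )
  structure(list(cohort = cohort, variants = variants, images = images,
                 features = features, truth_tbl = truth_tbl, truth = truth,
                 seed = as.integer(seed), level = level),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d patients, %d variant records, %s\n",
              nrow(x$cohort), nrow(x$variants),
              if (x$level == "image") sprintf("%d PET/CT pairs", length(x$images))
              else "feature-level (no images)"))
  invisible(x)
}

# canonical 110 feature names produced by extract_features()
radiomic_feature_names <- function() {
  base <- c("morph.vol", "morph.diam", "morph.surf", "morph.sv.ratio",
            "morph.comp.1", "morph.comp.2", "morph.sph", "morph.sph.dispr",
            "stat.mean", "stat.sum", "stat.var", "stat.skew", "stat.kurt",
            "stat.median", "stat.min", "stat.p10", "stat.p90", "stat.max",
            "stat.iqr", "stat.range", "stat.mad", "stat.medad", "stat.cov",
            "stat.qcod", "stat.energy", "stat.rms",
            "ih.mean", "ih.var", "ih.skew", "ih.kurt", "ih.median", "ih.min",
            "ih.p10", "ih.p90", "ih.max", "ih.mode", "ih.iqr", "ih.range",
            "ih.entropy", "ih.uniformity",
            "szm.sze", "szm.lze", "szm.lgze", "szm.hgze", "szm.szlge",
            "szm.szhge", "szm.lzlge", "szm.lzhge", "szm.glnu.norm",
            "szm.zsnu.norm", "szm.z.perc", "szm.gl.var")
  c(paste0("PET.", base), paste0("CT.", base),
    "SUVmax", "SUVmin", "SUVmean", "SUVpeak", "MTV", "TLG")
}

#' Generate the annotated variant table for given latent states
#'
#' Background somatic variants (CADD mixture: 70% benign-like U(0,10), 30%
#' deleterious U(15,40)), extra deleterious variants in the genes of each
#' disrupted pathway, germline-like contaminants (population AF ~ U(0.05,
#' 0.5) in all three databases, half also ClinVar benign/likely benign), a
#' configurable fraction of records failing the caller-evidence rule, and a
#' few recurrent artifact keys carried by > 10% of samples. The returned
#' tibble carries a generator-only `truth_class` column
#' (somatic/contaminant/artifact) dropped by [write_variant_table()].
#'
#' @param patient_states Character matrix patients x pathways
#'   ("functional"/"disrupted"), rownames = patient ids.
#' @param pathways Pathway tibble.
#' @param params A [simulation_truth()] (rate parameters are read from it).
#' @param seed Base seed.
#' @return A validated variant tibble with `truth_class`.
#' @export
generate_variants <- function(patient_states, pathways, params, seed = 1L) {
  assert_that(nrow(pathways) > 0, "empty pathway set")
  ids <- rownames(patient_states)
  gene_pool <- unique(c(unlist(pathways$genes),
                        sprintf("FILLER%02d", 1:30)))
  rec_keys <- if (params$n_recurrent > 0)
    sprintf("artifact:%d", seq_len(params$n_recurrent)) else character(0)

  per_patient <- map(ids, function(pid) {
    with_seed(derive_seed(seed, paste0("var_", pid)), {
      rows <- list()
      n_bg <- rpois(1, params$gene_rate)
      if (n_bg > 0) {
        genes <- sample(gene_pool, n_bg, replace = TRUE)
        deleterious <- runif(n_bg) < 0.3
        cadd <- ifelse(deleterious, runif(n_bg, 15, 40), runif(n_bg, 0, 10))
        rows$bg <- tibble(sample = pid, gene = genes,
                          variant_key = sprintf("%s:%s:%06d", genes, pid,
                                                sample.int(1e6, n_bg)),
                          cadd_phred = cadd, truth_class = "somatic")
      }
      dis_pw <- colnames(patient_states)[patient_states[pid, ] == "disrupted"]
      if (length(dis_pw) > 0) {
        extra <- map(dis_pw, function(pw) {
          n_ex <- rpois(1, params$extra_deleterious)
          if (n_ex == 0) return(NULL)
          pg <- pathways$genes[[match(pw, pathways$pathway_id)]]
          genes <- sample(pg, n_ex, replace = TRUE)
          tibble(sample = pid, gene = genes,
                 variant_key = sprintf("%s:%s:%06d", genes, pid,
                                       sample.int(1e6, n_ex)),
                 cadd_phred = runif(n_ex, 20, 40), truth_class = "somatic")
        })
        rows$extra <- bind_rows(extra)
      }
      n_somatic <- sum(map_int(rows, nrow))
      n_cont <- rpois(1, params$contaminant_rate * max(1, n_somatic))
      if (n_cont > 0) {
        genes <- sample(gene_pool, n_cont, replace = TRUE)
        rows$cont <- tibble(sample = pid, gene = genes,
                            variant_key = sprintf("germ:%s:%06d", genes,
                                                  sample.int(1e6, n_cont)),
                            cadd_phred = runif(n_cont, 0, 25),
                            truth_class = "contaminant")
      }
      if (length(rec_keys) > 0) {
        carry <- runif(length(rec_keys)) < 0.2
        if (any(carry)) {
          rows$rec <- tibble(sample = pid, gene = "FILLER01",
                             variant_key = rec_keys[carry],
                             cadd_phred = runif(sum(carry), 0, 10),
                             truth_class = "artifact")
        }
      }
      v <- bind_rows(rows)
      if (nrow(v) == 0) return(v)
      n <- nrow(v)
      # caller support and read counts; a fraction fails the evidence rule
      both <- runif(n) < 0.8
      fail_ev <- runif(n) < params$frac_fail_evidence
      reads <- ifelse(both, 11 + rpois(n, 25), 21 + rpois(n, 30))
      reads[fail_ev & both] <- sample.int(10, sum(fail_ev & both), replace = TRUE)
      reads[fail_ev & !both] <- sample.int(20, sum(fail_ev & !both), replace = TRUE)
      v$called_by <- ifelse(both, "callerA,callerB",
                            ifelse(runif(n) < 0.5, "callerA", "callerB"))
      v$alt_reads <- as.integer(reads)
      # population AFs: somatic records rare/missing, contaminants common
      is_cont <- v$truth_class == "contaminant"
      af_mis <- runif(n) < 0.6
      af1 <- ifelse(is_cont, runif(n, 0.05, 0.5),
                    ifelse(af_mis, NA, runif(n, 0, 0.005)))
      af2 <- ifelse(is_cont, runif(n, 0.05, 0.5),
                    ifelse(runif(n) < 0.6, NA, runif(n, 0, 0.005)))
      af3 <- ifelse(is_cont, runif(n, 0.05, 0.5),
                    ifelse(runif(n) < 0.6, NA, runif(n, 0, 0.005)))
      v$af_db1 <- af1; v$af_db2 <- af2; v$af_db3 <- af3
      benign <- is_cont & runif(n) < 0.5
      v$clinvar <- ifelse(benign,
                          ifelse(runif(n) < 0.5, "benign", "likely_benign"),
                          ifelse(runif(n) < 0.1, "other", "none"))
      v
    })
  })
  out <- bind_rows(per_patient)
  if (nrow(out) == 0) {
    return(tibble(sample = character(), gene = character(),
                  variant_key = character(), cadd_phred = numeric(),
                  called_by = character(), alt_reads = integer(),
                  af_db1 = numeric(), af_db2 = numeric(), af_db3 = numeric(),
                  clinvar = character(), truth_class = character(),
                  n_callers = integer()))
  }
  validate_variants(out)
}

# smooth white noise with a separable box-average filter (3 passes ~
# Gaussian); spatially correlated texture so size-zone features are
# non-degenerate under voxel-independent noise.
correlated_noise <- function(dims, width = 3) {
  arr <- array(rnorm(prod(dims)), dim = dims)
  half <- (width - 1L) %/% 2L
  smooth_axis <- function(a, axis) {
    ap <- aperm(a, c(axis, setdiff(1:3, axis)))
    dd <- dim(ap)
    m <- matrix(ap, nrow = dd[1])
    # reflect-pad rows, then a moving average as a sum of shifted slices
    mp <- rbind(m[half:1, , drop = FALSE], m,
                m[dd[1]:(dd[1] - half + 1), , drop = FALSE])
    acc <- matrix(0, dd[1], ncol(m))
    for (s in 0:(width - 1)) acc <- acc + mp[(1 + s):(dd[1] + s), , drop = FALSE]
    aperm(array(acc / width, dim = dd), order(c(axis, setdiff(1:3, axis))))
  }
  for (pass in 1:2) for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr / sd(arr)
}

#' Generate a synthetic ellipsoidal lesion volume
#'
#' Ellipsoidal mask of the requested volume (fixed mild anisotropy), intensity
#' = base level + spatially correlated noise whose amplitude scales with
#' `heterogeneity`, low-intensity background, and (PET) a homogeneous
#' reference region in a grid corner distant from the lesion.
#'
#' @param volume_mm3 Target lesion volume (> 0).
#' @param heterogeneity Texture amplitude (>= 0; 0 = homogeneous lesion).
#' @param spacing_mm Isotropic voxel spacing.
#' @param seed RNG seed.
#' @param modality `"PET"` or `"CT"`.
#' @param base Lesion base intensity (SUV or HU).
#' @param background Background intensity.
#' @param ref_level Reference-region intensity (PET only).
#' @return A [voi()]; attribute `too_small` is set when the mask is below 64
#'   voxels at the requested spacing.
#' @export
generate_lesion_image <- function(volume_mm3, heterogeneity = 1,
                                  spacing_mm = 2, seed = 1L,
                                  modality = c("PET", "CT"), base = NULL,
                                  background = NULL, ref_level = 1.5) {
  modality <- match.arg(modality)
  assert_that(volume_mm3 > 0, "volume_mm3 must be > 0")
  assert_that(heterogeneity >= 0, "heterogeneity must be >= 0")
  if (is.null(base)) base <- if (modality == "PET") 6 else 45
  if (is.null(background)) background <- if (modality == "PET") 0.3 else 0
  sp <- spacing_mm
  # ellipsoid semi-axes with mild anisotropy, volume-matched
  aniso <- c(1, 0.85, 1.15)
  r0 <- (3 * volume_mm3 / (4 * pi * prod(aniso)))^(1 / 3)
  semi <- r0 * aniso
  margin <- 8L
  half <- ceiling(semi / sp) + margin
  dims <- 2L * half + 1L
  ctr <- half + 1L
  ax <- function(k) ((seq_len(dims[k]) - ctr[k]) * sp) / semi[k]
  ex <- ax(1); ey <- ax(2); ez <- ax(3)
  dist2 <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`)
  mask <- dist2 <= 1
  with_seed(seed, {
    noise <- correlated_noise(dims)
    inten <- array(background, dim = dims) +
      abs(rnorm(prod(dims), 0, 0.02))
    inten[mask] <- base
    inten <- inten + heterogeneity * noise * ifelse(mask, 1, 0.05)
    inten <- pmax(inten, 0)
    ref <- NULL
    if (modality == "PET") {
      ref <- array(FALSE, dim = dims)
      ref[1:4, 1:4, 1:4] <- TRUE
      inten[ref] <- ref_level + rnorm(64, 0, 0.01)
    }
    v <- voi(array(inten, dim = dims), mask, rep(sp, 3), modality = modality,
             reference = ref)
    if (sum(mask) < 64) attr(v, "too_small") <- TRUE
    v
  })
}

# PET + CT pair for one patient from the latent size/texture driver
generate_patient_images <- function(z, spacing_mm, seed) {
  vol <- 3500 * exp(0.55 * z)
  het_pet <- 0.9 * exp(0.3 * z)
  het_ct <- 6 * exp(0.2 * z)
  suv <- 6 * exp(0.25 * z)
  list(
    pet = generate_lesion_image(vol, het_pet, spacing_mm,
                                seed = derive_seed(seed, "pet"),
                                modality = "PET", base = suv),
    ct = generate_lesion_image(vol, het_ct, spacing_mm,
                               seed = derive_seed(seed, "ct"),
                               modality = "CT")
  )
}

#' Write a synthetic study to disk
#'
#' Writes the clinical CSV, variant TSV, pathway GMT, per-patient volume text
#' files, and the ground truth as JSON (requires jsonlite) into `dir`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$cohort, file.path(dir, "clinical.csv"), progress = FALSE)
  write_variant_table(study$variants, file.path(dir, "variants.tsv"))
  write_gene_sets(study$truth$pathways, file.path(dir, "pathways.gmt"))
  if (!is.null(study$features)) {
    readr::write_csv(study$features, file.path(dir, "features.csv"),
                     progress = FALSE)
  }
  if (!is.null(study$images)) {
    imgdir <- file.path(dir, "images")
    dir.create(imgdir, showWarnings = FALSE)
    for (pid in names(study$images)) {
      write_voi(study$images[[pid]]$pet, file.path(imgdir, paste0(pid, ".pet")))
      write_voi(study$images[[pid]]$ct, file.path(imgdir, paste0(pid, ".ct")))
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- study$truth
    tr$pathways <- NULL
    jsonlite::write_json(c(tr, list(seed = study$seed)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
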