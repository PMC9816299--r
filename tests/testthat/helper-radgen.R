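# Shared fixtures and independent oracles, built in code at test time.

# ---- independent oracles -------------------------------------------------

# Brute-force 26-connected zone labeller: repeated set growth by scanning
# all voxel coordinates (no linear-index arithmetic, independent of the
# implementation's padded-array BFS).
brute_zones <- function(levels) {
  idx <- which(levels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(level = integer(), size = integer()))
  lv <- levels[idx]
  assigned <- rep(FALSE, nrow(idx))
  out <- list()
  for (s in seq_len(nrow(idx))) {
    if (assigned[s]) next
    members <- s
    assigned[s] <- TRUE
    repeat {
      grew <- FALSE
      for (cand in which(!assigned & lv == lv[s])) {
        d <- abs(sweep(idx[members, , drop = FALSE], 2, idx[cand, ], `-`))
        if (any(apply(d, 1, max) <= 1)) {
          members <- c(members, cand)
          assigned[cand] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    out[[length(out) + 1]] <- data.frame(level = lv[s], size = length(members))
  }
  do.call(rbind, out)
}

# GLSZM from the brute-force labeller, in the same sparse form as glszm()
brute_glszm <- function(levels) {
  z <- brute_zones(levels)
  if (nrow(z) == 0) return(tibble::tibble(level = integer(), size = integer(),
                                          count = integer()))
  agg <- stats::aggregate(list(count = rep(1L, nrow(z))),
                          by = list(level = z$level, size = z$size), FUN = sum)
  tibble::as_tibble(agg[order(agg$level, agg$size), ])
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (small n only).
enumerate_mw_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(vals), n1)
  u_of <- function(a) {
    xs <- vals[a]; ys <- vals[-a]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (length(vals) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Kaplan-Meier product-limit by hand
hand_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Naive exhaustive cutoff scan used as the optimize_cutoff oracle
naive_best_cutoff <- function(values, time, event, min_group_frac = 0.15) {
  uq <- sort(unique(values))
  if (length(uq) < 2) return(NULL)
  cuts <- (uq[-1] + uq[-length(uq)]) / 2
  best <- NULL
  for (ct in cuts) {
    hi <- values > ct
    if (min(sum(hi), sum(!hi)) < ceiling(min_group_frac * length(values))) next
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ hi)
    p <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p - 1e-12 ||
        (abs(p - best$p) <= 1e-12 && ct < best$cutoff)) {
      best <- list(cutoff = ct, p = p)
    }
  }
  best
}

# ---- fixtures ------------------------------------------------------------

# small PET/CT pair reused across radiomics tests
make_test_pair <- function(volume = 4000, seed = 11) {
  list(pet = generate_lesion_image(volume, 1, 2, seed = seed, modality = "PET"),
       ct = generate_lesion_image(volume, 6, 2, seed = seed + 1,
                                  modality = "CT"))
}

# Ten-variant fixture exercising each filtering rule once; n_samples = 20.
# 11 records over 10 distinct variant keys: "shared" is carried by 2/20
# samples (0.10, removed by the strict frequency rule; 2 records), v2 fails
# caller evidence (both callers, exactly 10 reads), v3 fails population AF
# (db2 = 0.02), v4 is ClinVar benign; v5..v10 pass every rule, so 6 of the
# 10 distinct variants are retained.
make_filter_fixture <- function() {
  tibble::tibble(
    sample = c("S1", "S2", "S1", "S1", "S1", "S2", "S2", "S3", "S3", "S4",
               "S4"),
    gene = c("G0", "G0", paste0("G", 2:10)),
    variant_key = c("shared", "shared", paste0("v", 2:10)),
    cadd_phred = seq(5, 50, length.out = 11),
    called_by = c("callerA,callerB", "callerA,callerB",  # shared
                  "callerA,callerB",                      # v2: 10 reads
                  "callerA,callerB",                      # v3: AF fail
                  "callerB",                              # v4: benign
                  "callerA,callerB",                      # v5: 11 reads, pass
                  "callerA",                              # v6: 21 reads, pass
                  "callerA,callerB", "callerB",
                  "callerA,callerB", "callerA"),
    alt_reads = c(30L, 30L, 10L, 30L, 40L, 11L, 21L, 25L, 35L, 28L, 50L),
    af_db1 = c(NA, NA, 0.001, 0.005, 0.0, NA, 0.002, NA, 0.009, NA, NA),
    af_db2 = c(NA, NA, NA, 0.02, NA, NA, NA, 0.003, NA, NA, 0.001),
    af_db3 = c(0.001, 0.001, NA, 0.001, NA, 0.004, NA, NA, NA, 0.002, NA),
    clinvar = c("none", "none", "other", "none", "benign", "none", "none",
                "none", "other", "none", "none")
  )
}

suppress_radgen_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

# muffle every warning except those matching `keep` (so expect_warning can
# still see the one under test)
suppress_warnings_except <- function(expr, keep) {
  withCallingHandlers(expr, warning = function(w) {
    if (!grepl(keep, conditionMessage(w))) invokeRestart("muffleWarning")
  })
}
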