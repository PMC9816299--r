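# IBSI-style radiomic features. The default roster has 52 features per
# modality: 8 morphology, 18 intensity statistics, 14 intensity histogram,
# 12 grey-level size-zone (GLSZM) features; PET additionally yields the six
# SUV metrics (SUVmax/min/mean/peak, MTV, TLG). Values are in arbitrary
# units unless stated.

#' Sum of masked intensities (stat.sum)
#'
#' The summed activity throughout the lesion; for PET this behaves like a
#' continuous analogue of metabolic tumor volume (strong volume confounding
#' by construction: stat.sum = mean intensity x voxel count).
#'
#' @param x A [voi()].
#' @return The sum of intensities inside the lesion mask.
#' @export
stat_sum <- function(x) {
  assert_that(any(x$mask), "empty mask", class = "radgen_validation_error")
  sum(x$intensity[x$mask])
}

#' Excess kurtosis of discretized intensities (ih.kurt)
#'
#' Population-moment excess kurtosis mu4/mu2^2 - 3 of the masked grey
#' levels. Undefined (returns `NA`) when the levels are constant.
#'
#' @param levels Integer grey levels of the masked voxels (vector), or the
#'   `levels` array from [discretize()] together with `mask`.
#' @param mask Optional mask when `levels` is an array.
#' @return Excess kurtosis, or `NA_real_` for zero variance.
#' @export
ih_kurt <- function(levels, mask = NULL) {
  v <- if (!is.null(mask)) levels[mask] else as.vector(levels)
  mu2 <- pop_moment(v, 2)
  if (mu2 == 0) return(NA_real_)
  pop_moment(v, 4) / mu2^2 - 3
}

# ---- GLSZM ---------------------------------------------------------------

#' Grey-level size-zone matrix
#'
#' Counts 26-connected zones of equal grey level by zone size. Returned in
#' sparse form: one row per (level, size) with the number of such zones.
#'
#' @param levels 3D integer grey-level array (0 outside the mask), e.g.
#'   `discretize(...)$levels`.
#' @param mask Optional mask restricting the zones (defaults to `levels > 0`).
#' @return A tibble with columns `level`, `size`, `count`.
#' @export
glszm <- function(levels, mask = NULL) {
  if (is.null(mask)) mask <- levels > 0
  zs <- zone_sizes(levels, mask)
  if (nrow(zs) == 0) return(tibble(level = integer(), size = integer(),
                                   count = integer()))
  zs |>
    dplyr::count(.data$level, .data$size, name = "count") |>
    arrange(.data$level, .data$size)
}

# Label 26-connected zones of equal level; returns tibble(level, size) with
# one row per zone. Uses a zero-padded array so linear-index neighbour
# offsets cannot wrap across faces.
zone_sizes <- function(levels, mask) {
  d <- dim(levels)
  pd <- d + 2L
  lv <- array(0L, dim = pd)
  lv[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    ifelse(mask, levels, 0L)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_offs <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  todo <- which(lv > 0L)
  visited <- rep(FALSE, length(lv))
  out_level <- integer(0); out_size <- integer(0)
  for (start in todo) {
    if (visited[start]) next
    lvl <- lv[start]
    visited[start] <- TRUE
    frontier <- start
    size <- 1L
    while (length(frontier) > 0) {
      nbs <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nbs <- nbs[nbs >= 1 & nbs <= length(lv)]
      nbs <- nbs[!visited[nbs] & lv[nbs] == lvl]
      visited[nbs] <- TRUE
      size <- size + length(nbs)
      frontier <- nbs
    }
    out_level <- c(out_level, lvl)
    out_size <- c(out_size, size)
  }
  tibble(level = out_level, size = out_size)
}

#' GLSZM-derived features
#'
#' Twelve size-zone features computed from the sparse GLSZM: small/large zone
#' emphasis, low/high grey-level zone emphasis, the four joint emphases,
#' normalized grey-level and zone-size non-uniformity, zone percentage
#' (number of zones over masked voxels), and grey-level variance over zones.
#'
#' @param szm GLSZM tibble from [glszm()].
#' @param n_voxels Number of masked voxels.
#' @return A named list of the 12 `szm.*` features.
#' @export
szm_features <- function(szm, n_voxels) {
  assert_that(nrow(szm) > 0, "empty GLSZM")
  i <- szm$level; j <- szm$size; s <- szm$count
  nz <- sum(s)
  w <- s / nz
  mu <- sum(w * i)
  list(
    szm.sze = sum(w / j^2),
    szm.lze = sum(w * j^2),
    szm.lgze = sum(w / i^2),
    szm.hgze = sum(w * i^2),
    szm.szlge = sum(w / (i^2 * j^2)),
    szm.szhge = sum(w * i^2 / j^2),
    szm.lzlge = sum(w * j^2 / i^2),
    szm.lzhge = sum(w * i^2 * j^2),
    szm.glnu.norm = sum(tapply(w, i, sum)^2),
    szm.zsnu.norm = sum(tapply(w, j, sum)^2),
    szm.z.perc = nz / n_voxels,
    szm.gl.var = sum(w * (i - mu)^2)
  )
}

# ---- intensity statistics (18) ------------------------------------------

stat_features <- function(vals) {
  n <- length(vals)
  m <- mean(vals)
  mu2 <- pop_moment(vals, 2)
  p <- quantile(vals, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  list(
    stat.mean = m,
    stat.sum = sum(vals),
    stat.var = mu2,
    stat.skew = if (mu2 > 0) pop_moment(vals, 3) / mu2^1.5 else NA_real_,
    stat.kurt = if (mu2 > 0) pop_moment(vals, 4) / mu2^2 - 3 else NA_real_,
    stat.median = median(vals),
    stat.min = min(vals),
    stat.p10 = p[1],
    stat.p90 = p[4],
    stat.max = max(vals),
    stat.iqr = p[3] - p[2],
    stat.range = max(vals) - min(vals),
    stat.mad = mean(abs(vals - m)),
    stat.medad = median(abs(vals - median(vals))),
    stat.cov = if (m != 0) sqrt(mu2) / m else NA_real_,
    stat.qcod = if ((p[3] + p[2]) != 0) (p[3] - p[2]) / (p[3] + p[2]) else NA_real_,
    stat.energy = sum(vals^2),
    stat.rms = sqrt(mean(vals^2))
  )
}

# ---- intensity histogram (14) -------------------------------------------

ih_features <- function(lv_vals) {
  m <- mean(lv_vals)
  mu2 <- pop_moment(lv_vals, 2)
  p <- quantile(lv_vals, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  tab <- table(lv_vals)
  prob <- as.numeric(tab) / length(lv_vals)
  mode_lv <- as.numeric(names(tab)[which.max(tab)])
  list(
    ih.mean = m,
    ih.var = mu2,
    ih.skew = if (mu2 > 0) pop_moment(lv_vals, 3) / mu2^1.5 else NA_real_,
    ih.kurt = ih_kurt(lv_vals),
    ih.median = median(lv_vals),
    ih.min = min(lv_vals),
    ih.p10 = p[1],
    ih.p90 = p[4],
    ih.max = max(lv_vals),
    ih.mode = mode_lv,
    ih.iqr = p[3] - p[2],
    ih.range = max(lv_vals) - min(lv_vals),
    ih.entropy = -sum(prob * log2(prob)),
    ih.uniformity = sum(prob^2)
  )
}

# ---- morphology (8) ------------------------------------------------------

#' Morphological volume
#'
#' Voxel-count approximation: number of mask voxels times the voxel volume.
#'
#' @param mask 3D binary mask.
#' @param spacing Voxel spacing (mm, length 3).
#' @return Volume in mm^3.
#' @export
morph_vol <- function(mask, spacing) {
  assert_that(any(mask), "empty mask", class = "radgen_validation_error")
  sum(mask) * prod(spacing)
}

# Surface area by exposed-face counting (voxel approximation).
surface_area <- function(mask, spacing) {
  d <- dim(mask)
  m <- array(FALSE, dim = d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- sweep(idx, 2, s, `+`)
    exposed <- !m[nb]
    area <- area + sum(exposed) * face[ceiling(k / 2)]
  }
  area
}

morph_features <- function(mask, spacing) {
  vol <- morph_vol(mask, spacing)
  surf <- surface_area(mask, spacing)
  # maximum 3D diameter over surface voxels (voxels with an exposed face)
  d <- dim(mask)
  m <- array(FALSE, dim = d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  idx <- which(m, arr.ind = TRUE)
  nb <- function(s) m[sweep(idx, 2, s, `+`)]
  interior <- nb(c(1, 0, 0)) & nb(c(-1, 0, 0)) & nb(c(0, 1, 0)) &
    nb(c(0, -1, 0)) & nb(c(0, 0, 1)) & nb(c(0, 0, -1))
  surf_idx <- idx[!interior, , drop = FALSE]
  pts <- sweep(surf_idx, 2, c(1, 1, 1), `-`)
  pts <- sweep(pts, 2, spacing, `*`)
  diam <- max_diameter(pts)
  list(
    morph.vol = vol,
    morph.diam = diam,
    morph.surf = surf,
    morph.sv.ratio = surf / vol,
    morph.comp.1 = vol / (sqrt(pi) * surf^1.5),
    morph.comp.2 = 36 * pi * vol^2 / surf^3,
    morph.sph = (36 * pi * vol^2)^(1 / 3) / surf,
    morph.sph.dispr = surf / (36 * pi * vol^2)^(1 / 3)
  )
}

# Maximum pairwise distance between points (mm). Exact for small sets; for
# large surfaces a multi-start farthest-point iteration from the six axis
# extremes (exact for convex bodies, and within a voxel of exact for the
# near-ellipsoidal masks this package produces).
max_diameter <- function(pts) {
  m <- nrow(pts)
  if (m <= 1) return(0)
  if (m <= 600) return(max(stats::dist(pts)))
  starts <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  best <- 0
  for (s in starts) {
    i <- s
    repeat {
      d2 <- rowSums(sweep(pts, 2, pts[i, ], `-`)^2)
      j <- which.max(d2)
      if (sqrt(d2[j]) <= best + 1e-12) break
      best <- sqrt(d2[j])
      i <- j
    }
  }
  best
}

# ---- SUV metrics ---------------------------------------------------------

#' SUV metrics for a PET lesion
#'
#' Max/min/mean SUV over the (undilated) lesion mask, SUVpeak (maximal mean
#' within a 1 cm^3 sphere centred on a lesion voxel, clipped at grid bounds),
#' metabolic tumor volume MTV (lesion volume, ml), and total lesion
#' glycolysis TLG = SUVmean x MTV.
#'
#' @param pet A PET [voi()] in SUV units (unnormalized).
#' @return A named list with `SUVmax`, `SUVmin`, `SUVmean`, `SUVpeak`,
#'   `MTV`, `TLG`.
#' @export
suv_metrics <- function(pet) {
  assert_that(any(pet$mask), "empty PET mask", class = "radgen_validation_error")
  vals <- pet$intensity[pet$mask]
  sp <- pet$spacing
  r <- (3 * 1000 / (4 * pi))^(1 / 3)  # 1 cm^3 sphere radius in mm (~6.2)
  span <- floor(r / sp)
  if (any(span >= dim(pet$intensity))) warn("SUVpeak sphere clipped at grid bounds")
  og <- expand.grid(dx = -span[1]:span[1], dy = -span[2]:span[2],
                    dz = -span[3]:span[3])
  keep <- (og$dx * sp[1])^2 + (og$dy * sp[2])^2 + (og$dz * sp[3])^2 <= r^2
  og <- og[keep, , drop = FALSE]
  d <- dim(pet$intensity)
  centers <- which(pet$mask, arr.ind = TRUE)
  peak <- max(vapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1] + og$dx; cy <- centers[i, 2] + og$dy
    cz <- centers[i, 3] + og$dz
    ok <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
    mean(pet$intensity[cbind(cx[ok], cy[ok], cz[ok])])
  }, numeric(1)))
  mtv_ml <- morph_vol(pet$mask, sp) / 1000
  suv_mean <- mean(vals)
  list(SUVmax = max(vals), SUVmin = min(vals), SUVmean = suv_mean,
       SUVpeak = peak, MTV = mtv_ml, TLG = suv_mean * mtv_ml)
}

# ---- full extraction -----------------------------------------------------

modality_features <- function(v, config) {
  mask <- v$mask
  vals <- v$intensity[mask]
  disc <- discretize(v, n_bins = config$n_bins)
  lv_vals <- disc$levels[mask]
  szm <- glszm(disc$levels, mask)
  c(morph_features(mask, v$spacing),
    stat_features(vals),
    ih_features(lv_vals),
    szm_features(szm, sum(mask)))
}

#' Extract the full radiomic feature vector for a patient
#'
#' Pipeline per modality: (PET only) SUV metrics on the raw lesion, then
#' reference-region normalization; trilinear resampling to the analysis grid;
#' Chebyshev dilation of the lesion mask; fixed-bin-number discretization;
#' then 52 features per modality (8 morphology, 18 intensity statistics,
#' 14 intensity histogram, 12 GLSZM), prefixed `PET.` / `CT.` - 104 in total
#' plus the 6 SUV metrics.
#'
#' @param pet,ct PET and CT [voi()] objects for the same lesion.
#' @param config A [radgen_config()].
#' @return A one-row tibble with 110 feature columns.
#' @export
extract_features <- function(pet, ct, config = radgen_config()) {
  assert_that(check_min_size(pet$mask, config$min_voxels) &&
                check_min_size(ct$mask, config$min_voxels),
              paste0("lesion below ", config$min_voxels, " voxels"),
              class = "radgen_validation_error")
  suv <- suv_metrics(pet)
  target <- config$resample_mm[1]
  petn <- normalize_suv(pet)
  prep <- function(v) {
    v <- resample_voi(v, target)
    v$mask <- dilate_mask(v$mask, config$dilation_voxels)
    v
  }
  petf <- modality_features(prep(petn), config)
  ctf <- modality_features(prep(ct), config)
  fx <- c(setNames(petf, paste0("PET.", names(petf))),
          setNames(ctf, paste0("CT.", names(ctf))),
          suv)
  as_tibble(fx)
}
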