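# VOI preprocessing: minimum-size QC, reference-region SUV normalization,
# isotropic resampling (trilinear intensities, nearest-neighbour masks),
# Chebyshev mask dilation, and intensity discretization.

#' Lesion size QC
#'
#' Lesions below 64 voxels are excluded from radiomic analysis (texture
#' matrices are unstable on smaller supports).
#'
#' @param mask 3D binary mask.
#' @param min_voxels Minimum voxel count.
#' @return `TRUE` iff the mask has at least `min_voxels` voxels.
#' @export
check_min_size <- function(mask, min_voxels = 64) {
  sum(mask) >= min_voxels
}

#' Normalize a PET volume by its reference region
#'
#' Divides all intensities by the mean intensity inside the reference-region
#' mask (background normalization before interpolation). Idempotent once the
#' reference mean is 1.
#'
#' @param pet A PET [voi()] with a non-empty reference mask.
#' @return The normalized `voi`.
#' @export
normalize_suv <- function(pet) {
  assert_that(!is.null(pet$reference) && any(pet$reference),
              "PET volume has no reference-region mask")
  ref_mean <- mean(pet$intensity[pet$reference])
  assert_that(is.finite(ref_mean) && ref_mean > 0,
              "reference region mean must be positive",
              class = "radgen_validation_error")
  pet$intensity <- pet$intensity / ref_mean
  pet
}

# Trilinear interpolation of a 3D array at fractional voxel indices
# (1-based voxel centers), clamped at the borders.
trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(floor(xi), d[1]); x1 <- cl(x0 + 1, d[1]); fx <- cl(xi, d[1]) - x0
  y0 <- cl(floor(yi), d[2]); y1 <- cl(y0 + 1, d[2]); fy <- cl(yi, d[2]) - y0
  z0 <- cl(floor(zi), d[3]); z1 <- cl(z0 + 1, d[3]); fz <- cl(zi, d[3]) - z0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  at <- function(i, j, k) arr[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
  c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
  c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
  c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a VOI to an isotropic grid
#'
#' Intensities are trilinearly interpolated, masks resampled by nearest
#' neighbour, and the spacing updated. Resampling to the current isotropic
#' spacing is an exact identity.
#'
#' @param x A [voi()].
#' @param target_mm Isotropic target spacing (mm).
#' @return The resampled `voi`.
#' @export
resample_voi <- function(x, target_mm) {
  assert_that(target_mm > 0, "target spacing must be positive")
  sp <- x$spacing
  if (all(sp == target_mm)) return(x)
  d <- dim(x$intensity)
  extent <- d * sp
  nd <- pmax(1L, as.integer(round(extent / target_mm)))
  # new voxel centers in old fractional index space
  ax <- function(k) ((seq_len(nd[k]) - 0.5) * target_mm) / sp[k] + 0.5
  gx <- ax(1); gy <- ax(2); gz <- ax(3)
  xi <- rep(gx, times = nd[2] * nd[3])
  yi <- rep(rep(gy, each = nd[1]), times = nd[3])
  zi <- rep(gz, each = nd[1] * nd[2])
  newint <- array(trilinear(x$intensity, xi, yi, zi), dim = nd)
  nn <- function(m) {
    idx <- cbind(pmin(pmax(round(xi), 1), d[1]),
                 pmin(pmax(round(yi), 1), d[2]),
                 pmin(pmax(round(zi), 1), d[3]))
    array(m[idx], dim = nd)
  }
  newmask <- nn(x$mask)
  if (!any(newmask)) abort("lesion mask vanished during resampling",
                           class = "radgen_validation_error")
  newref <- if (!is.null(x$reference)) nn(x$reference)
  voi(newint, newmask, rep(target_mm, 3), modality = x$modality,
      reference = newref)
}

#' Dilate a binary mask
#'
#' Chebyshev (cube) dilation: a voxel belongs to the dilated mask iff a mask
#' voxel lies within `voxels` steps along every axis (i.e. a cube structuring
#' element of half-width `voxels`), clipped at the grid bounds. Implemented
#' separably as three 1D sliding-window maxima.
#'
#' @param mask 3D binary array.
#' @param voxels Dilation radius in voxels (0 = identity).
#' @return The dilated logical array.
#' @export
dilate_mask <- function(mask, voxels = 5) {
  m <- array(as.logical(mask), dim = dim(mask))
  if (voxels == 0) return(m)
  d <- dim(m)
  shift_or <- function(a, axis, s) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (s > 0) { idx_dst[[axis]] <- (1 + s):n; idx_src[[axis]] <- 1:(n - s) }
    else if (s < 0) { idx_dst[[axis]] <- 1:(n + s); idx_src[[axis]] <- (1 - s):n }
    if (length(idx_dst[[axis]]) == 0 || (s != 0 && n <= abs(s))) return(out)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) {
    acc <- m
    for (s in setdiff(-voxels:voxels, 0)) acc <- acc | shift_or(m, axis, s)
    m <- acc
  }
  m
}

#' Discretize masked intensities into grey levels
#'
#' Fixed-bin-number (default, 32 bins spanning the masked intensity range —
#' invariant to affine intensity transforms) or fixed-bin-size discretization.
#' A constant region maps entirely to level 1.
#'
#' @param x A [voi()] or a 3D intensity array.
#' @param mask Binary mask (taken from `x` when it is a `voi`).
#' @param n_bins Number of grey levels for fixed-bin-number.
#' @param scheme `"fixed_bin_number"` or `"fixed_bin_size"`.
#' @param bin_size Bin width for fixed-bin-size.
#' @return A list: `levels` (3D integer array, 0 outside the mask), `n_levels`,
#'   `edges` (bin edges).
#' @export
discretize <- function(x, mask = NULL, n_bins = 32,
                       scheme = c("fixed_bin_number", "fixed_bin_size"),
                       bin_size = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(x, "voi")) { mask <- x$mask; x <- x$intensity }
  assert_that(!is.null(mask) && any(mask), "discretize needs a non-empty mask",
              class = "radgen_validation_error")
  vals <- x[mask]
  lo <- min(vals); hi <- max(vals)
  lv <- array(0L, dim = dim(x))
  if (scheme == "fixed_bin_number") {
    if (hi == lo) {
      lv[mask] <- 1L
      n_levels <- 1L
      edges <- c(lo, hi)
    } else {
      lv[mask] <- pmin(n_bins, floor(n_bins * (vals - lo) / (hi - lo)) + 1L)
      n_levels <- as.integer(n_bins)
      edges <- seq(lo, hi, length.out = n_bins + 1)
    }
  } else {
    assert_that(!is.null(bin_size) && bin_size > 0,
                "fixed_bin_size needs a positive bin_size")
    lv[mask] <- floor((vals - lo) / bin_size) + 1L
    n_levels <- max(lv)
    edges <- lo + bin_size * (0:n_levels)
  }
  list(levels = lv, n_levels = n_levels, edges = edges)
}
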