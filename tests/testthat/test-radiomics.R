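test_that("minimum lesion size boundary is 64 voxels", {
  m <- array(FALSE, c(8, 8, 8))
  m[1:4, 1:4, 1:4] <- TRUE           # 64 voxels
  expect_true(check_min_size(m))
  m[1, 1, 1] <- FALSE                # 63
  expect_false(check_min_size(m))
  expect_false(check_min_size(array(FALSE, c(4, 4, 4))))
  expect_true(check_min_size(array(TRUE, c(10, 10, 10))))
})

test_that("SUV normalization divides by the reference mean and is idempotent", {
  arr <- array(0, c(6, 6, 6)); arr[3:4, 3:4, 3] <- c(4, 8, 4, 8)
  mask <- array(FALSE, c(6, 6, 6)); mask[3:4, 3:4, 3] <- TRUE
  ref <- array(FALSE, c(6, 6, 6)); ref[1, 1, 1:2] <- TRUE
  arr[ref] <- 2
  v <- voi(arr, mask, c(2, 2, 2), "PET", reference = ref)
  vn <- normalize_suv(v)
  expect_equal(sort(unique(vn$intensity[vn$mask])), c(2, 4))
  # after normalization the reference mean is 1 -> renormalizing is identity
  vnn <- normalize_suv(vn)
  expect_equal(vnn$intensity, vn$intensity)

  arr[ref] <- 0
  v0 <- voi(arr, mask, c(2, 2, 2), "PET", reference = ref)
  expect_error(normalize_suv(v0), "positive")
})

test_that("resampling preserves constants, is identity at equal spacing", {
  arr <- array(7, c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10)); mask[4:7, 4:7, 4:7] <- TRUE
  v <- voi(arr, mask, c(2, 2, 2), "CT")
  expect_identical(resample_voi(v, 2), v)
  v4 <- resample_voi(v, 4)
  expect_true(all(abs(v4$intensity - 7) < 1e-12))
  # downsampling 2 -> 4 mm halves linear voxel counts (+-1)
  expect_true(all(abs(dim(v4$intensity) - 5) <= 1))
  expect_equal(v4$spacing, c(4, 4, 4))
  # smooth gradient survives round trip approximately
  g <- array(rep(seq_len(10), 100), c(10, 10, 10)) * 1.0
  vg <- voi(g, mask, c(2, 2, 2), "CT")
  vg2 <- resample_voi(vg, 4)
  expect_lt(max(abs(vg2$intensity - array(rep(seq(1.5, 9.5, 2), 25),
                                          c(5, 5, 5)))), 0.76)
})

test_that("Chebyshev dilation gives exact cube counts", {
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
  expect_equal(sum(dilate_mask(m, 5)), 11^3)      # 1331
  expect_identical(dilate_mask(m, 0), m)
  m2 <- array(FALSE, c(15, 15, 15)); m2[1, 1, 1] <- TRUE
  expect_equal(sum(dilate_mask(m2, 5)), 6^3)      # clipped corner cube
  # dilation never decreases morph.vol
  pair <- make_test_pair()
  expect_gte(morph_vol(dilate_mask(pair$pet$mask, 5), pair$pet$spacing),
             morph_vol(pair$pet$mask, pair$pet$spacing))
})

test_that("fixed-bin-number discretization spans the range, affine-invariant", {
  arr <- array(0, c(4, 4, 4)); arr[1:32] <- 0:31
  mask <- array(FALSE, c(4, 4, 4)); mask[1:32] <- TRUE
  d <- discretize(arr, mask, n_bins = 32)
  expect_setequal(d$levels[mask], 1:32)
  # constant region -> single occupied level
  dc <- discretize(array(5, c(4, 4, 4)), mask)
  expect_true(all(dc$levels[mask] == 1L))
  # affine intensity transform leaves the level grid unchanged
  d2 <- discretize(3.7 * arr + 11, mask, n_bins = 32)
  expect_identical(d$levels, d2$levels)
  expect_error(discretize(arr, array(FALSE, c(4, 4, 4))), "mask")
})

test_that("stat.sum is the masked intensity sum with its identities", {
  arr <- array(0, c(4, 4, 4)); arr[1:3] <- c(2, 3, 5)
  mask <- array(FALSE, c(4, 4, 4)); mask[1:3] <- TRUE
  v <- voi(arr, mask, c(2, 2, 2), "PET")
  expect_equal(stat_sum(v), 10)
  v2 <- v; v2$intensity <- 2 * v2$intensity
  expect_equal(stat_sum(v2), 20)
  # stat.sum = mean x voxel count
  expect_equal(stat_sum(v), mean(arr[mask]) * sum(mask))
})

test_that("ih.kurt matches hand-computed moments and flags constants", {
  expect_equal(ih_kurt(c(1, 1, 1, 5)), 21 / 9 - 3, tolerance = 1e-12)
  expect_equal(ih_kurt(c(1, 5, 1, 5)), -2)
  expect_true(is.na(ih_kurt(c(3, 3, 3))))
})

test_that("GLSZM matches the stated toy examples", {
  lv <- array(0L, c(3, 3, 3)); lv[1:2, 1:2, 1:2] <- 3L
  s <- glszm(lv)
  expect_equal(nrow(s), 1)
  expect_equal(s$level, 3L); expect_equal(s$size, 8L); expect_equal(s$count, 1L)

  # two separated single voxels of level 2
  lv2 <- array(0L, c(5, 5, 5)); lv2[1, 1, 1] <- 2L; lv2[5, 5, 5] <- 2L
  s2 <- glszm(lv2)
  expect_equal(s2$count[s2$level == 2 & s2$size == 1], 2L)

  # checkerboard: diagonal touches merge under 26-connectivity
  lv3 <- array(0L, c(3, 3, 1))
  lv3[cbind(c(1, 3, 2, 1, 3), c(1, 1, 2, 3, 3), 1)] <- 1L
  s3 <- glszm(lv3)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$size, 5L)
})

test_that("GLSZM equals the brute-force labeller on random grids", {
  set.seed(99)
  for (i in 1:40) {
    lv <- array(sample(0:2, 27, replace = TRUE), c(3, 3, 3))
    expect_equal(glszm(lv), brute_glszm(lv), ignore_attr = TRUE)
  }
  for (i in 1:10) {
    lv <- array(sample(0:3, 125, replace = TRUE), c(5, 5, 5))
    expect_equal(glszm(lv), brute_glszm(lv), ignore_attr = TRUE)
  }
})

test_that("size-zone features match hand formulas", {
  one_zone <- tibble::tibble(level = 3L, size = 8L, count = 1L)
  f <- szm_features(one_zone, n_voxels = 8)
  expect_equal(f$szm.z.perc, 1 / 8)
  expect_equal(f$szm.lzhge, 3^2 * 8^2)
  isolated <- tibble::tibble(level = 1L, size = 1L, count = 8L)
  f2 <- szm_features(isolated, n_voxels = 8)
  expect_equal(f2$szm.z.perc, 1)
  expect_equal(f2$szm.lzhge, 1)
  # zone percentage bound
  pair <- make_test_pair()
  d <- discretize(pair$pet)
  s <- glszm(d$levels, pair$pet$mask)
  zp <- szm_features(s, sum(pair$pet$mask))$szm.z.perc
  expect_true(zp > 0 && zp <= 1)
})

test_that("morphological volume and SUV metrics follow their definitions", {
  m <- array(FALSE, c(6, 6, 6)); m[1:2, 1:2, 1:2] <- TRUE
  expect_equal(morph_vol(m, c(2, 2, 2)), 8 * 8)   # 64 mm^3
  expect_error(morph_vol(array(FALSE, c(3, 3, 3)), c(2, 2, 2)), "empty")

  # uniform lesion: max = min = mean = peak
  arr <- array(4, c(20, 20, 20))
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  v <- voi(arr, mask, c(2, 2, 2), "PET")
  s <- suv_metrics(v)
  expect_equal(s$SUVmax, 4); expect_equal(s$SUVmin, 4)
  expect_equal(s$SUVmean, 4); expect_equal(s$SUVpeak, 4)
  expect_equal(s$MTV, 216 * 8 / 1000)
  expect_equal(s$TLG, s$SUVmean * s$MTV)

  # a single hot voxel is averaged down by the 1 cm^3 sphere
  arr2 <- array(1, c(20, 20, 20)); arr2[10, 10, 10] <- 10
  v2 <- voi(arr2, mask, c(2, 2, 2), "PET")
  s2 <- suv_metrics(v2)
  expect_lt(s2$SUVpeak, s2$SUVmax)
  expect_gt(s2$SUVpeak, 1)
})

test_that("full extraction yields the documented feature vector", {
  pair <- make_test_pair()
  fx <- extract_features(pair$pet, pair$ct)
  expect_equal(ncol(fx), 110)
  expect_equal(sum(grepl("^PET\\.", names(fx))), 52)
  expect_equal(sum(grepl("^CT\\.", names(fx))), 52)
  expect_true(all(c("SUVmax", "SUVmin", "SUVmean", "SUVpeak", "MTV", "TLG")
                  %in% names(fx)))
  expect_equal(fx$TLG, fx$SUVmean * fx$MTV)
  # deterministic
  fx2 <- extract_features(pair$pet, pair$ct)
  expect_identical(fx, fx2)
  # axis flip leaves GLSZM features unchanged (26-connectivity symmetry)
  flip <- function(v) {
    v$intensity <- v$intensity[dim(v$intensity)[1]:1, , ]
    v$mask <- v$mask[dim(v$mask)[1]:1, , ]
    if (!is.null(v$reference)) v$reference <- v$reference[dim(v$reference)[1]:1, , ]
    v
  }
  fx3 <- extract_features(flip(pair$pet), flip(pair$ct))
  szm_cols <- grep("szm", names(fx), value = TRUE)
  expect_equal(fx3[, szm_cols], fx[, szm_cols], tolerance = 1e-12)
  # too-small lesion is rejected
  tiny <- generate_lesion_image(200, 1, 2, seed = 3, modality = "PET")
  tinyc <- generate_lesion_image(200, 5, 2, seed = 4, modality = "CT")
  expect_error(extract_features(tiny, tinyc), "64")
})

test_that("stat.sum tracks lesion volume and MTV across a cohort", {
  small <- generate_lesion_image(1000, 0.5, 2, seed = 21, modality = "PET")
  large <- generate_lesion_image(8000, 0.5, 2, seed = 21, modality = "PET")
  expect_gt(stat_sum(large), stat_sum(small))
  # rank correlation of stat.sum with MTV across sizes (volume confounding)
  set.seed(77)
  vols <- exp(runif(12, log(1500), log(9000)))
  stats_tbl <- t(vapply(seq_along(vols), function(i) {
    p <- generate_lesion_image(vols[i], 0.5, 2, seed = 300 + i,
                               modality = "PET")
    c(ss = stat_sum(p), mtv = suv_metrics(p)$MTV)
  }, numeric(2)))
  expect_gt(cor(stats_tbl[, "ss"], stats_tbl[, "mtv"], method = "spearman"),
            0.9)
})
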