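test_that("fixed-bin-count discretization matches hand binning", {
  grid <- function(vals) image_volume(array(vals, c(length(vals), 1, 1)))
  roi <- function(n) binary_mask(array(TRUE, c(n, 1, 1)))
  lev <- discretize_roi(grid(0:255), roi(256), 256)
  expect_identical(as.integer(lev), 0:255 + 1L)
  lev2 <- discretize_roi(grid(c(0, 5, 10)), roi(3), 2)
  expect_identical(as.integer(lev2), c(1L, 2L, 2L))
  lev3 <- discretize_roi(grid(rep(42, 4)), roi(4), 16)
  expect_true(all(lev3 == 1L))
  expect_error(discretize_roi(grid(1:3), roi(3), 1), class = "validation_error")
})

test_that("first-order features match hand computation and conventions", {
  f <- first_order_features(c(1, 2, 3))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["range"]), 2)
  expect_equal(unname(f["energy"]), 14)
  expect_equal(unname(f["variance"]), 2 / 3)
  expect_equal(unname(f["root_mean_square"]), sqrt(14 / 3))
  expect_equal(unname(f["median"]), 2)

  fc <- first_order_features(rep(5, 10))
  expect_equal(unname(fc[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_equal(unname(fc["uniformity"]), 1)
  expect_equal(unname(fc["entropy"]), 0)

  set.seed(3)
  v <- rnorm(50)
  expect_equal(first_order_features(v), first_order_features(sample(v)))
  expect_error(first_order_features(3), class = "degenerate_roi_error")
  expect_length(f, 14)
})

test_that("shape features: cube volume, sphere sphericity, scaling law", {
  cube <- binary_mask(array(TRUE, c(10, 10, 10)))
  sc <- shape_features(cube)
  expect_equal(unname(sc["volume_mm3"]), 1000)

  sph <- make_sphere_mask(20, 45)
  ss <- shape_features(sph)
  expect_gt(unname(ss["sphericity"]), 0.95)
  expect_lte(unname(ss["sphericity"]), 1.0)
  expect_equal(unname(ss["maximum_3d_diameter"]), 40, tolerance = 0.05)

  sph2 <- binary_mask(sph$voxels, spacing_mm = c(2, 2, 2))
  ss2 <- shape_features(sph2)
  expect_equal(unname(ss2["volume_mm3"]), 8 * unname(ss["volume_mm3"]))
  expect_equal(unname(ss2["maximum_3d_diameter"]),
               2 * unname(ss["maximum_3d_diameter"]))
  expect_equal(unname(ss2["major_axis_length"]),
               2 * unname(ss["major_axis_length"]), tolerance = 1e-8)
})

test_that("GLCM counts equal brute-force pair enumeration on small grids", {
  set.seed(31)
  for (rep in 1:8) {
    d <- sample(2:5, 3, replace = TRUE)
    nlev <- sample(2:4, 1)
    lev <- array(sample.int(nlev, prod(d), replace = TRUE), d)
    roiv <- array(runif(prod(d)) < 0.8, d)
    if (!any(roiv)) roiv[1] <- TRUE
    got <- ringomics:::.glcm_counts_cpp(as.integer(lev), as.logical(roiv),
                                        as.integer(d), nlev)
    expect_equal(unname(got), unname(brute_glcm_counts(lev, roiv, nlev)))
  }
})

test_that("GLCM features: degenerate and symmetry properties", {
  roi <- binary_mask(array(TRUE, c(3, 3, 3)))
  lev_const <- array(1L, c(3, 3, 3))
  g <- glcm_features(lev_const, roi, 4)
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["angular_second_moment"]), 1)

  set.seed(32)
  nlev <- 4L
  lev <- array(sample.int(nlev, 27, replace = TRUE), c(3, 3, 3))
  g1 <- glcm_features(lev, roi, nlev)
  g2 <- glcm_features(nlev + 1L - lev, roi, nlev)
  expect_equal(g1["contrast"], g2["contrast"])
  expect_equal(g1["difference_average"], g2["difference_average"])

  single <- binary_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)))
  expect_error(glcm_features(lev, single, nlev),
               class = "degenerate_roi_error")
})

test_that("GLRLM counts equal brute-force run enumeration; hand cases", {
  set.seed(33)
  for (rep in 1:8) {
    d <- sample(2:5, 3, replace = TRUE)
    nlev <- sample(2:4, 1)
    lev <- array(sample.int(nlev, prod(d), replace = TRUE), d)
    roiv <- array(runif(prod(d)) < 0.8, d)
    if (!any(roiv)) roiv[1] <- TRUE
    got <- ringomics:::.glrlm_counts_cpp(as.integer(lev), as.logical(roiv),
                                         as.integer(d), nlev)
    brute <- brute_glrlm_counts(lev, roiv, nlev)
    expect_equal(unname(got[, seq_len(ncol(brute))]), unname(brute))
  }

  # constant 4x4x1 plane: hand-counted runs per direction
  roi4 <- binary_mask(array(TRUE, c(4, 4, 1)))
  lev4 <- array(1L, c(4, 4, 1))
  m <- ringomics:::.glrlm_counts_cpp(as.integer(lev4), as.logical(roi4$voxels),
                                     c(4L, 4L, 1L), 1L)
  # x and y: 4 runs of length 4; two in-plane diagonals: 7 runs each;
  # all 9 out-of-plane directions: 16 runs of length 1
  expect_equal(sum(m[1, ]), 4 + 4 + 7 + 7 + 9 * 16)
  expect_equal(m[1, 4], 2 * 4 + 2)  # the four-long runs incl. main diagonals
  fr <- glrlm_features(lev4, roi4, 1)
  expect_equal(unname(fr["run_percentage"]),
               (4 + 4 + 7 + 7 + 9 * 16) / (13 * 16))

  # 8-level parity pattern: neighbours differ along every 3D direction,
  # so every run has length 1
  d <- c(4, 4, 4)
  idx <- arrayInd(seq_len(prod(d)), d)
  lev_cb <- array(1L + (idx[, 1] %% 2L) + 2L * (idx[, 2] %% 2L) +
                    4L * (idx[, 3] %% 2L), d)
  roi_cb <- binary_mask(array(TRUE, d))
  fcb <- glrlm_features(lev_cb, roi_cb, 8)
  expect_equal(unname(fcb["short_run_emphasis"]), 1)
  expect_equal(unname(fcb["long_run_emphasis"]), 1)
})

test_that("NGTDM table matches hand computation; noise lowers coarseness", {
  # 3x3x1 plane, all level 1 except a deviant centre at level 3
  lev <- array(1L, c(3, 3, 1))
  lev[2, 2, 1] <- 3L
  roi <- binary_mask(array(TRUE, c(3, 3, 1)))
  tab <- ringomics:::.ngtdm_table_cpp(as.integer(lev), as.logical(roi$voxels),
                                      c(3L, 3L, 1L), 3L)
  expect_equal(tab$n, c(8, 0, 1))
  # corners see mean (2*1+3)/3; edges mean (4*1+3)/5; centre sees mean 1
  expect_equal(tab$s, c(4 * abs(1 - 5 / 3) + 4 * abs(1 - 7 / 5), 0, 2),
               tolerance = 1e-12)
  feats <- ngtdm_features(lev, roi, 3)
  expect_true(all(is.finite(feats)))

  const <- ngtdm_features(array(1L, c(3, 3, 3)),
                          binary_mask(array(TRUE, c(3, 3, 3))), 4)
  expect_equal(unname(const["contrast"]), 0)
  expect_equal(unname(const["busyness"]), 0)

  set.seed(34)
  drops <- vapply(1:10, function(i) {
    base <- array(rep(seq(0, 1, length.out = 12), 12 * 12), c(12, 12, 12))
    roi12 <- binary_mask(array(TRUE, c(12, 12, 12)))
    smooth_lev <- discretize_roi(image_volume(base), roi12, 8)
    noisy <- base + rnorm(length(base), 0, 0.5)
    noisy_lev <- discretize_roi(image_volume(noisy), roi12, 8)
    ngtdm_features(smooth_lev, roi12, 8)["coarseness"] -
      ngtdm_features(noisy_lev, roi12, 8)["coarseness"]
  }, numeric(1))
  expect_true(all(drops > 0))
})

test_that("catalogue arithmetic: 14 + 8 + 45 x 6 = 292 per region, 584 total", {
  cat <- feature_catalogue()
  expect_equal(nrow(cat), 584)
  expect_equal(sum(cat$region == "intra"), 292)
  expect_equal(sum(cat$region == "peri"), 292)
  tab <- table(cat$family[cat$region == "intra"])
  expect_equal(unname(tab["first_order"]), 14)
  expect_equal(unname(tab["shape"]), 8)
  expect_equal(unname(tab["glcm"] + tab["glrlm"] + tab["ngtdm"]), 270)
  expect_false(any(duplicated(cat$column)))
})

test_that("extraction returns 584 finite values, constant volumes included", {
  sph <- make_sphere_mask(6, 32)
  vol <- image_volume(array(40, c(32, 32, 32)))
  rois <- build_peritumoral_ring(sph)
  row <- extract_case(vol, rois)
  expect_length(row, 584)
  expect_true(all(is.finite(row)))
  expect_equal(unname(row["intra_glcm_contrast_b32"]), 0)
  expect_equal(sum(startsWith(names(row), "peri_")), 292)
})

test_that("intensity and texture features are invariant to 90-degree grid rotation", {
  set.seed(35)
  cfg <- cohort_config(n_cases = 1, grid_shape = c(32, 32, 32),
                       tumor_radius_mm = c(5, 6))
  ph <- generate_phantom(cfg, "High", 5)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , ]
  vol_r <- image_volume(rot(ph$volume$voxels))
  msk_r <- binary_mask(rot(ph$tumor_mask$voxels))
  r1 <- build_peritumoral_ring(ph$tumor_mask)
  r2 <- build_peritumoral_ring(msk_r)
  f1 <- extract_case(ph$volume, r1, bin_counts = c(16, 32))
  f2 <- extract_case(vol_r, r2, bin_counts = c(16, 32))
  nonshape <- !grepl("_shape_", names(f1))
  expect_equal(f1[nonshape], f2[nonshape], tolerance = 1e-8)
})
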