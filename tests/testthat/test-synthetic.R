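small_cfg <- function(n_cases = 4, ...) {
  cohort_config(n_cases = n_cases, grid_shape = c(32, 32, 32),
                tumor_radius_mm = c(5, 7), ...)
}

test_that("phantom generation is a pure function of config and seed", {
  cfg <- small_cfg()
  a <- generate_phantom(cfg, "High", 11)
  b <- generate_phantom(cfg, "High", 11)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$tumor_mask$voxels, b$tumor_mask$voxels)
  c <- generate_phantom(cfg, "High", 12)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
  expect_true(any(a$tumor_mask$voxels))
  expect_true(all(a$volume$voxels >= -1024 & a$volume$voxels <= 3071))
})

test_that("zero texture SD degenerates to the class mean inside the tumor", {
  tp <- default_texture_params()
  tp$High$intra$intensity_sd_HU <- 0
  cfg <- small_cfg(texture_params = tp)
  ph <- generate_phantom(cfg, "High", 3)
  inside <- ph$volume$voxels[ph$tumor_mask$voxels]
  expect_true(all(inside == tp$High$intra$mean_HU))
})

test_that("longer correlation length yields a longer semivariogram range", {
  cfg <- small_cfg()
  ranges <- vapply(c(1, 4), function(cl) {
    tp <- default_texture_params()
    tp$High$intra$correlation_length_mm <- cl
    cfgi <- small_cfg(texture_params = tp)
    ph <- generate_phantom(cfgi, "High", 17)
    # carve the largest interior box to get a stationary sample
    field <- ph$volume$voxels[10:24, 10:24, 10:24]
    gam <- semivariogram_x(field, 1:8)
    sill <- max(gam)
    # first lag reaching 80% of the sill
    which(gam >= 0.8 * sill)[1]
  }, numeric(1))
  expect_gt(ranges[2], ranges[1])
})

test_that("NLR ratios always respect the labeling rule; Mix sub-types are balanced", {
  for (s in 1:20) {
    h <- generate_nlr_values("High", s)
    expect_true(all(h >= 1))
    l <- generate_nlr_values("Low", s + 100)
    expect_true(all(l < 1))
    m <- generate_nlr_values("Mix", s + 200)
    expect_equal(sum(m >= 1), 1)
  }
  expect_error(generate_nlr_values("VeryHigh", 1), class = "validation_error")

  intra_high <- vapply(1:10000, function(s)
    generate_nlr_values("Mix", s)[["nlr_intra"]] >= 1, logical(1))
  frac <- mean(intra_high)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("survival generator: censoring, ordering, and event coding", {
  cfg <- small_cfg()
  cfg$survival_params$censoring_rate <- 0
  out <- t(vapply(1:50, function(s)
    generate_survival("Mix", NULL, cfg, s), numeric(4)))
  expect_true(all(out[, "dfs_event"] == 1))
  expect_true(all(out[, "os_event"] == 1))
  expect_true(all(out[, "dfs_time"] <= out[, "os_time"]))

  cfg2 <- small_cfg()
  out2 <- t(vapply(1:400, function(s)
    generate_survival("Low", NULL, cfg2, s), numeric(4)))
  cens_frac <- 1 - mean(out2[, "dfs_event"])
  expect_lt(abs(cens_frac - cfg2$survival_params$censoring_rate), 0.1)
})

test_that("null survival model gives calibrated log-rank p-values", {
  cfg <- small_cfg()
  cfg$survival_params$log_hr <- c(High = 0, Mix = 0, Low = 0)
  cfg$survival_params$censoring_rate <- 0
  set.seed(5)
  ps <- vapply(1:120, function(r) {
    cls <- sample(c("High", "Mix", "Low"), 45, replace = TRUE)
    out <- t(vapply(seq_along(cls), function(i)
      generate_survival(cls[i], NULL, cfg, r * 1000 + i), numeric(4)))
    logrank_test(out[, "dfs_time"], out[, "dfs_event"], cls)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is reproducible with consistent labels", {
  cfg <- small_cfg(n_cases = 6, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(vapply(a$cases, `[[`, character(1), "latent_class"),
                   vapply(b$cases, `[[`, character(1), "latent_class"))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$cases[[3]]$volume$voxels, b$cases[[3]]$volume$voxels)
  # label consistency: status recomputed from ratios equals the latent class
  expect_identical(nlr_status(a$clinical$nlr_intra, a$clinical$nlr_peri),
                   vapply(a$cases, `[[`, character(1), "latent_class"))
})

test_that("class proportions drive class counts", {
  cfg <- cohort_config(n_cases = 240, grid_shape = c(32, 32, 32),
                       tumor_radius_mm = c(5, 7), seed = 13)
  set.seed(cfg$seed)
  cls <- sample(c("High", "Mix", "Low"), cfg$n_cases, replace = TRUE,
                prob = cfg$class_proportions[c("High", "Mix", "Low")])
  # the full generator must reproduce exactly this class sequence
  cfg_small <- cohort_config(n_cases = 12, grid_shape = c(32, 32, 32),
                             tumor_radius_mm = c(5, 7), seed = 13)
  coh <- generate_cohort(cfg_small)
  expect_identical(vapply(coh$cases, `[[`, character(1), "latent_class"),
                   cls[1:12])
  # multinomial check at n = 240: each count within 3 SDs of 80
  sdev <- sqrt(240 * (1 / 3) * (2 / 3))
  expect_true(all(abs(table(cls) - 80) <= 3 * sdev))

  cfg_pure <- cohort_config(n_cases = 5, grid_shape = c(32, 32, 32),
                            tumor_radius_mm = c(5, 7),
                            class_proportions = c(High = 1, Mix = 0, Low = 0))
  pure <- generate_cohort(cfg_pure)
  expect_true(all(pure$clinical$nlr_status == "High"))
})

test_that("cohort writes NIfTI, clinical.csv and truth.json", {
  out <- withr::local_tempdir()
  cfg <- small_cfg(n_cases = 2, seed = 21)
  coh <- generate_cohort(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "clinical.csv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  expect_true(file.exists(file.path(out, "case_001_ct.nii.gz")))
  back <- read_volume(file.path(out, "case_001_ct.nii.gz"))
  expect_equal(back$voxels, coh$cases[[1]]$volume$voxels, tolerance = 1e-5)
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  # the planted signal is the correlation length, in both regions
  expect_true("correlation_length_mm" %in%
                truth$informative_texture_directions$parameter)
})

test_that("config validation rejects malformed studies", {
  expect_error(cohort_config(class_proportions = c(High = 0.6, Mix = 0.3,
                                                   Low = 0.3)),
               class = "validation_error")
  expect_error(cohort_config(grid_shape = c(16, 48, 48)),
               class = "validation_error")
  expect_error(cohort_config(tumor_radius_mm = c(10, 30)),
               class = "geometry_error")
  expect_error(cohort_config(survival_params = list(
    shape = 1.2, scale = 36, log_hr = c(High = Inf, Mix = 0, Low = 0),
    covariate_log_hr = c(age_decade = 0), censoring_rate = 0.3,
    os_extra_mean = 6, pfs_scale = 8)), class = "validation_error")
})
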