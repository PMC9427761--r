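#' Configuration for a synthetic phantom cohort
#'
#' Assembles and validates the parameters of the synthetic study: CT-like
#' phantoms whose intratumoral and peritumoral texture differs by a latent
#' NLR class, plus linked clinical records (NLR ratios, survival, treatment
#' response). Defaults emulate a three-class cohort of 240 cases on 48^3
#' grids at 1 mm spacing, with the class signal planted in the texture
#' correlation length (4 mm for NLR-High vs 2 mm for NLR-Low, the Mix class
#' halfway in the intratumoral region only) at equal noise SD (15 HU).
#'
#' @param n_cases number of cases.
#' @param class_proportions named fractions over \code{High}, \code{Mix},
#'   \code{Low}, summing to 1.
#' @param grid_shape voxel grid triple (each >= 32).
#' @param spacing_mm positive spacing triple in mm.
#' @param tumor_radius_mm length-2 range of mean tumor radius in mm.
#' @param texture_params per-class, per-region texture parameters: each of
#'   \code{High}, \code{Mix}, \code{Low} holds \code{intra} and \code{peri}
#'   lists with \code{correlation_length_mm}, \code{intensity_sd_HU},
#'   \code{mean_HU}.
#' @param background_mean_HU,background_sd_HU smooth abdominal-like
#'   background field parameters.
#' @param air_pocket_prob probability of planting a -1000 HU air pocket
#'   outside the tumor.
#' @param survival_params list with Weibull \code{shape} and \code{scale}
#'   (months), named \code{log_hr} per class, \code{covariate_log_hr}
#'   (age per decade), \code{censoring_rate} in [0, 1), \code{os_extra_mean}
#'   (mean of the exponential OS - DFS residual, months) and
#'   \code{pfs_scale} for the immunotherapy endpoint.
#' @param response_params per-class probability vectors over CR, PR, SD, PD.
#' @param immunotherapy_fraction fraction of cases carrying PFS and RECIST
#'   response fields.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_cases = 240,
                          class_proportions = c(High = 1/3, Mix = 1/3,
                                                Low = 1/3),
                          grid_shape = c(48, 48, 48),
                          spacing_mm = c(1, 1, 1),
                          tumor_radius_mm = c(8, 12),
                          texture_params = default_texture_params(),
                          background_mean_HU = 40,
                          background_sd_HU = 8,
                          air_pocket_prob = 0.3,
                          survival_params = list(
                            shape = 1.2, scale = 36,
                            log_hr = c(High = 1.0, Mix = 0.5, Low = 0),
                            covariate_log_hr = c(age_decade = 0.1),
                            censoring_rate = 0.3,
                            os_extra_mean = 6,
                            pfs_scale = 8),
                          response_params = list(
                            High = c(CR = 0.02, PR = 0.06, SD = 0.22,
                                     PD = 0.70),
                            Mix = c(CR = 0.07, PR = 0.28, SD = 0.15,
                                    PD = 0.50),
                            Low = c(CR = 0.13, PR = 0.48, SD = 0.09,
                                    PD = 0.30)),
                          immunotherapy_fraction = 0.15,
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              class_proportions = class_proportions,
              grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              tumor_radius_mm = as.numeric(tumor_radius_mm),
              texture_params = texture_params,
              background_mean_HU = background_mean_HU,
              background_sd_HU = background_sd_HU,
              air_pocket_prob = air_pocket_prob,
              survival_params = survival_params,
              response_params = response_params,
              immunotherapy_fraction = immunotherapy_fraction,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_texture_params <- function() {
  mk <- function(corr) list(correlation_length_mm = corr,
                            intensity_sd_HU = 15, mean_HU = 60)
  list(High = list(intra = mk(4), peri = mk(4)),
       Mix = list(intra = mk(3), peri = mk(2)),
       Low = list(intra = mk(2), peri = mk(2)))
}

validate_cohort_config <- function(cfg) {
  cls <- c("High", "Mix", "Low")
  if (!all(cls %in% names(cfg$class_proportions)) ||
      abs(sum(cfg$class_proportions) - 1) > 1e-9)
    ring_stop("class_proportions must cover High/Mix/Low and sum to 1",
              "validation_error")
  if (any(cfg$class_proportions < 0))
    ring_stop("class_proportions must be non-negative", "validation_error")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 32))
    ring_stop("grid_shape must be a triple, each >= 32", "validation_error")
  if (any(cfg$spacing_mm <= 0))
    ring_stop("spacing_mm must be positive", "validation_error")
  if (length(cfg$tumor_radius_mm) != 2 || any(cfg$tumor_radius_mm <= 0) ||
      diff(cfg$tumor_radius_mm) < 0)
    ring_stop("tumor_radius_mm must be a positive increasing range",
              "validation_error")
  # tumor (with perturbation headroom) must fit with a 4 mm margin
  half_extent <- min(cfg$grid_shape * cfg$spacing_mm) / 2
  if (max(cfg$tumor_radius_mm) * 1.3 + 4 > half_extent)
    ring_stop("tumor does not fit inside the grid with a 4 mm margin",
              "geometry_error")
  for (cl in cls) {
    for (reg in c("intra", "peri")) {
      tp <- cfg$texture_params[[cl]][[reg]]
      if (tp$correlation_length_mm <= 0 || tp$intensity_sd_HU < 0)
        ring_stop("texture lengths must be > 0 and SDs >= 0",
                  "validation_error")
    }
    pr <- cfg$response_params[[cl]]
    if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0))
      ring_stop("response probabilities must be a distribution over CR/PR/SD/PD",
                "validation_error")
  }
  sv <- cfg$survival_params
  if (!all(is.finite(sv$log_hr)))
    ring_stop("log hazard ratios must be finite", "validation_error")
  if (sv$censoring_rate < 0 || sv$censoring_rate >= 1)
    ring_stop("censoring_rate must be in [0, 1)", "validation_error")
  invisible(cfg)
}

# Stationary Gaussian random field: white noise smoothed by a separable
# Gaussian kernel (sigma = correlation length), rescaled to unit variance
# before applying the requested SD and mean.
gaussian_random_field <- function(grid_shape, spacing_mm,
                                  correlation_length_mm, sd_HU, mean_HU) {
  w <- array(rnorm(prod(grid_shape)), dim = grid_shape)
  if (sd_HU == 0) return(array(mean_HU, dim = grid_shape))
  sigma_vox <- correlation_length_mm / spacing_mm
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sqrt(sum(k^2))  # unit output variance per axis
    n <- grid_shape[ax]
    cm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      cm[i, j[ok]] <- k[ok]
    }
    w <- apply_along(w, ax, cm)
  }
  mean_HU + sd_HU * w
}

#' Generate one CT-like phantom for a latent NLR class
#'
#' Builds a randomly perturbed ellipsoidal tumor mask centred in the grid,
#' fills the tumor interior and the 0-4 mm peritumoral shell with stationary
#' Gaussian random fields carrying the class's texture parameters, overlays
#' them on a smooth abdominal-like background (about 40 HU) with an optional
#' -1000 HU air pocket outside the tumor, and clamps to [-1024, 3071] HU.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param latent_class one of \code{"High"}, \code{"Mix"}, \code{"Low"}.
#' @param seed integer seed for this case.
#' @return list with \code{volume} (\code{image_volume}), \code{tumor_mask}
#'   (\code{binary_mask}) and \code{latent_class}.
#' @export
generate_phantom <- function(config, latent_class, seed) {
  validate_cohort_config(config)
  if (!latent_class %in% c("High", "Mix", "Low"))
    ring_stop("unknown latent class", "validation_error")
  set.seed(as.integer(seed))
  gs <- config$grid_shape
  sp <- config$spacing_mm

  # tumor mask: jittered ellipsoid with a smooth radial perturbation
  r0 <- runif(1, config$tumor_radius_mm[1], config$tumor_radius_mm[2])
  semi <- r0 * (1 + runif(3, -0.15, 0.15))
  centre <- (gs - 1) * sp / 2 + runif(3, -2, 2)
  ax <- lapply(1:3, function(a) ((seq_len(gs[a]) - 1) * sp[a] - centre[a]))
  q <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, `+`),
             (ax[[3]] / semi[3])^2, `+`)
  perturb <- gaussian_random_field(gs, sp, 6, 0.08, 0)
  tumor <- q <= (1 + perturb)^2
  if (!any(tumor))
    ring_stop("degenerate tumor mask", "geometry_error")

  bg <- gaussian_random_field(gs, sp, 8, config$background_sd_HU,
                              config$background_mean_HU)
  tp <- config$texture_params[[latent_class]]
  f_in <- gaussian_random_field(gs, sp, tp$intra$correlation_length_mm,
                                tp$intra$intensity_sd_HU, tp$intra$mean_HU)
  f_peri <- gaussian_random_field(gs, sp, tp$peri$correlation_length_mm,
                                  tp$peri$intensity_sd_HU, tp$peri$mean_HU)

  tmask <- binary_mask(tumor, spacing_mm = sp)
  sdist <- signed_distance(tmask)
  shell <- sdist > 0 & sdist <= 4

  vox <- bg
  vox[tumor] <- f_in[tumor]
  vox[shell] <- f_peri[shell]

  if (runif(1) < config$air_pocket_prob) {
    # small air pocket well outside the tumor and its shell
    pocket_r <- runif(1, 2, 4)
    cand <- which(sdist > 4 + pocket_r)
    if (length(cand) > 0) {
      ci <- arrayInd(sample(cand, 1), gs)
      pc <- (ci - 1) * sp
      dist2 <- outer(outer((ax[[1]] + centre[1] - pc[1])^2,
                           (ax[[2]] + centre[2] - pc[2])^2, `+`),
                     (ax[[3]] + centre[3] - pc[3])^2, `+`)
      vox[dist2 <= pocket_r^2] <- -1000
    }
  }
  vox <- pmin(pmax(vox, -1024), 3071)

  list(volume = image_volume(vox, spacing_mm = sp),
       tumor_mask = tmask,
       latent_class = latent_class)
}

#' Generate per-region NLR ratios for a latent class
#'
#' Draws neutrophil and lymphocyte counts per region from class-conditioned
#' distributions so that the neutrophil/lymphocyte ratio respects the
#' labeling rule exactly: High has both ratios >= 1, Low both < 1, and Mix
#' exactly one >= 1 (the affected region chosen with equal probability,
#' mirroring the two Mix sub-types).
#'
#' @inheritParams generate_phantom
#' @return named numeric: \code{nlr_intra}, \code{nlr_peri}.
#' @export
generate_nlr_values <- function(latent_class, seed) {
  if (!latent_class %in% c("High", "Mix", "Low"))
    ring_stop("unknown latent class", "validation_error")
  set.seed(as.integer(seed))
  draw_ratio <- function(high) {
    # lognormal ratio conditioned on its side of 1, from counts
    repeat {
      lymph <- rpois(1, 80) + 20
      ratio <- rlnorm(1, meanlog = if (high) 0.5 else -0.5, sdlog = 0.4)
      neut <- if (high) max(ceiling(ratio * lymph), lymph) else
        min(floor(ratio * lymph), lymph - 1)
      if (neut >= 0 && (neut >= lymph) == high) return(neut / lymph)
    }
  }
  sides <- switch(latent_class,
                  High = c(TRUE, TRUE),
                  Low = c(FALSE, FALSE),
                  Mix = if (runif(1) < 0.5) c(TRUE, FALSE) else
                    c(FALSE, TRUE))
  c(nlr_intra = draw_ratio(sides[1]), nlr_peri = draw_ratio(sides[2]))
}

# Uniform censoring horizon solved so a baseline subject's censoring
# probability equals the configured rate:
# P(C < T) = E_C[S0(C)] = (1/c) * integral of S0 over (0, c).
censoring_horizon <- function(shape, scale, rate) {
  if (rate <= 0) return(Inf)
  s0 <- function(t) exp(-(t / scale)^shape)
  f <- function(cmax)
    integrate(s0, 0, cmax, rel.tol = 1e-8)$value / cmax - rate
  uniroot(f, lower = 1e-6, upper = scale * 1e4, tol = 1e-8)$root
}

#' Generate survival outcomes under a Weibull proportional-hazards model
#'
#' DFS event times follow a Weibull PH model with linear predictor equal to
#' the class log-hazard-ratio plus covariate effects; OS is DFS plus an
#' independent exponential residual, so DFS <= OS always. One uniform
#' censoring time applies to both endpoints; its horizon is solved from the
#' configured baseline censoring rate.
#'
#' @inheritParams generate_phantom
#' @param covariates optional named list/vector; \code{age} contributes
#'   \code{covariate_log_hr["age_decade"] * (age - 57) / 10} to the linear
#'   predictor.
#' @return named numeric: \code{dfs_time}, \code{dfs_event}, \code{os_time},
#'   \code{os_event} (times in months, events 0/1).
#' @export
generate_survival <- function(latent_class, covariates = NULL, config, seed) {
  if (!latent_class %in% c("High", "Mix", "Low"))
    ring_stop("unknown latent class", "validation_error")
  sv <- config$survival_params
  set.seed(as.integer(seed))
  lp <- sv$log_hr[[latent_class]]
  if (!is.null(covariates$age))
    lp <- lp + sv$covariate_log_hr[["age_decade"]] * (covariates$age - 57) / 10
  t_dfs <- sv$scale * (-log(runif(1)) / exp(lp))^(1 / sv$shape)
  t_os <- t_dfs + rexp(1, rate = 1 / sv$os_extra_mean)
  cmax <- censoring_horizon(sv$shape, sv$scale, sv$censoring_rate)
  cens <- if (is.finite(cmax)) runif(1, 0, cmax) else Inf
  c(dfs_time = min(t_dfs, cens), dfs_event = as.numeric(t_dfs <= cens),
    os_time = min(t_os, cens), os_event = as.numeric(t_os <= cens))
}

#' Generate a full synthetic cohort
#'
#' Draws latent classes by the configured proportions, then per case a
#' phantom, NLR ratios consistent with the class label, survival outcomes
#' and (for the immunotherapy subset) PFS and a RECIST response category.
#' The whole cohort is a pure function of the config (which includes the
#' seed). Optionally writes NIfTI volumes/masks, \code{clinical.csv} and a
#' \code{truth.json} recording the planted structure.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param out_dir optional output directory.
#' @param balanced draw class counts exactly proportional to the
#'   configured proportions (shuffled), rather than multinomially; use for
#'   fixed cohort designs such as 80/80/80.
#' @return list with \code{cases} (each holding \code{case_id},
#'   \code{volume}, \code{tumor_mask}, \code{latent_class}),
#'   \code{clinical} (data.frame) and \code{truth} (planted parameters,
#'   including which texture parameters differ between classes).
#' @export
generate_cohort <- function(config, out_dir = NULL, balanced = FALSE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  cls <- c("High", "Mix", "Low")
  classes <- if (balanced) {
    counts <- round(config$n_cases * config$class_proportions[cls])
    while (sum(counts) < config$n_cases)
      counts[which.max(config$class_proportions[cls])] <-
        counts[which.max(config$class_proportions[cls])] + 1
    while (sum(counts) > config$n_cases)
      counts[which.max(counts)] <- counts[which.max(counts)] - 1
    sample(rep(cls, counts))
  } else {
    sample(cls, config$n_cases, replace = TRUE,
           prob = config$class_proportions[cls])
  }
  immuno <- runif(config$n_cases) < config$immunotherapy_fraction
  case_seeds <- sample.int(.Machine$integer.max - 10L, config$n_cases)

  cases <- vector("list", config$n_cases)
  clin <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    cl <- classes[i]
    ph <- generate_phantom(config, cl, case_seeds[i])
    nlr <- generate_nlr_values(cl, case_seeds[i] + 1L)
    set.seed(case_seeds[i] + 2L)
    age <- round(rnorm(1, 57, 10))
    sex <- sample(c("male", "female"), 1, prob = c(0.68, 0.32))
    t_stage <- sample(paste0("T", 1:4), 1, prob = c(0.22, 0.12, 0.14, 0.52))
    n_stage <- sample(paste0("N", 0:3), 1, prob = c(0.45, 0.18, 0.10, 0.27))
    m_stage <- sample(c("M0", "M1"), 1, prob = c(0.95, 0.05))
    surv <- generate_survival(cl, list(age = age), config, case_seeds[i] + 3L)
    set.seed(case_seeds[i] + 4L)
    if (immuno[i]) {
      sv <- config$survival_params
      t_pfs <- sv$pfs_scale *
        (-log(runif(1)) / exp(sv$log_hr[[cl]]))^(1 / sv$shape)
      cpfs <- runif(1, 0, censoring_horizon(sv$shape, sv$pfs_scale,
                                            sv$censoring_rate))
      pfs_time <- min(t_pfs, cpfs)
      pfs_event <- as.numeric(t_pfs <= cpfs)
      response <- sample(c("CR", "PR", "SD", "PD"), 1,
                         prob = config$response_params[[cl]])
    } else {
      pfs_time <- NA_real_; pfs_event <- NA_real_; response <- NA_character_
    }
    cid <- sprintf("case_%03d", i)
    cases[[i]] <- list(case_id = cid, volume = ph$volume,
                       tumor_mask = ph$tumor_mask, latent_class = cl)
    clin[[i]] <- data.frame(
      case_id = cid, nlr_intra = nlr[["nlr_intra"]],
      nlr_peri = nlr[["nlr_peri"]],
      nlr_status = nlr_status(nlr[["nlr_intra"]], nlr[["nlr_peri"]]),
      dfs_time = surv[["dfs_time"]], dfs_event = surv[["dfs_event"]],
      os_time = surv[["os_time"]], os_event = surv[["os_event"]],
      pfs_time = pfs_time, pfs_event = pfs_event, response = response,
      age = age, sex = sex, t_stage = t_stage, n_stage = n_stage,
      m_stage = m_stage)
  }
  clinical <- do.call(rbind, clin)
  stopifnot(all(clinical$nlr_status == classes))

  tex <- config$texture_params
  informative <- list()
  for (reg in c("intra", "peri"))
    for (par in c("correlation_length_mm", "intensity_sd_HU", "mean_HU")) {
      vals <- vapply(cls, function(cl) tex[[cl]][[reg]][[par]], numeric(1))
      if (length(unique(vals)) > 1)
        informative[[length(informative) + 1]] <-
          list(region = reg, parameter = par, values = as.list(vals))
    }
  truth <- list(seed = config$seed, classes = classes,
                informative_texture_directions = informative,
                survival_log_hr = as.list(config$survival_params$log_hr))

  if (!is.null(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      ring_stop(paste0("cannot create output directory ", out_dir),
                "io_error")
    for (cs in cases) {
      write_volume(cs$volume, file.path(out_dir,
                                        paste0(cs$case_id, "_ct.nii.gz")))
      write_mask(cs$tumor_mask,
                 file.path(out_dir, paste0(cs$case_id, "_mask.nii.gz")))
    }
    write.csv(clinical, file.path(out_dir, "clinical.csv"),
              row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cases = cases, clinical = clinical, truth = truth)
}

#' Simulate a tabular cohort with explicitly planted informative features
#'
#' A direct feature-space generator used to study the selector in isolation:
#' standard-normal noise columns, of which the first \code{n_informative}
#' receive a mean shift of \code{effect} SDs in the positive class. The
#' planted column indices are the ground truth for selection-recovery
#' checks.
#'
#' @param n cases (balanced classes).
#' @param p feature columns.
#' @param n_informative number of planted informative columns.
#' @param effect mean shift in SD units.
#' @param seed integer seed.
#' @return list with \code{x} (matrix), \code{y} (0/1), \code{informative}
#'   (column indices).
#' @export
simulate_feature_table <- function(n = 240, p = 100, n_informative = 5,
                                   effect = 1, seed = 1) {
  set.seed(as.integer(seed))
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + effect *
    matrix(y, n, n_informative)
  colnames(x) <- sprintf("f%03d", seq_len(p))
  list(x = x, y = y, informative = seq_len(n_informative))
}
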