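#' Fixed-bin-count discretization of ROI intensities
#'
#' Bins the ROI intensity range [min, max] into \code{n_bins} equal-width
#' levels 1..n_bins. A constant ROI maps to level 1 everywhere. Voxels
#' outside the ROI are set to level 0 and ignored by all texture code.
#'
#' @param volume an \code{image_volume}.
#' @param roi a nonempty \code{binary_mask} on the same grid.
#' @param n_bins integer >= 2.
#' @return integer 3D array of levels.
#' @export
discretize_roi <- function(volume, roi, n_bins) {
  if (!same_grid(volume, roi))
    ring_stop("roi geometry does not match volume", "alignment_error")
  if (!any(roi$voxels)) ring_stop("empty ROI", "degenerate_roi_error")
  if (n_bins < 2) ring_stop("n_bins must be >= 2", "validation_error")
  v <- volume$voxels[roi$voxels]
  lev <- array(0L, dim = dim(volume$voxels))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev[roi$voxels] <- 1L
  } else {
    lev[roi$voxels] <- pmin(
      as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins)) + 1L,
      as.integer(n_bins))
  }
  lev
}

#' First-order intensity features
#'
#' The 14 first-order statistics of an ROI intensity sample: mean, median,
#' minimum, maximum, range, variance, standard deviation, skewness, kurtosis,
#' energy, entropy (on a fixed 64-bin histogram), mean absolute deviation,
#' root mean square, and uniformity. Variance is the population moment;
#' skewness and kurtosis of a constant sample are 0 by convention.
#'
#' @param values numeric vector of >= 2 ROI intensities.
#' @return named numeric vector of length 14.
#' @export
first_order_features <- function(values) {
  if (length(values) < 2)
    ring_stop("first-order features need >= 2 voxels", "degenerate_roi_error")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  # fixed 64-bin histogram over the observed range
  rng <- range(values)
  if (rng[1] == rng[2]) {
    p <- 1
  } else {
    b <- pmin(floor((values - rng[1]) / (rng[2] - rng[1]) * 64) + 1, 64)
    p <- tabulate(b, 64) / n
    p <- p[p > 0]
  }
  c(mean = mu,
    median = median(values),
    minimum = rng[1],
    maximum = rng[2],
    range = rng[2] - rng[1],
    variance = m2,
    standard_deviation = sqrt(m2),
    skewness = skew,
    kurtosis = kurt,
    energy = sum(values^2),
    entropy = -sum(p * log2(p)),
    mean_absolute_deviation = mean(abs(values - mu)),
    root_mean_square = sqrt(mean(values^2)),
    uniformity = sum(p^2))
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
gauss_smooth3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    n <- dim(a)[ax]
    # banded convolution matrix with renormalized truncated edges
    cm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      cm[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    a <- apply_along(a, ax, cm)
  }
  a
}

# multiply an n_ax x n_ax matrix along one axis of a 3D array
apply_along <- function(a, ax, m) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  res <- m %*% matrix(ap, nrow = dp[1])
  aperm(array(res, dim = dp), order(perm))
}

#' Shape features of a binary mask
#'
#' The eight shape descriptors: volume (voxel count times voxel volume),
#' surface area of a triangulated isosurface (marching tetrahedra at the 0.5
#' level of a lightly smoothed mask field, which removes voxelization bias),
#' surface-to-volume ratio, sphericity, maximum 3D diameter (largest
#' centre-to-centre distance between surface voxels), and major/minor axis
#' length and elongation from the principal components of the voxel centre
#' coordinates.
#'
#' @param mask nonempty \code{binary_mask}.
#' @return named numeric vector of length 8.
#' @export
shape_features <- function(mask) {
  if (!any(mask$voxels)) ring_stop("empty mask", "degenerate_roi_error")
  d <- dim(mask$voxels)
  sp <- mask$spacing_mm
  nv <- sum(mask$voxels)
  vol <- nv * prod(sp)

  # isosurface area: pad so boundary surfaces close, smooth 0.8 voxels
  pad <- 4L
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$voxels)
  f <- gauss_smooth3(f, 0.8)
  area <- .surface_area_mt_cpp(as.numeric(f), as.integer(dim(f)), sp, 0.5)

  idx <- which(mask$voxels, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)
  # surface voxels: any 6-neighbour outside the mask (or outside the grid)
  surf <- surface_voxels(mask$voxels)
  spts <- sweep(which(surf, arr.ind = TRUE) - 1, 2, sp, `*`)
  # max pairwise distance only needs per-(y,z)-column x-extremes
  if (nrow(spts) > 2) {
    key <- paste(spts[, 2], spts[, 3])
    keep <- unlist(lapply(split(seq_len(nrow(spts)), key), function(ii) {
      ii[c(which.min(spts[ii, 1]), which.max(spts[ii, 1]))]
    }), use.names = FALSE)
    spts <- spts[unique(keep), , drop = FALSE]
  }
  maxdiam <- if (nrow(spts) >= 2) .max_pairwise_dist_cpp(spts) else 0

  if (nv >= 2) {
    ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])

  c(volume_mm3 = vol,
    surface_area_mm2 = area,
    surface_to_volume_ratio = if (vol > 0) area / vol else 0,
    sphericity = if (area > 0) pi^(1 / 3) * (6 * vol)^(2 / 3) / area else 0,
    maximum_3d_diameter = maxdiam,
    major_axis_length = major,
    minor_axis_length = minor,
    elongation = if (major > 0) sqrt(ev[2] / ev[1]) else 0)
}

surface_voxels <- function(m) {
  d <- dim(m)
  shift <- function(dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    out[okx, oky, okz] <- m[xs[okx], ys[oky], zs[okz]]
    out
  }
  inside <- shift(1, 0, 0) & shift(-1, 0, 0) & shift(0, 1, 0) &
    shift(0, -1, 0) & shift(0, 0, 1) & shift(0, 0, -1)
  m & !inside
}

glcm_feature_names <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy",
  "angular_second_moment", "contrast",
  "inverse_difference", "inverse_difference_normalized",
  "inverse_difference_moment", "inverse_difference_moment_normalized",
  "inverse_variance", "correlation", "autocorrelation",
  "cluster_tendency", "cluster_shade", "cluster_prominence",
  "information_correlation_1", "information_correlation_2")

#' Gray-level co-occurrence features
#'
#' Co-occurrence counts are accumulated symmetrically over all 13 unique 3D
#' unit offsets into a single merged matrix, normalized, and summarized by
#' 24 co-occurrence statistics. Dissimilarity is not listed separately: for
#' a merged symmetric matrix it equals the difference average. Correlation
#' and the information-correlation features are 0 when the relevant
#' marginal variance or entropy vanishes.
#'
#' @param levels integer level array from \code{\link{discretize_roi}}.
#' @param roi nonempty \code{binary_mask}.
#' @param n_levels number of levels used in discretization.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(levels, roi, n_levels) {
  counts <- .glcm_counts_cpp(as.integer(levels), as.logical(roi$voxels),
                             as.integer(dim(levels)), as.integer(n_levels))
  if (sum(counts) == 0)
    ring_stop("ROI has no co-occurring voxel pairs", "degenerate_roi_error")
  p <- counts / sum(counts)
  ng <- n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)

  dvals <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(p[dvals == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pd)
  dvar <- sum(((0:(ng - 1)) - da)^2 * pd)
  pdnz <- pd[pd > 0]

  svals <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(p[svals == k]), numeric(1))
  sa <- sum((2:(2 * ng)) * ps)
  svar <- sum(((2:(2 * ng)) - sa)^2 * ps)
  psnz <- ps[ps > 0]

  pnz <- p[p > 0]
  hxy <- -sum(pnz * log2(pnz))
  pxi <- px[row(p)[p > 0]]
  pyj <- px[col(p)[p > 0]]
  hxy1 <- -sum(pnz * log2(pxi * pyj))
  pxnz <- px[px > 0]
  hx <- -sum(pxnz * log2(pxnz))
  op <- outer(pxnz, pxnz)
  hxy2 <- -sum(op * log2(op))
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- if (hxy2 >= hxy && hxy > 0) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0

  out <- c(
    max(p), mu, sig2, hxy,
    da, dvar, -sum(pdnz * log2(pdnz)),
    sa, svar, -sum(psnz * log2(psnz)),
    sum(p^2), sum((i - j)^2 * p),
    sum(p / (1 + dvals)), sum(p / (1 + dvals / ng)),
    sum(p / (1 + (i - j)^2)), sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p[dvals > 0] / dvals[dvals > 0]^2),
    corr, sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p), sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    ic1, ic2)
  names(out) <- glcm_feature_names
  out
}

glrlm_feature_names <- c(
  "short_run_emphasis", "long_run_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
  "run_length_nonuniformity", "run_length_nonuniformity_normalized",
  "run_percentage",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis",
  "gray_level_variance", "run_length_variance", "run_entropy")

#' Gray-level run-length features
#'
#' Run-length matrices over the 13 unique 3D directions are merged by
#' summation and summarized by the 16 run-length statistics. Runs are
#' maximal same-level streaks of in-ROI voxels; out-of-ROI voxels break
#' runs. Run percentage is total runs over 13 times the ROI voxel count
#' (the maximum possible run count over the merged directions), so it lies
#' in (0, 1].
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(levels, roi, n_levels) {
  m <- .glrlm_counts_cpp(as.integer(levels), as.logical(roi$voxels),
                         as.integer(dim(levels)), as.integer(n_levels))
  ns <- sum(m)
  if (ns == 0)
    ring_stop("ROI has no runs", "degenerate_roi_error")
  nvox <- sum(roi$voxels)
  g <- seq_len(nrow(m))
  r <- seq_len(ncol(m))
  rg <- rowSums(m)   # per gray level
  rr <- colSums(m)   # per run length
  p <- m / ns
  mug <- sum(g * rg) / ns
  mur <- sum(r * rr) / ns
  pnz <- p[p > 0]
  out <- c(
    sum(rr / r^2) / ns,
    sum(rr * r^2) / ns,
    sum(rg^2) / ns,
    sum(rg^2) / ns^2,
    sum(rr^2) / ns,
    sum(rr^2) / ns^2,
    ns / (13 * nvox),
    sum(rg / g^2) / ns,
    sum(rg * g^2) / ns,
    sum(sweep(sweep(m, 1, g^2, `/`), 2, r^2, `/`)) / ns,
    sum(sweep(sweep(m, 1, g^2, `*`), 2, r^2, `/`)) / ns,
    sum(sweep(sweep(m, 1, g^2, `/`), 2, r^2, `*`)) / ns,
    sum(sweep(sweep(m, 1, g^2, `*`), 2, r^2, `*`)) / ns,
    sum((g - mug)^2 * rg) / ns,
    sum((r - mur)^2 * rr) / ns,
    -sum(pnz * log2(pnz)))
  names(out) <- glrlm_feature_names
  out
}

ngtdm_feature_names <- c("coarseness", "contrast", "busyness", "complexity",
                         "strength")

#' Neighbourhood gray-tone difference features
#'
#' For each ROI voxel with at least one in-ROI 26-neighbour, the absolute
#' difference between its level and the mean level of those neighbours is
#' accumulated per level, giving coarseness, contrast, busyness, complexity
#' and strength. Degenerate conventions: a constant ROI has contrast,
#' busyness, complexity and strength 0 and coarseness capped at 1e6.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(levels, roi, n_levels) {
  tab <- .ngtdm_table_cpp(as.integer(levels), as.logical(roi$voxels),
                          as.integer(dim(levels)), as.integer(n_levels))
  ni <- tab$n
  si <- tab$s
  nvc <- sum(ni)
  if (nvc == 0)
    ring_stop("no ROI voxel has an in-ROI neighbour", "degenerate_roi_error")
  pi_ <- ni / nvc
  act <- which(pi_ > 0)
  ngp <- length(act)
  g <- seq_along(pi_)

  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6

  contrast <- if (ngp > 1) {
    pp <- outer(pi_[act], pi_[act])
    dd <- outer(g[act], g[act], `-`)^2
    (sum(pp * dd) / (ngp * (ngp - 1))) * (sum(si) / nvc)
  } else 0

  bus_den <- if (ngp > 1) {
    ip <- g[act] * pi_[act]
    sum(abs(outer(ip, ip, `-`)))
  } else 0
  busyness <- if (bus_den > 0) sum(pi_ * si) / bus_den else 0

  complexity <- if (ngp > 1) {
    aij <- outer(g[act], g[act], function(a, b) abs(a - b))
    num <- outer(pi_[act] * si[act], pi_[act] * si[act], `+`)
    den <- outer(pi_[act], pi_[act], `+`)
    sum(aij * num / den) / nvc
  } else 0

  strength <- if (sum(si) > 0 && ngp > 1) {
    pp <- outer(pi_[act], pi_[act], `+`)
    dd <- outer(g[act], g[act], `-`)^2
    sum(pp * dd) / sum(si)
  } else 0

  out <- c(coarseness, contrast, busyness, complexity, strength)
  names(out) <- ngtdm_feature_names
  out
}

#' The radiomics feature catalogue
#'
#' Enumerates the full feature pool: per region (intratumoral, peritumoral)
#' 14 first-order + 8 shape + 45 texture features (24 GLCM, 16 GLRLM,
#' 5 NGTDM) at each of the discretization bin counts. With the default six
#' bin counts this is 292 features per region, 584 in total. Column names
#' look like \code{peri_glcm_contrast_b32}.
#'
#' @param bin_counts integer vector of fixed bin counts for texture
#'   discretization.
#' @return data.frame with columns \code{column}, \code{region},
#'   \code{family}, \code{feature}, \code{bin_count}.
#' @export
feature_catalogue <- function(bin_counts = c(8, 16, 32, 64, 128, 256)) {
  fo <- names(first_order_features(c(0, 1)))
  sh <- c("volume_mm3", "surface_area_mm2", "surface_to_volume_ratio",
          "sphericity", "maximum_3d_diameter", "major_axis_length",
          "minor_axis_length", "elongation")
  rows <- list()
  for (region in c("intra", "peri")) {
    rows[[length(rows) + 1]] <- data.frame(
      region = region, family = "first_order", feature = fo,
      bin_count = NA_integer_)
    rows[[length(rows) + 1]] <- data.frame(
      region = region, family = "shape", feature = sh,
      bin_count = NA_integer_)
    for (b in bin_counts) {
      rows[[length(rows) + 1]] <- data.frame(
        region = region,
        family = rep(c("glcm", "glrlm", "ngtdm"),
                     c(length(glcm_feature_names),
                       length(glrlm_feature_names),
                       length(ngtdm_feature_names))),
        feature = c(glcm_feature_names, glrlm_feature_names,
                    ngtdm_feature_names),
        bin_count = as.integer(b))
    }
  }
  cat <- do.call(rbind, rows)
  cat$column <- paste0(cat$region, "_", cat$family, "_", cat$feature,
                       ifelse(is.na(cat$bin_count), "",
                              paste0("_b", cat$bin_count)))
  cat[, c("column", "region", "family", "feature", "bin_count")]
}

extract_region <- function(volume, roi, bin_counts, region_name) {
  vals <- volume$voxels[roi$voxels]
  if (length(vals) < 2)
    ring_stop(paste0("degenerate ", region_name, " ROI (",
                     length(vals), " voxels)"), "degenerate_roi_error")
  out <- c(first_order_features(vals), shape_features(roi))
  for (b in bin_counts) {
    lev <- discretize_roi(volume, roi, b)
    out <- c(out, glcm_features(lev, roi, b), glrlm_features(lev, roi, b),
             ngtdm_features(lev, roi, b))
  }
  out
}

#' Extract the full feature row for one case
#'
#' Computes the complete feature pool on the intratumoral ROI (the full
#' tumor mask) and the peritumoral ring ROI, in catalogue column order.
#'
#' @param volume an \code{image_volume}.
#' @param rois a \code{\link{roi_set}}.
#' @param bin_counts texture discretization bin counts (default six values,
#'   giving 584 features).
#' @return named numeric vector, one value per catalogue column.
#' @export
extract_case <- function(volume, rois, bin_counts = c(8, 16, 32, 64, 128, 256)) {
  cat <- feature_catalogue(bin_counts)
  intra <- extract_region(volume, rois$tumor_mask, bin_counts, "intratumoral")
  peri <- extract_region(volume, rois$ring_mask, bin_counts, "peritumoral")
  out <- c(intra, peri)
  names(out) <- cat$column
  if (any(!is.finite(out)))
    ring_stop(paste0("non-finite features: ",
                     paste(head(cat$column[!is.finite(out)], 5),
                           collapse = ", ")), "validation_error")
  out
}

#' Extract a feature table for a cohort of cases
#'
#' Builds the peritumoral ring (with HU-threshold exclusions) and extracts
#' the full feature row for every case.
#'
#' @param cases list of cases, each a list with elements \code{volume} and
#'   \code{tumor_mask} (as produced by \code{\link{generate_cohort}}).
#' @param outer_mm,inner_mm ring band extents in mm.
#' @param air_hu,vessel_hu exclusion thresholds, see
#'   \code{\link{exclusion_from_hu}}.
#' @inheritParams extract_case
#' @param progress print one dot per case.
#' @return data.frame with \code{case_id} and one column per feature.
#' @export
extract_cohort <- function(cases, outer_mm = 2, inner_mm = 1,
                           air_hu = -500, vessel_hu = 300,
                           bin_counts = c(8, 16, 32, 64, 128, 256),
                           progress = FALSE) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    excl <- exclusion_from_hu(cs$volume, air_hu, vessel_hu)
    rois <- build_peritumoral_ring(cs$tumor_mask, outer_mm, inner_mm, excl)
    if (progress) cat(".")
    extract_case(cs$volume, rois, bin_counts)
  })
  if (progress) cat("\n")
  out <- as.data.frame(do.call(rbind, rows))
  ids <- vapply(cases, function(cs) cs$case_id %||% NA_character_,
                character(1))
  if (all(is.na(ids))) ids <- sprintf("case_%03d", seq_along(cases))
  cbind(data.frame(case_id = ids), out)
}
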