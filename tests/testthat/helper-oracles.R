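# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive: full pairwise enumeration, no shared code with the
# implementation paths it checks.

make_sphere_mask <- function(radius_mm, n, spacing = c(1, 1, 1),
                             centre = NULL) {
  sp <- rep(spacing, length.out = 3)
  if (is.null(centre)) centre <- (n - 1) * sp / 2
  ax <- lapply(1:3, function(a) (seq_len(n) - 1) * sp[a] - centre[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  binary_mask(r2 <= radius_mm^2, spacing_mm = sp)
}

radial_mm <- function(mask) {
  sp <- mask$spacing_mm
  n <- dim(mask$voxels)
  centre <- (n - 1) * sp / 2
  idx <- which(mask$voxels, arr.ind = TRUE)
  sqrt(colSums((t(sweep(idx - 1, 2, sp, `*`)) - centre)^2))
}

# signed distance by full pairwise enumeration against the opposite set
brute_signed_distance <- function(mask) {
  d <- dim(mask$voxels)
  sp <- mask$spacing_mm
  fg <- sweep(which(mask$voxels, arr.ind = TRUE) - 1, 2, sp, `*`)
  bg <- sweep(which(!mask$voxels, arr.ind = TRUE) - 1, 2, sp, `*`)
  out <- array(0, d)
  for (i in seq_len(prod(d))) {
    p <- as.numeric((arrayInd(i, d) - 1) * sp)
    out[i] <- if (mask$voxels[i])
      -sqrt(min(colSums((t(bg) - p)^2)))
    else
      sqrt(min(colSums((t(fg) - p)^2)))
  }
  out
}

offsets13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

brute_glcm_counts <- function(levels, roi, nlev) {
  d <- dim(levels)
  m <- matrix(0, nlev, nlev)
  for (o in seq_len(nrow(offsets13))) {
    dd <- offsets13[o, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!roi[x, y, z]) next
      x2 <- x + dd[1]; y2 <- y + dd[2]; z2 <- z + dd[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      if (!roi[x2, y2, z2]) next
      a <- levels[x, y, z]; b <- levels[x2, y2, z2]
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  m
}

brute_glrlm_counts <- function(levels, roi, nlev) {
  d <- dim(levels)
  maxrun <- max(d)
  m <- matrix(0, nlev, maxrun)
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (o in seq_len(nrow(offsets13))) {
    dd <- offsets13[o, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      p <- c(x, y, z)
      if (!roi[x, y, z]) next
      prev <- p - dd
      if (inb(prev) && roi[prev[1], prev[2], prev[3]] &&
          levels[prev[1], prev[2], prev[3]] == levels[x, y, z]) next
      len <- 1
      cur <- p + dd
      while (inb(cur) && roi[cur[1], cur[2], cur[3]] &&
             levels[cur[1], cur[2], cur[3]] == levels[x, y, z]) {
        len <- len + 1
        cur <- cur + dd
      }
      m[levels[x, y, z], len] <- m[levels[x, y, z], len] + 1
    }
  }
  m
}

brute_ngtdm_table <- function(levels, roi, nlev) {
  d <- dim(levels)
  ni <- numeric(nlev); si <- numeric(nlev)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!roi[x, y, z]) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      if (roi[x2, y2, z2]) nb <- c(nb, levels[x2, y2, z2])
    }
    if (length(nb) == 0) next
    l <- levels[x, y, z]
    ni[l] <- ni[l] + 1
    si[l] <- si[l] + abs(l - mean(nb))
  }
  list(n = ni, s = si)
}

# AUC as the fraction of concordant (positive, negative) score pairs
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Harrell's C by full pair enumeration (higher lp = higher risk)
brute_c_index <- function(lp, times, events) {
  n <- length(lp)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # the earlier time must be an observed event for the pair to be usable
    if (times[i] == times[j] && events[i] == events[j]) next
    first <- if (times[i] < times[j]) i else j
    other <- if (first == i) j else i
    if (times[i] == times[j]) { first <- which(c(events[i], events[j]) == 1)
      first <- c(i, j)[first[1]]; other <- setdiff(c(i, j), first) }
    if (events[first] != 1) next
    usable <- usable + 1
    conc <- conc + if (lp[first] > lp[other]) 1 else
      if (lp[first] == lp[other]) 0.5 else 0
  }
  conc / usable
}

# Cox partial likelihood (Efron would matter only with tied event times;
# fixtures use distinct times so Breslow = Efron = exact)
brute_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# empirical semivariogram along the x axis at integer-voxel lags
semivariogram_x <- function(a, lags) {
  vapply(lags, function(h) {
    d <- dim(a)
    v1 <- a[seq_len(d[1] - h), , ]
    v2 <- a[(h + 1):d[1], , ]
    mean((v1 - v2)^2) / 2
  }, numeric(1))
}
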