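#' Construct an image volume
#'
#' A minimal container for a 3D scalar grid in Hounsfield units with voxel
#' spacing and world origin in mm. Axes follow the array's (x, y, z) storage
#' order; voxel centre \code{(i, j, k)} (0-based) sits at
#' \code{origin + c(i, j, k) * spacing} in world mm.
#'
#' @param voxels 3D numeric array of intensities (HU). All values must be
#'   finite.
#' @param spacing_mm positive length-3 numeric, voxel spacing in mm.
#' @param origin_mm length-3 numeric, world position of voxel (0,0,0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    ring_stop("voxels must be a 3D array", "validation_error")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    ring_stop("spacing_mm must be three positive finite values",
              "validation_error")
  if (any(!is.finite(voxels)))
    ring_stop("all voxel values must be finite", "validation_error")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' Construct a binary mask on the grid of an image volume
#'
#' @param voxels 3D logical array (or 0/1 numeric, which is coerced).
#' @inheritParams image_volume
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(voxels, spacing_mm = c(1, 1, 1),
                        origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    ring_stop("voxels must be a 3D array", "validation_error")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      ring_stop("mask voxels must be binary (0/1 or logical)",
                "validation_error")
    voxels <- array(voxels == 1, dim = dim(voxels))
  }
  if (!is.logical(voxels))
    ring_stop("mask voxels must be binary (0/1 or logical)",
              "validation_error")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    ring_stop("spacing_mm must be three positive finite values",
              "validation_error")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm, HU range [", signif(min(x$voxels), 5), ", ",
      signif(max(x$voxels), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm, ", sum(x$voxels), " foreground voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

nifti_affine <- function(spacing, origin) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  aff
}

#' Read and write volumes and masks as NIfTI
#'
#' Geometry (spacing, origin) travels through the NIfTI sform. Masks are
#' validated against a reference volume: the grids must agree and the stored
#' values must be binary.
#'
#' @param path file path, typically ending in \code{.nii.gz}.
#' @param reference an \code{image_volume} whose grid the mask must match.
#' @return \code{read_volume} an \code{image_volume}; \code{read_mask} a
#'   \code{binary_mask}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    ring_stop(paste0("no such file: ", path), "io_error")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  geo <- nifti_geometry(img)
  image_volume(arr, spacing_mm = geo$spacing, origin_mm = geo$origin)
}

# spacing from the stored affine (column norms), origin from its offset
nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  list(spacing = sqrt(colSums(xf[1:3, 1:3]^2)), origin = xf[1:3, 4])
}

#' @rdname read_volume
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path))
    ring_stop(paste0("no such file: ", path), "io_error")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (!all(arr %in% c(0, 1)))
    ring_stop("mask file contains non-binary values", "validation_error")
  geo <- nifti_geometry(img)
  m <- binary_mask(array(arr == 1, dim = dim(arr)), spacing_mm = geo$spacing,
                   origin_mm = geo$origin)
  if (!is.null(reference) && !same_grid(m, reference))
    ring_stop("mask geometry does not match reference volume",
              "alignment_error")
  m
}

#' @rdname read_volume
#' @param x an \code{image_volume} or \code{binary_mask}.
#' @export
write_volume <- function(x, path) {
  arr <- if (is.logical(x$voxels)) array(as.integer(x$voxels),
                                         dim = dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  img <- RNifti::`sform<-`(img, structure(nifti_affine(x$spacing_mm,
                                                       x$origin_mm),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(x, path) write_volume(x, path)

#' Resample a volume and mask to isotropic spacing
#'
#' Intensities are interpolated trilinearly; the mask by nearest neighbour,
#' per common IBSI-style image processing. The target grid shares the world
#' origin and covers the span of the source voxel centres.
#'
#' @param volume an \code{image_volume}.
#' @param mask a \code{binary_mask} on the same grid.
#' @param target_mm positive scalar, output spacing in mm along every axis.
#' @return list with elements \code{volume} and \code{mask}.
#' @export
resample_isotropic <- function(volume, mask, target_mm) {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    ring_stop("target_mm must be a positive scalar", "validation_error")
  if (!same_grid(volume, mask))
    ring_stop("mask geometry does not match volume", "alignment_error")
  d <- dim(volume$voxels)
  sp <- volume$spacing_mm
  if (all(abs(sp - target_mm) < 1e-9))
    return(list(volume = volume, mask = mask))
  # target centre positions expressed as continuous source indices
  nn <- pmax(2L, floor((d - 1) * sp / target_mm) + 1L)
  u <- lapply(1:3, function(a) (seq_len(nn[a]) - 1) * target_mm / sp[a])
  # trilinear gather over the 8 cell corners
  lo <- lapply(1:3, function(a) pmin(pmax(floor(u[[a]]), 0), d[a] - 2L))
  w <- lapply(1:3, function(a) u[[a]] - lo[[a]])
  ix <- function(a, corner) lo[[a]] + corner + 1L  # 1-based
  wt <- function(a, corner) if (corner == 0) 1 - w[[a]] else w[[a]]
  out <- array(0, dim = nn)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    sub <- volume$voxels[ix(1, cx), ix(2, cy), ix(3, cz), drop = FALSE]
    wgt <- outer(outer(wt(1, cx), wt(2, cy)), wt(3, cz))
    out <- out + sub * array(wgt, dim = nn)
  }
  ni <- lapply(1:3, function(a) pmin(pmax(round(u[[a]]), 0), d[a] - 1L) + 1L)
  mout <- mask$voxels[ni[[1]], ni[[2]], ni[[3]], drop = FALSE]
  if (!any(mout))
    ring_stop("mask is empty after resampling", "degenerate_roi_error")
  list(volume = image_volume(out, spacing_mm = rep(target_mm, 3),
                             origin_mm = volume$origin_mm),
       mask = binary_mask(mout, spacing_mm = rep(target_mm, 3),
                          origin_mm = volume$origin_mm))
}
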