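#' Signed Euclidean distance to a mask boundary
#'
#' For every voxel centre, the distance in mm to the nearest voxel centre of
#' the opposite set: negative inside the mask, positive outside. Computed
#' with a separable anisotropic Euclidean distance transform, so spacing is
#' honoured per axis.
#'
#' @param mask a \code{binary_mask} with at least one foreground and, for a
#'   meaningful sign, at least one background voxel.
#' @return numeric 3D array of signed distances in mm.
#' @export
signed_distance <- function(mask) {
  if (!inherits(mask, "binary_mask"))
    ring_stop("mask must be a binary_mask", "validation_error")
  d <- dim(mask$voxels)
  if (!any(mask$voxels))
    ring_stop("mask is empty", "degenerate_roi_error")
  d_out <- sqrt(.edt_sq_cpp(as.logical(mask$voxels), as.integer(d),
                            mask$spacing_mm))
  d_in <- if (all(mask$voxels)) rep(0, prod(d)) else
    sqrt(.edt_sq_cpp(!as.logical(mask$voxels), as.integer(d),
                     mask$spacing_mm))
  array(d_out - d_in, dim = d)
}

#' Region-of-interest set: tumor, peritumoral ring, exclusions
#'
#' @param tumor_mask,ring_mask,exclusion_mask \code{binary_mask} objects on
#'   one shared grid. The ring never intersects the exclusion mask.
#' @return An object of class \code{roi_set}.
#' @export
roi_set <- function(tumor_mask, ring_mask, exclusion_mask) {
  for (m in list(tumor_mask, ring_mask, exclusion_mask))
    if (!inherits(m, "binary_mask"))
      ring_stop("roi_set components must be binary_mask objects",
                "validation_error")
  if (!same_grid(tumor_mask, ring_mask) ||
      !same_grid(tumor_mask, exclusion_mask))
    ring_stop("roi_set masks must share one grid", "alignment_error")
  if (any(ring_mask$voxels & exclusion_mask$voxels))
    ring_stop("ring mask intersects exclusion mask", "validation_error")
  structure(list(tumor_mask = tumor_mask, ring_mask = ring_mask,
                 exclusion_mask = exclusion_mask), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> tumor ", sum(x$tumor_mask$voxels), " vox, ring ",
      sum(x$ring_mask$voxels), " vox, excluded ",
      sum(x$exclusion_mask$voxels), " vox\n", sep = "")
  invisible(x)
}

#' Build the peritumoral ring around a tumor mask
#'
#' The ring is the signed-distance band extending \code{inner_mm} inside and
#' \code{outer_mm} outside the tumor boundary (defaults give the 3 mm shell
#' spanning 1 mm inside to 2 mm outside), minus any excluded voxels. The
#' boundary sits at the voxel-face interface: voxel-centre distances from
#' \code{\link{signed_distance}} are shifted half the smallest voxel pitch
#' toward the boundary, so a voxel immediately inside the tumor lies at
#' about \eqn{-h/2}, not \eqn{-h}. The ring keeps voxels with shifted
#' signed distance in \code{(-inner_mm, +outer_mm]}. The intratumoral ROI
#' remains the full tumor mask; the ring's inner band intentionally
#' overlaps it.
#'
#' @param tumor nonempty \code{binary_mask}.
#' @param outer_mm,inner_mm non-negative band extents in mm, not both zero.
#' @param exclusion optional \code{binary_mask} of voxels to drop from the
#'   ring (air, vessels, adjacent organs); \code{NULL} means none.
#' @return A \code{\link{roi_set}}.
#' @export
build_peritumoral_ring <- function(tumor, outer_mm = 2, inner_mm = 1,
                                   exclusion = NULL) {
  if (!inherits(tumor, "binary_mask") || !any(tumor$voxels))
    ring_stop("tumor must be a nonempty binary_mask", "validation_error")
  if (outer_mm < 0 || inner_mm < 0 || (outer_mm == 0 && inner_mm == 0))
    ring_stop("outer_mm and inner_mm must be >= 0 and not both 0",
              "validation_error")
  if (is.null(exclusion))
    exclusion <- binary_mask(array(FALSE, dim(tumor$voxels)),
                             spacing_mm = tumor$spacing_mm,
                             origin_mm = tumor$origin_mm)
  if (!same_grid(tumor, exclusion))
    ring_stop("exclusion mask geometry does not match tumor mask",
              "alignment_error")
  sd_mm <- signed_distance(tumor)
  sd_face <- sd_mm - 0.5 * min(tumor$spacing_mm) * sign(sd_mm)
  band <- sd_face > -inner_mm & sd_face <= outer_mm
  ringv <- band & !exclusion$voxels
  if (!any(ringv))
    ring_stop("peritumoral ring is empty after exclusion",
              "degenerate_roi_error")
  roi_set(tumor_mask = tumor,
          ring_mask = binary_mask(ringv, spacing_mm = tumor$spacing_mm,
                                  origin_mm = tumor$origin_mm),
          exclusion_mask = exclusion)
}

#' Exclusion mask from Hounsfield-unit thresholds
#'
#' Marks voxels darker than \code{air_hu} (air cavities) or brighter than
#' \code{vessel_hu} (contrast-filled vessels, bone) for exclusion from the
#' peritumoral ring. A coarse stand-in for the manual exclusion of air,
#' adjacent organs and large vessels; thresholds are caller-tunable.
#'
#' @param volume an \code{image_volume}.
#' @param air_hu,vessel_hu finite thresholds with \code{air_hu < vessel_hu}.
#' @return A \code{binary_mask} of excluded voxels.
#' @export
exclusion_from_hu <- function(volume, air_hu = -500, vessel_hu = 300) {
  if (!is.finite(air_hu) || !is.finite(vessel_hu) || air_hu >= vessel_hu)
    ring_stop("need finite air_hu < vessel_hu", "validation_error")
  binary_mask(volume$voxels < air_hu | volume$voxels > vessel_hu,
              spacing_mm = volume$spacing_mm, origin_mm = volume$origin_mm)
}
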