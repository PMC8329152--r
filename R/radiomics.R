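# Volumetric radiomic shape features from a binary mask with voxel spacing:
# maximum axial diameter (mm), surface area (mm^2), volume (mm^3).

check_mask_spacing <- function(mask, spacing) {
  if (length(dim(mask)) != 3L) stopf("mask must be a 3-D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be three positive reals")
}

#' Nodule volume in cubic millimetres
#'
#' Occupied-voxel count times the physical voxel volume.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing Voxel spacing in mm, length 3.
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
nodule_volume <- function(mask, spacing = c(1, 1, 1)) {
  check_mask_spacing(mask, spacing)
  sum(mask != 0) * prod(spacing)
}

#' Nodule surface area in square millimetres
#'
#' Triangulates the 0.5-isosurface of the (lightly smoothed) mask by
#' marching tetrahedra and sums the triangle areas in physical coordinates.
#' One pass of a separable (1,2,1)/4 smoothing kernel anti-aliases the voxel
#' staircase; on digitized spheres of radius >= 8 voxels this lands within a
#' few percent of the analytic area, where raw voxel-face counting is ~50%
#' high and an unsmoothed triangulation ~30% high.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing Voxel spacing in mm, length 3.
#' @param smooth_passes Number of smoothing passes before meshing (default 1).
#'   Masks so small that smoothing extinguishes them fall back to the raw
#'   (unsmoothed) mesh, keeping the area positive.
#' @return Surface area in mm^2 (0 with a warning for an empty mask).
#' @export
nodule_surface_area <- function(mask, spacing = c(1, 1, 1), smooth_passes = 1L) {
  check_mask_spacing(mask, spacing)
  if (!any(mask != 0)) {
    warnf("empty mask: surface area is 0")
    return(0)
  }
  a <- mt_surface_area(as.numeric(mask != 0), dim(mask), as.numeric(spacing),
                       as.integer(smooth_passes), 0.5)
  if (a == 0) {
    # a mask of one or two voxels can be extinguished by the smoothing;
    # fall back to the raw (unsmoothed) mesh so the area stays positive
    a <- mt_surface_area(as.numeric(mask != 0), dim(mask), as.numeric(spacing),
                         0L, 0.5)
  }
  a
}

#' Maximum axial diameter in millimetres
#'
#' Maximum over axial (fixed-z) slices of the largest pairwise Euclidean
#' distance between occupied-voxel centers within the slice, in mm. Distances
#' are measured between voxel centers, matching the contour-point convention
#' of LIDC-style annotations.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing Voxel spacing in mm, length 3.
#' @return Diameter in mm (0 with a warning for an empty mask; 0 for a
#'   single-voxel mask).
#' @export
nodule_max_axial_diameter <- function(mask, spacing = c(1, 1, 1)) {
  check_mask_spacing(mask, spacing)
  mask <- mask != 0
  if (!any(mask)) {
    warnf("empty mask: diameter is 0")
    return(0)
  }
  best <- 0
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    ij <- which(sl, arr.ind = TRUE)
    if (nrow(ij) < 2L) next
    pts <- cbind(ij[, 1] * spacing[1], ij[, 2] * spacing[2])
    if (nrow(pts) > 8L) {
      h <- grDevices::chull(pts)  # hull vertices suffice for the diameter
      if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
    }
    d <- max(stats::dist(pts))
    if (d > best) best <- d
  }
  best
}

#' Radiomic feature table for a cohort
#'
#' Computes the three shape features for every mask in the cohort.
#'
#' @param cohort A `nodule_cohort` with rendered masks.
#' @return data.frame with columns `diameter_mm`, `surface_area_mm2`,
#'   `volume_mm3`, one row per nodule.
#' @export
compute_radiomics <- function(cohort) {
  if (is.null(cohort$masks)) stopf("cohort has no rendered masks")
  sp <- cohort$spacing %||% c(1, 1, 1)
  n <- length(cohort$masks)
  out <- data.frame(diameter_mm = numeric(n), surface_area_mm2 = numeric(n),
                    volume_mm3 = numeric(n))
  for (i in seq_len(n)) {
    m <- cohort$masks[[i]]
    out$diameter_mm[i] <- nodule_max_axial_diameter(m, sp)
    out$surface_area_mm2[i] <- nodule_surface_area(m, sp)
    out$volume_mm3[i] <- nodule_volume(m, sp)
  }
  out
}
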