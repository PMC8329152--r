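# Reader for LIDC-style XML nodule annotations: per-slice edge-point
# contours with z-positions plus the nine ordinal characteristic scores.
#
# Dialect (a simplified LIDC reading-session message):
#   <LidcReadMessage>
#     <readingSession>
#       <unblindedReadNodule>
#         <noduleID>...</noduleID>
#         <characteristics>
#           <subtlety>..</subtlety> ... <malignancy>..</malignancy>
#         </characteristics>
#         <roi>
#           <imageZposition>12.0</imageZposition>
#           <edgeMap><xCoord>10</xCoord><yCoord>12</yCoord></edgeMap>
#           ...
#         </roi>
#       </unblindedReadNodule>
#     </readingSession>
#   </LidcReadMessage>
#
# Coordinate convention: 0-based voxel indices, (x, y) within a slice, z by
# slice position in mm; contour points sit at voxel centers and trace the
# first pixel OUTSIDE the nodule, so rasterization keeps only strictly
# interior pixels.

characteristic_names <- function() c(biomarker_names(), "malignancy")

#' Parse LIDC-style XML nodule annotations
#'
#' @param source Path to an XML file, or a single XML string.
#' @return List of `nodule_annotation` objects: `nodule_id`,
#'   `characteristics` (named integer vector of the 9 scores), `contours`
#'   (list of `list(z_mm, points)` with `points` an n x 2 integer matrix of
#'   (x, y) voxel coordinates). Nodules with missing characteristics are
#'   excluded with a warning; malformed XML raises a parse error.
#' @export
parse_lidc_annotations <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    stopf("malformed annotation XML: %s", conditionMessage(e)))
  nodes <- xml2::xml_find_all(doc, ".//unblindedReadNodule")
  out <- list()
  for (nd in nodes) {
    id <- xml2::xml_text(xml2::xml_find_first(nd, "./noduleID"))
    ch_node <- xml2::xml_find_first(nd, "./characteristics")
    vals <- vapply(characteristic_names(), function(nm) {
      v <- xml2::xml_text(xml2::xml_find_first(ch_node, paste0("./", nm)))
      suppressWarnings(as.integer(v))
    }, integer(1))
    if (anyNA(vals)) {
      warnf("nodule %s: missing characteristic scores; record excluded", id)
      next
    }
    rois <- xml2::xml_find_all(nd, "./roi")
    contours <- lapply(rois, function(roi) {
      z <- as.numeric(xml2::xml_text(xml2::xml_find_first(roi, "./imageZposition")))
      xs <- as.integer(xml2::xml_text(xml2::xml_find_all(roi, "./edgeMap/xCoord")))
      ys <- as.integer(xml2::xml_text(xml2::xml_find_all(roi, "./edgeMap/yCoord")))
      list(z_mm = z, points = cbind(x = xs, y = ys))
    })
    contours <- Filter(function(cc) nrow(cc$points) >= 3L, contours)
    if (length(contours) == 0L) {
      warnf("nodule %s: no contour with >= 3 points; record excluded", id)
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(nodule_id = id, characteristics = vals, contours = contours),
      class = "nodule_annotation")
  }
  out
}

# strictly-interior polygon fill on an nx x ny pixel grid (0-based vertex
# coordinates at pixel centers). Returns a logical matrix [x, y]. Pixels on
# the polygon outline (vertices and interpolated edge pixels) are excluded:
# the outline traces the first pixel outside the nodule.
poly_fill_strict <- function(points, nx, ny) {
  fill <- matrix(FALSE, nx, ny)
  px <- points[, 1]; py <- points[, 2]
  nv <- length(px)
  nxt <- c(seq_len(nv)[-1L], 1L)
  eps <- 1e-9
  for (y in seq.int(max(0L, floor(min(py))), min(ny - 1L, ceiling(max(py))))) {
    xc <- numeric(0)
    for (i in seq_len(nv)) {
      y1 <- py[i]; y2 <- py[nxt[i]]
      if (y1 == y2) next
      # half-open rule [min, max) so shared vertices count once
      if (min(y1, y2) <= y && y < max(y1, y2)) {
        t <- (y - y1) / (y2 - y1)
        xc <- c(xc, px[i] + t * (px[nxt[i]] - px[i]))
      }
    }
    if (length(xc) < 2L) next
    xc <- sort(xc)
    for (j in seq.int(1L, length(xc) - 1L, by = 2L)) {
      xa <- xc[j]; xb <- xc[j + 1L]
      xs <- seq.int(ceiling(xa - eps), floor(xb + eps))
      xs <- xs[xs > xa + eps & xs < xb - eps & xs >= 0L & xs <= nx - 1L]
      if (length(xs)) fill[xs + 1L, y + 1L] <- TRUE
    }
  }
  # outline pixels: integer points lying exactly on a polygon edge
  for (i in seq_len(nv)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- px[nxt[i]]; y2 <- py[nxt[i]]
    xs <- max(0L, floor(min(x1, x2))):min(nx - 1L, ceiling(max(x1, x2)))
    ys <- max(0L, floor(min(y1, y2))):min(ny - 1L, ceiling(max(y1, y2)))
    for (x in xs) for (y in ys) {
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9) fill[x + 1L, y + 1L] <- FALSE
    }
  }
  fill
}

#' Rasterize a nodule annotation to a 3-D mask
#'
#' Fills each per-slice contour with an even-odd scanline, keeping only
#' pixels strictly inside the polygon and excluding the outline pixels
#' themselves (the outline sits on the first pixel outside the nodule).
#' Contour z-positions are matched to the nearest slice within half the
#' slice spacing.
#'
#' @param annotation A `nodule_annotation`.
#' @param grid_shape Integer triple (X, Y, Z) of the target grid.
#' @param spacing Voxel spacing in mm, length 3.
#' @param z_origin z-position (mm) of slice index 1 (default 0).
#' @return Logical X x Y x Z array. A degenerate (zero-area) contour
#'   contributes no voxels, with a warning.
#' @export
rasterize_annotation <- function(annotation, grid_shape, spacing = c(1, 1, 1),
                                 z_origin = 0) {
  stopifnot(inherits(annotation, "nodule_annotation"))
  grid_shape <- as.integer(grid_shape)
  mask <- array(FALSE, grid_shape)
  for (cc in annotation$contours) {
    pts <- cc$points
    if (any(pts[, 1] < 0L) || any(pts[, 1] > grid_shape[1] - 1L) ||
        any(pts[, 2] < 0L) || any(pts[, 2] > grid_shape[2] - 1L))
      stopf("contour extends outside the grid in x/y")
    zi <- (cc$z_mm - z_origin) / spacing[3]
    zr <- round(zi)
    if (abs(zi - zr) > 0.5 + 1e-9 || zr < 0 || zr > grid_shape[3] - 1L)
      stopf("contour z-position %.2f mm has no slice within half the slice spacing",
            cc$z_mm)
    sl <- poly_fill_strict(pts, grid_shape[1], grid_shape[2])
    if (!any(sl)) warnf("degenerate contour at z = %.2f mm: zero interior", cc$z_mm)
    mask[, , zr + 1L] <- mask[, , zr + 1L] | sl
  }
  mask
}

#' Extract a fixed-size box around a nodule
#'
#' Cuts a `box_shape` block from the intensity grid, centered at the mask
#' centroid (rounded to the nearest voxel) and zero-padded where the box
#' overruns the grid edge; the mask is cropped identically.
#'
#' @param intensity_grid 3-D numeric array (at least box-sized).
#' @param mask 3-D logical array, same shape as `intensity_grid`, non-empty.
#' @param box_shape Integer triple (default 32, 32, 16).
#' @return List with `volume` and `mask`, both of shape `box_shape`.
#' @export
extract_box <- function(intensity_grid, mask, box_shape = c(32L, 32L, 16L)) {
  box_shape <- as.integer(box_shape)
  gdim <- dim(intensity_grid)
  if (!all(dim(mask) == gdim)) stopf("mask and intensity grid shapes differ")
  if (!any(mask)) stopf("cannot extract a box around an empty mask")
  if (any(gdim < box_shape)) stopf("intensity grid is smaller than the box")
  ctr <- round(colMeans(which(mask, arr.ind = TRUE)))
  vol_out <- array(0, box_shape)
  mask_out <- array(FALSE, box_shape)
  # source range for each axis, plus the destination offset from padding
  lo <- ctr - floor((box_shape - 1L) / 2)
  hi <- lo + box_shape - 1L
  src <- lapply(1:3, function(a) max(1L, lo[a]):min(gdim[a], hi[a]))
  dst <- lapply(1:3, function(a) src[[a]] - lo[a] + 1L)
  vol_out[dst[[1]], dst[[2]], dst[[3]]] <-
    intensity_grid[src[[1]], src[[2]], src[[3]]]
  mask_out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  list(volume = vol_out, mask = mask_out)
}

#' Write cohort masks as LIDC-style fixture XML
#'
#' Emits one annotation per nodule: per-slice edge-point contours placed on
#' the first pixel outside the mask (8-connected outer ring, ordered by
#' angle around the slice centroid -- exact for the star-convex masks the
#' generator renders) plus the nine characteristic scores. Round-trips
#' through [parse_lidc_annotations()] and [rasterize_annotation()] back to
#' the original masks.
#'
#' @param cohort A `nodule_cohort` with rendered masks (possibly zero rows).
#' @param path Output XML file path.
#' @return `path`, invisibly.
#' @export
write_lidc_xml <- function(cohort, path) {
  rec <- cohort_records(cohort)
  n <- nrow(rec)
  if (n > 0L && is.null(cohort$masks)) stopf("cohort has no rendered masks")
  sp <- cohort$spacing %||% c(1, 1, 1)
  doc <- xml2::xml_new_root("LidcReadMessage")
  session <- xml2::xml_add_child(doc, "readingSession")
  for (i in seq_len(n)) {
    nd <- xml2::xml_add_child(session, "unblindedReadNodule")
    xml2::xml_add_child(nd, "noduleID", sprintf("N%04d", i))
    ch <- xml2::xml_add_child(nd, "characteristics")
    for (nm in characteristic_names())
      xml2::xml_add_child(ch, nm, as.character(rec[[nm]][i]))
    mask <- cohort$masks[[i]]
    for (z in seq_len(dim(mask)[3])) {
      sl <- mask[, , z]
      if (!any(sl)) next
      ring <- outer_ring(sl)
      if (nrow(ring) < 3L) next
      roi <- xml2::xml_add_child(nd, "roi")
      xml2::xml_add_child(roi, "imageZposition",
                          format((z - 1L) * sp[3], nsmall = 1))
      for (p in seq_len(nrow(ring))) {
        em <- xml2::xml_add_child(roi, "edgeMap")
        xml2::xml_add_child(em, "xCoord", as.character(ring[p, 1]))
        xml2::xml_add_child(em, "yCoord", as.character(ring[p, 2]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# 8-connected outer ring of a slice mask (the first pixels outside it),
# ordered by angle around the mask centroid. 0-based coordinates.
outer_ring <- function(sl) {
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sl
  dil <- pad
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    dil[2:(nx + 1L), 2:(ny + 1L)] <- dil[2:(nx + 1L), 2:(ny + 1L)] |
      pad[2:(nx + 1L) + dx, 2:(ny + 1L) + dy]
  }
  ring <- which(dil[2:(nx + 1L), 2:(ny + 1L)] & !sl, arr.ind = TRUE) - 1L
  if (nrow(ring) == 0L) return(ring)
  ij <- which(sl, arr.ind = TRUE) - 1L
  ctr <- colMeans(ij)
  ang <- atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1])
  ring[order(ang), , drop = FALSE]
}
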