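# Tile-and-append fusion of deep image features with auxiliary feature
# vectors. The short auxiliary vector (biomarkers and/or radiomics) is
# repeated a fixed number of times and concatenated to the 64-dim image
# feature vector, giving the canonical fused lengths:
#   image + biomarkers (8 x 8)            -> 128
#   image + radiomics  (3 x 21)           -> 127
#   image + both       (11 x 6)           -> 130

fusion_recipes <- list(
  image_only      = list(repeats = 0L,  length = 64L),
  image_biomarker = list(repeats = 8L,  length = 128L),
  image_radiomic  = list(repeats = 21L, length = 127L),
  image_both      = list(repeats = 6L,  length = 130L)
)

#' Tile-and-append an auxiliary vector to an image feature vector
#'
#' @param image_feat Numeric image feature vector (length 64 in the standard
#'   pipeline).
#' @param aux Numeric auxiliary vector of length m.
#' @param repeats Positive integer; `aux` is repeated this many times, order
#'   preserved within each repetition.
#' @return Numeric vector of length `length(image_feat) + m * repeats`.
#' @export
tile_append <- function(image_feat, aux, repeats) {
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stopf("repeats must be a positive integer")
  c(as.numeric(image_feat), rep(as.numeric(aux), times = repeats))
}

#' Fuse a cohort's image features with biomarkers and/or radiomics
#'
#' Row i of the output is [tile_append()] of row i of the inputs. For
#' `"image_both"` the auxiliary vector is the 8 biomarkers followed by the 3
#' radiomic features (diameter, surface area, volume), m = 11, repeated 6
#' times. No scaling is applied before fusion.
#'
#' @param features n x 64 matrix of deep image features.
#' @param biomarkers n x 8 matrix (required for biomarker recipes).
#' @param radiomics n x 3 matrix or data.frame (required for radiomic
#'   recipes), columns ordered diameter, surface area, volume.
#' @param recipe One of `"image_only"`, `"image_biomarker"`,
#'   `"image_radiomic"`, `"image_both"`.
#' @return n x L fused matrix with L = 64, 128, 127 or 130.
#' @export
fuse_cohort <- function(features, biomarkers = NULL, radiomics = NULL,
                        recipe = c("image_biomarker", "image_radiomic",
                                   "image_both", "image_only")) {
  recipe <- match.arg(recipe)
  features <- as.matrix(features)
  n <- nrow(features)
  need_bm <- recipe %in% c("image_biomarker", "image_both")
  need_rad <- recipe %in% c("image_radiomic", "image_both")
  if (need_bm) {
    if (is.null(biomarkers)) stopf("recipe %s requires biomarkers", recipe)
    biomarkers <- as.matrix(biomarkers)
    if (nrow(biomarkers) != n) stopf("biomarkers row count (%d) != features (%d)",
                                     nrow(biomarkers), n)
  }
  if (need_rad) {
    if (is.null(radiomics)) stopf("recipe %s requires radiomics", recipe)
    radiomics <- as.matrix(radiomics)
    if (nrow(radiomics) != n) stopf("radiomics row count (%d) != features (%d)",
                                    nrow(radiomics), n)
  }
  if (recipe == "image_only") return(features)
  aux <- switch(recipe,
                image_biomarker = biomarkers,
                image_radiomic  = radiomics,
                image_both      = cbind(biomarkers, radiomics))
  reps <- fusion_recipes[[recipe]]$repeats
  tiled <- aux[, rep(seq_len(ncol(aux)), times = reps), drop = FALSE]
  out <- cbind(features, tiled)
  dimnames(out) <- NULL
  out
}
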