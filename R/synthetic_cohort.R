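# Synthetic LIDC-like cohort generator.
#
# A single latent malignancy driver u ~ Uniform(0,1) per nodule drives (i) the
# 1-5 malignancy suspicion category via fixed thresholds, (ii) the mean of each
# ordinal biomarker through a linear link plus Gaussian jitter, and (iii) the
# rendered nodule size/shape (equivalent radius grows with u, spike count
# grows with the spiculation score). This reproduces the statistical premise
# the classification pipeline relies on -- biomarkers and morphology carry
# malignancy signal, with intermediate (R3) nodules in between -- without
# claiming fidelity to real CT texture.

# Ordinal ranges and latent slopes for the eight biomarkers. Positive slope:
# higher latent malignancy shifts the marker up; calcification trends toward 6
# ("absent") because suspicious nodules are typically non-calcified.
.biomarker_def <- data.frame(
  name  = c("subtlety", "int_structure", "calcification", "sphericity",
            "margin", "lobulation", "spiculation", "texture"),
  lo    = c(1, 1, 1, 1, 1, 1, 1, 1),
  hi    = c(5, 4, 6, 5, 5, 5, 5, 5),
  slope = c(1, 0, 1, -0.5, -0.8, 1, 1, 0.3),
  stringsAsFactors = FALSE
)

#' Biomarker column names
#'
#' The eight ordinal radiologist-scored imaging biomarkers, in canonical
#' order: subtlety, internal structure, calcification, sphericity, margin,
#' lobulation, spiculation, texture.
#' @return Character vector of length 8.
#' @export
biomarker_names <- function() .biomarker_def$name

#' Configuration for the synthetic cohort generator
#'
#' @param n_nodules Number of nodules to generate (at least 10).
#' @param r3_fraction Expected fraction of intermediate-malignancy (R3)
#'   nodules; default 0.374 matches the R3 share of the LIDC-style cohort the
#'   pipeline targets.
#' @param class_balance Fraction of suspicious (R4/R5) nodules among non-R3
#'   nodules.
#' @param biomarker_effect Non-negative strength of the monotone link between
#'   the latent malignancy driver and biomarker means. 0 decouples biomarkers
#'   from malignancy; the default 2 saturates size-linked markers at the
#'   latent extremes.
#' @param noise_sd Standard deviation of Gaussian jitter added on the ordinal
#'   scale before rounding/clamping.
#' @param driver_noise Standard deviation of the Gaussian rating noise the
#'   panel adds to the latent driver before it is thresholded into the 1-5
#'   malignancy category (the noisy rating is rank-normalized first, so the
#'   configured class fractions are realized exactly in expectation). This
#'   makes the intermediate (R3) band a set of *rater-uncertain* nodules --
#'   many of them genuinely benign or suspicious by their underlying driver
#'   -- rather than an ontologically distinct middle class, and keeps the
#'   classes from being perfectly separable as a noiseless rating would be.
#' @param size_jitter Standard deviation (mm) of Gaussian jitter on the
#'   rendered nodule's equivalent radius, decoupling morphology from the
#'   latent driver: real CT morphology is a weaker malignancy signal than
#'   radiologist-scored biomarkers, and the default reproduces that ordering.
#' @param volume_shape Integer triple, voxel grid of each nodule box.
#' @param spacing_mm Positive real triple, voxel spacing in mm.
#' @param render If `FALSE`, skip rendering volumes/masks (biomarker-only
#'   cohorts are much cheaper for large n).
#' @param seed Integer RNG seed; identical configs generate identical cohorts.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_nodules,
                             r3_fraction = 0.374,
                             class_balance = 0.5,
                             biomarker_effect = 2,
                             noise_sd = 0.7,
                             driver_noise = 0.25,
                             size_jitter = 1.0,
                             volume_shape = c(32L, 32L, 16L),
                             spacing_mm = c(1, 1, 1),
                             render = TRUE,
                             seed = 1L) {
  n_nodules <- as.integer(n_nodules)
  if (is.na(n_nodules) || n_nodules < 10L)
    stopf("n_nodules must be an integer >= 10, got %s", n_nodules)
  if (r3_fraction < 0 || r3_fraction > 1)
    stopf("r3_fraction must lie in [0, 1]")
  if (class_balance < 0 || class_balance > 1)
    stopf("class_balance must lie in [0, 1]")
  if (biomarker_effect < 0) stopf("biomarker_effect must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (driver_noise < 0) stopf("driver_noise must be non-negative")
  if (size_jitter < 0) stopf("size_jitter must be non-negative")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stopf("volume_shape must be three positive integers")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stopf("spacing_mm must be three positive reals")
  structure(list(
    n_nodules = n_nodules, r3_fraction = r3_fraction,
    class_balance = class_balance, biomarker_effect = biomarker_effect,
    noise_sd = noise_sd, driver_noise = driver_noise,
    size_jitter = size_jitter,
    volume_shape = volume_shape,
    spacing_mm = as.numeric(spacing_mm), render = isTRUE(render),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Sample ordinal biomarkers for given latent malignancy values
#'
#' Each marker mean moves linearly with the latent driver (slope scaled by
#' `config$biomarker_effect`), receives Gaussian jitter of sd
#' `config$noise_sd`, and is rounded and clamped to its ordinal range
#' (1-5 for most markers, 1-4 internal structure, 1-6 calcification).
#'
#' @param latent Numeric vector of latent malignancy values in `[0, 1]`.
#' @param config A [generator_config()].
#' @return Integer matrix `length(latent)` x 8 with biomarker columns.
#' @export
sample_biomarkers <- function(latent, config) {
  if (any(is.na(latent)) || any(latent < 0) || any(latent > 1))
    stopf("latent values must lie in [0, 1]")
  n <- length(latent)
  def <- .biomarker_def
  out <- matrix(0L, n, nrow(def), dimnames = list(NULL, def$name))
  for (j in seq_len(nrow(def))) {
    span <- def$hi[j] - def$lo[j]
    g <- 0.5 + def$slope[j] * config$biomarker_effect * (latent - 0.5) / 2
    raw <- def$lo[j] + span * g + rnorm(n, 0, config$noise_sd)
    out[, j] <- as.integer(clamp(round(raw), def$lo[j], def$hi[j]))
  }
  out
}

#' Render a synthetic nodule volume and mask
#'
#' The mask is a star-convex ellipsoid-with-spikes: an ellipsoid whose
#' equivalent radius grows linearly with the latent driver, plus radial
#' Gaussian bumps whose count grows with the spiculation score. The intensity
#' volume is background noise with an elevated foreground inside the mask.
#'
#' @param biomarkers Named integer vector (or 1-row matrix) of the 8
#'   biomarkers; only `spiculation` influences the shape.
#' @param latent Latent malignancy in `[0, 1]`.
#' @param config A [generator_config()].
#' @return List with `volume` (numeric array) and `mask` (logical array),
#'   both of shape `config$volume_shape`.
#' @export
render_nodule <- function(biomarkers, latent, config) {
  if (is.matrix(biomarkers)) biomarkers <- biomarkers[1L, ]
  if (length(latent) != 1L || is.na(latent) || latent < 0 || latent > 1)
    stopf("latent must be a single value in [0, 1]")
  shp <- config$volume_shape
  sp <- config$spacing_mm

  r_min <- 2.5; r_max <- 5.0
  r <- r_min + (r_max - r_min) * latent
  jit <- config$size_jitter %||% 0
  if (jit > 0) r <- clamp(r + rnorm(1L, 0, jit), 2.0, r_max + 0.5)
  axes <- r * runif(3L, 0.85, 1.15)

  spic <- as.numeric(biomarkers[["spiculation"]])
  n_spikes <- max(0L, as.integer(round(2 * (spic - 1))))
  spike_amp <- if (n_spikes > 0) 0.3 * r * runif(n_spikes, 0.7, 1) else numeric(0)

  max_extent <- max(axes) + if (n_spikes > 0) max(spike_amp) else 0
  half_min <- min(shp * sp) / 2
  if (max_extent > half_min)
    stopf("nodule radius %.1f mm exceeds half the smallest grid dimension (%.1f mm)",
          max_extent, half_min)

  cx <- (seq_len(shp[1]) - (shp[1] + 1) / 2) * sp[1]
  cy <- (seq_len(shp[2]) - (shp[2] + 1) / 2) * sp[2]
  cz <- (seq_len(shp[3]) - (shp[3] + 1) / 2) * sp[3]
  gx <- rep(cx, times = shp[2] * shp[3])
  gy <- rep(rep(cy, each = shp[1]), times = shp[3])
  gz <- rep(cz, each = shp[1] * shp[2])
  dist <- sqrt(gx^2 + gy^2 + gz^2)
  nz <- dist > 0
  dxu <- ifelse(nz, gx / dist, 0)
  dyu <- ifelse(nz, gy / dist, 0)
  dzu <- ifelse(nz, gz / dist, 1)

  # ellipsoid radius along each direction
  r_dir <- 1 / sqrt((dxu / axes[1])^2 + (dyu / axes[2])^2 + (dzu / axes[3])^2)

  if (n_spikes > 0) {
    sdir <- matrix(rnorm(3 * n_spikes), ncol = 3L)
    sdir <- sdir / sqrt(rowSums(sdir^2))
    w2 <- 0.06  # angular width of spikes
    for (s in seq_len(n_spikes)) {
      dot <- dxu * sdir[s, 1] + dyu * sdir[s, 2] + dzu * sdir[s, 3]
      r_dir <- r_dir + spike_amp[s] * exp(-(1 - dot) / w2)
    }
  }

  mask <- dist <= r_dir
  mask[!nz] <- TRUE  # grid center is always inside
  volume <- rnorm(length(mask), 0, 0.15)
  volume[mask] <- volume[mask] + 1 + rnorm(sum(mask), 0, 0.1)
  dim(mask) <- shp
  dim(volume) <- shp
  list(volume = volume, mask = mask)
}

#' Generate a synthetic nodule cohort
#'
#' Draws one latent malignancy value per nodule, assigns the 1-5 malignancy
#' category by thresholding the latent so the expected R3 fraction equals
#' `config$r3_fraction`, samples biomarkers, and (optionally) renders a
#' volume/mask pair per nodule. Nodules are grouped into synthetic patients
#' of 1-5 nodules each.
#'
#' @param config A [generator_config()].
#' @return A `nodule_cohort`: list with `biomarkers` (data.frame with
#'   patient_id, the 8 biomarker columns and malignancy), `volumes`, `masks`
#'   (lists of arrays, `NULL` when not rendered), `spacing`, `latent` (the
#'   generator's ground truth driver) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stopf("config must be created by generator_config()")
  with_seed(config$seed, {
    n <- config$n_nodules
    u <- runif(n)  # true driver: biomarkers and morphology follow this
    # panel rating channel: noisy view of the driver, rank-normalized so the
    # realized class fractions match the configured ones
    v <- u + rnorm(n, 0, config$driver_noise %||% 0)
    q <- (rank(v, ties.method = "first") - 0.5) / n
    r3 <- config$r3_fraction
    c1 <- (1 - r3) * (1 - config$class_balance)  # end of R12 band
    c2 <- c1 + r3                                # end of R3 band
    malignancy <- integer(n)
    malignancy[q < c1] <- ifelse(q[q < c1] < c1 / 2, 1L, 2L)
    malignancy[q >= c1 & q < c2] <- 3L
    hi <- q >= c2
    malignancy[hi] <- ifelse(q[hi] < c2 + (1 - c2) / 2, 4L, 5L)

    bm <- sample_biomarkers(u, config)

    # synthetic patients with 1-5 nodules each
    sizes <- sample(1:5, n, replace = TRUE)
    pid_idx <- rep(seq_along(sizes), sizes)[seq_len(n)]
    patient_id <- sprintf("SYN-%04d", pid_idx)

    volumes <- masks <- NULL
    if (config$render) {
      volumes <- vector("list", n)
      masks <- vector("list", n)
      for (i in seq_len(n)) {
        nd <- render_nodule(bm[i, ], u[i], config)
        volumes[[i]] <- nd$volume
        masks[[i]] <- nd$mask
      }
    }

    biomarkers <- data.frame(patient_id = patient_id,
                             as.data.frame(bm),
                             malignancy = malignancy,
                             stringsAsFactors = FALSE)
    structure(list(biomarkers = biomarkers, volumes = volumes, masks = masks,
                   spacing = config$spacing_mm, latent = u, config = config),
              class = "nodule_cohort")
  })
}

#' @export
print.nodule_cohort <- function(x, ...) {
  n <- nrow(x$biomarkers)
  tab <- table(factor(x$biomarkers$malignancy, levels = 1:5))
  cat(sprintf("<nodule_cohort> %d nodules (%s volumes)\n", n,
              if (is.null(x$volumes)) "no" else "with"))
  cat("  malignancy R1..R5:", paste(tab, collapse = " / "), "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes the annotation table as CSV (one row per nodule: patient_id, the 8
#' biomarkers, malignancy) and, when rendered, the volumes/masks plus spacing
#' as a single array container (RDS).
#'
#' @param cohort A `nodule_cohort`.
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$biomarkers, file.path(dir, "nodules.csv"), row.names = FALSE)
  if (!is.null(cohort$volumes)) {
    saveRDS(list(volumes = cohort$volumes, masks = cohort$masks,
                 spacing = cohort$spacing, latent = cohort$latent),
            file.path(dir, "arrays.rds"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `nodules.csv` (and optionally `arrays.rds`).
#' @return A `nodule_cohort`.
#' @export
read_cohort <- function(dir) {
  bio <- read.csv(file.path(dir, "nodules.csv"), stringsAsFactors = FALSE)
  arr_path <- file.path(dir, "arrays.rds")
  volumes <- masks <- NULL; spacing <- c(1, 1, 1); latent <- NULL
  if (file.exists(arr_path)) {
    arr <- readRDS(arr_path)
    volumes <- arr$volumes; masks <- arr$masks
    spacing <- arr$spacing; latent <- arr$latent
  }
  structure(list(biomarkers = bio, volumes = volumes, masks = masks,
                 spacing = spacing, latent = latent, config = NULL),
            class = "nodule_cohort")
}
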