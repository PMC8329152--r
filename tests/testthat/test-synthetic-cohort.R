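test_that("config validation rejects degenerate settings", {
  expect_error(generator_config(5L), "n_nodules")
  expect_error(generator_config(100L, r3_fraction = 1.2), "r3_fraction")
  expect_error(generator_config(100L, volume_shape = c(32, 0, 16)), "volume_shape")
  expect_error(generator_config(100L, spacing_mm = c(1, -1, 1)), "spacing")
  expect_error(generator_config(100L, biomarker_effect = -1), "biomarker_effect")
})

test_that("biomarker distributions are independent of latent when the effect is zero", {
  cfg <- generator_config(100L, biomarker_effect = 0)
  set.seed(11)
  lo <- sample_biomarkers(rep(0.1, 2000), cfg)
  hi <- sample_biomarkers(rep(0.9, 2000), cfg)
  for (m in c("spiculation", "lobulation", "subtlety")) {
    p <- wilcox.test(lo[, m], hi[, m], exact = FALSE)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("size-linked markers saturate at the latent maximum without noise", {
  cfg <- generator_config(100L, noise_sd = 0)
  b <- sample_biomarkers(1, cfg)
  expect_equal(b[1, "spiculation"], 5L, ignore_attr = TRUE)
  expect_equal(b[1, "lobulation"], 5L, ignore_attr = TRUE)
  expect_equal(b[1, "subtlety"], 5L, ignore_attr = TRUE)
  expect_error(sample_biomarkers(1.5, cfg), "latent")
})

test_that("latent drives spiculation strongly at the default effect", {
  # floor frozen from a generator self-oracle run (observed rho ~ 0.84 at
  # n = 5000; minus 3 standard errors)
  co <- test_cohort_tabular(5000L, seed = 32L)
  rho <- cor(co$latent, co$biomarkers$spiculation, method = "spearman")
  expect_gt(rho, 0.80)
})

test_that("minimum spiculation renders a pure ellipsoid with convex slices", {
  cfg <- generator_config(100L)
  bm <- sample_biomarkers(0, cfg)
  bm[1, "spiculation"] <- 1L
  set.seed(5)
  nd <- render_nodule(bm[1, ], 0, cfg)
  # every axial slice of an ellipsoid has contiguous runs in each row/column
  for (z in seq_len(dim(nd$mask)[3])) {
    sl <- nd$mask[, , z]
    if (!any(sl)) next
    for (i in seq_len(nrow(sl))) {
      run <- which(sl[i, ])
      if (length(run) > 1) expect_true(all(diff(run) == 1L))
    }
  }
  expect_true(nd$mask[16, 16, 8])  # center voxel inside
})

test_that("rendering is deterministic and monotone in latent", {
  cfg <- generator_config(100L)
  bm <- sample_biomarkers(0.5, cfg)
  a <- with(list(), { set.seed(42); render_nodule(bm[1, ], 0.5, cfg) })
  b <- with(list(), { set.seed(42); render_nodule(bm[1, ], 0.5, cfg) })
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)

  count_at <- function(latent, seed) {
    set.seed(seed)
    mean(vapply(1:100, function(i) {
      bmx <- sample_biomarkers(latent, cfg)
      sum(render_nodule(bmx[1, ], latent, cfg)$mask)
    }, numeric(1)))
  }
  expect_gt(count_at(0.9, 7), count_at(0.1, 7))
})

test_that("oversized nodules are rejected", {
  cfg <- generator_config(100L, volume_shape = c(10L, 10L, 8L), size_jitter = 0)
  bm <- sample_biomarkers(1, cfg)
  set.seed(1)
  expect_error(render_nodule(bm[1, ], 1, cfg), "half the smallest grid dimension")
})

test_that("realized class mix matches the configured fractions", {
  co <- test_cohort_tabular(4000L, seed = 33L)
  r3 <- sum(co$biomarkers$malignancy == 3L)
  expect_lt(abs(r3 - 4000 * 0.374), 3 * sqrt(4000 * 0.374 * 0.626) + 1)
  # R12/R45 balance
  n12 <- sum(co$biomarkers$malignancy <= 2L)
  n45 <- sum(co$biomarkers$malignancy >= 4L)
  expect_lt(abs(n12 - n45), 3 * sqrt(4000 * 0.313) + 1)
  # malignancy ranks align with size-linked biomarkers
  expect_gt(cor(co$biomarkers$malignancy, co$biomarkers$spiculation,
                method = "spearman"), 0)
  expect_gt(cor(co$biomarkers$malignancy, co$biomarkers$lobulation,
                method = "spearman"), 0)
})

test_that("r3_fraction = 0 produces no intermediate nodules", {
  co <- generate_cohort(generator_config(200L, r3_fraction = 0, render = FALSE,
                                         seed = 8L))
  expect_false(any(co$biomarkers$malignancy == 3L))
})

test_that("identical configs generate identical cohorts", {
  cfg <- generator_config(40L, seed = 77L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$masks, b$masks)
  expect_identical(a$latent, b$latent)
})

test_that("cohorts round-trip through the tabular/array container", {
  co <- generate_cohort(generator_config(15L, seed = 55L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$biomarkers, co$biomarkers)
  expect_identical(back$volumes, co$volumes)
  expect_identical(back$masks, co$masks)
})
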