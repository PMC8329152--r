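make_annotation <- function(points, z_mm = 0, chars = NULL) {
  chars <- chars %||% stats::setNames(rep(3L, 9), c(biomarker_names(), "malignancy"))
  structure(list(nodule_id = "T1", characteristics = chars,
                 contours = list(list(z_mm = z_mm, points = points))),
            class = "nodule_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fixture XML round-trips annotation counts and characteristics", {
  co <- generate_cohort(generator_config(10L, seed = 88L))
  path <- withr::local_tempfile(fileext = ".xml")
  write_lidc_xml(co, path)
  ann <- parse_lidc_annotations(path)
  expect_length(ann, 10L)
  for (i in seq_along(ann)) {
    expect_equal(unname(ann[[i]]$characteristics[biomarker_names()]),
                 unname(unlist(co$biomarkers[i, biomarker_names()])))
    expect_equal(unname(ann[[i]]$characteristics[["malignancy"]]),
                 co$biomarkers$malignancy[i])
  }
})

test_that("an empty cohort writes valid XML with zero nodules", {
  co <- generate_cohort(generator_config(10L, seed = 88L))
  co$biomarkers <- co$biomarkers[0, , drop = FALSE]
  co$masks <- list(); co$volumes <- list()
  path <- withr::local_tempfile(fileext = ".xml")
  write_lidc_xml(co, path)
  expect_length(parse_lidc_annotations(path), 0L)
})

test_that("nodules with missing characteristics are excluded with a warning", {
  xml <- paste0(
    "<LidcReadMessage><readingSession><unblindedReadNodule>",
    "<noduleID>N1</noduleID><characteristics>",
    paste0("<", biomarker_names(), ">3</", biomarker_names(), ">", collapse = ""),
    "</characteristics>",  # malignancy missing
    "<roi><imageZposition>0.0</imageZposition>",
    "<edgeMap><xCoord>1</xCoord><yCoord>1</yCoord></edgeMap>",
    "<edgeMap><xCoord>3</xCoord><yCoord>1</yCoord></edgeMap>",
    "<edgeMap><xCoord>2</xCoord><yCoord>3</yCoord></edgeMap>",
    "</roi></unblindedReadNodule></readingSession></LidcReadMessage>")
  expect_warning(ann <- parse_lidc_annotations(xml), "excluded")
  expect_length(ann, 0L)
  expect_error(parse_lidc_annotations("<unclosed"), "malformed")
})

test_that("hand-written fixture contours parse with exact point counts", {
  square <- cbind(c(2, 7, 7, 2), c(2, 2, 7, 7))
  tri <- cbind(c(1, 5, 3), c(1, 1, 4))
  mk_roi <- function(pts, z) paste0(
    "<roi><imageZposition>", z, "</imageZposition>",
    paste0("<edgeMap><xCoord>", pts[, 1], "</xCoord><yCoord>", pts[, 2],
           "</yCoord></edgeMap>", collapse = ""), "</roi>")
  chars <- paste0("<", c(biomarker_names(), "malignancy"), ">2</",
                  c(biomarker_names(), "malignancy"), ">", collapse = "")
  xml <- paste0("<LidcReadMessage><readingSession>",
                "<unblindedReadNodule><noduleID>A</noduleID>",
                "<characteristics>", chars, "</characteristics>",
                mk_roi(square, "0.0"), mk_roi(square, "1.0"),
                "</unblindedReadNodule>",
                "<unblindedReadNodule><noduleID>B</noduleID>",
                "<characteristics>", chars, "</characteristics>",
                mk_roi(tri, "2.0"), "</unblindedReadNodule>",
                "</readingSession></LidcReadMessage>")
  ann <- parse_lidc_annotations(xml)
  expect_length(ann, 2L)
  expect_length(ann[[1]]$contours, 2L)
  expect_equal(nrow(ann[[1]]$contours[[1]]$points), 4L)
  expect_equal(nrow(ann[[2]]$contours[[1]]$points), 3L)
  expect_equal(ann[[2]]$contours[[1]]$z_mm, 2)
})

test_that("a 6x6 square outline rasterizes to the 16 strictly interior voxels", {
  sq <- cbind(c(2:7, rep(7, 5), 6:2, rep(2, 4)),
              c(rep(2, 6), 3:7, rep(7, 5), 6:3))  # dense pixel chain
  ann <- make_annotation(sq)
  m <- rasterize_annotation(ann, c(10L, 10L, 1L))
  expect_equal(sum(m), 16L)
  expect_true(all(m[4:7, 4:7, 1]))
})

test_that("degenerate collinear contours rasterize to nothing, with a warning", {
  ann <- make_annotation(cbind(c(1, 3, 5), c(2, 2, 2)))
  expect_warning(m <- rasterize_annotation(ann, c(8L, 8L, 1L)), "degenerate")
  expect_equal(sum(m), 0L)
})

test_that("contours outside the grid or between slices are rejected", {
  ann <- make_annotation(cbind(c(2, 12, 6), c(2, 2, 6)))
  expect_error(rasterize_annotation(ann, c(10L, 10L, 1L)), "outside")
  ann2 <- make_annotation(cbind(c(1, 3, 2), c(1, 1, 3)), z_mm = 4.9)
  expect_error(rasterize_annotation(ann2, c(8L, 8L, 2L), spacing = c(1, 1, 1)),
               "slice")
})

test_that("rasterization matches a brute-force even-odd oracle", {
  set.seed(31)
  for (rep in 1:8) {
    poly <- random_star_polygon(sample(5:12, 1), 10, 10, 4, 8)
    if (nrow(unique(poly)) < 3) next
    ann <- make_annotation(poly)
    m <- rasterize_annotation(ann, c(20L, 20L, 1L))
    oracle <- pip_strict_oracle(poly, 20L, 20L)
    expect_equal(m[, , 1], oracle)
  }
})

test_that("sphere masks survive the write -> parse -> rasterize round trip", {
  co <- generate_cohort(generator_config(10L, seed = 90L))
  path <- withr::local_tempfile(fileext = ".xml")
  write_lidc_xml(co, path)
  ann <- parse_lidc_annotations(path)
  for (i in c(1L, 4L, 7L)) {
    m <- rasterize_annotation(ann[[i]], dim(co$masks[[i]]), co$spacing)
    expect_lt(abs(sum(m) / sum(co$masks[[i]]) - 1), 0.05)
  }
})

test_that("extract_box centers, pads and keeps the fixed shape", {
  set.seed(41)
  grid <- array(rnorm(48 * 48 * 24), c(48, 48, 24))
  mask <- array(FALSE, dim(grid))
  mask[23:26, 23:26, 11:14] <- TRUE   # centroid at (24.5, 24.5, 12.5) -> 24,24,12
  bx <- extract_box(grid, mask)
  expect_equal(dim(bx$volume), c(32, 32, 16))
  ctr <- round(colMeans(which(mask, arr.ind = TRUE)))
  expect_equal(bx$volume, grid[(ctr[1] - 15):(ctr[1] + 16),
                               (ctr[2] - 15):(ctr[2] + 16),
                               (ctr[3] - 7):(ctr[3] + 8)])

  # centroid 4 voxels from the x = 0 face: padding margin of 12 zero planes
  mask2 <- array(FALSE, dim(grid)); mask2[4, 24, 12] <- TRUE
  bx2 <- extract_box(grid, mask2)
  expect_equal(dim(bx2$volume), c(32, 32, 16))
  expect_true(all(bx2$volume[1:12, , ] == 0))
  expect_false(all(bx2$volume[13, , ] == 0))

  # recomputed mask centroid lands within one voxel of the box center
  co <- test_cohort_rendered()
  for (i in 1:5) {
    bx3 <- extract_box(co$volumes[[i]], co$masks[[i]])
    ctr3 <- colMeans(which(bx3$mask, arr.ind = TRUE))
    expect_true(all(abs(ctr3 - c(16.5, 16.5, 8.5)) <= 1.5))
  }
  expect_error(extract_box(grid, array(FALSE, dim(grid))), "empty")
})
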