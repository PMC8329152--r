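tiny_spec <- function(l2 = 0.001) {
  malignet_spec(conv_blocks = list(2L, 3L), dense = c(8L, 4L, 1L),
                input_shape = c(8L, 8L, 4L), l2 = l2)
}

test_that("the reference architecture has the documented trace, head and size", {
  net <- malignet_build(malignet_spec(), seed = 1L)
  tr <- malignet_shape_trace(net)
  expect_equal(tr[, "channels"], c(32L, 64L, 128L, 256L, 512L))
  expect_equal(tr[4, 1:3], c(x = 2L, y = 2L, z = 1L))
  expect_equal(tr[5, 1:3], c(x = 2L, y = 2L, z = 1L))  # no pool after block 5

  # closed-form parameter count over the declared layers
  widths <- c(32, 32, 64, 64, 128, 128, 256, 256, 512, 512)
  cin <- c(1, widths[-10])
  conv_params <- sum(27 * cin * widths + widths)
  dense_in <- c(2 * 2 * 1 * 512, 1024, 64)
  dense_out <- c(1024, 64, 1)
  expect_equal(malignet_param_count(net),
               conv_params + sum(dense_in * dense_out + dense_out))

  # forward pass on an all-zeros box: finite scalar score, 64 features
  box <- array(0, c(32, 32, 16, 1))
  s <- malignet_predict(net, box)
  expect_length(s, 1L)
  expect_true(is.finite(s) && s >= 0 && s <= 1)
  f <- malignet_features(net, box)
  expect_equal(dim(f), c(1L, 64L))
})

test_that("analytic gradients agree with finite differences", {
  net <- malignet_build(tiny_spec(), seed = 7L)
  set.seed(8)
  x <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  y <- c(1, 0, 1)
  w <- nodulefuse:::cnn_get_weights(net$ptr)
  lossfn <- function(w) {
    nodulefuse:::cnn_set_weights(net$ptr, w)
    p <- pmin(pmax(nodulefuse:::cnn_forward(net$ptr, as.numeric(x),
                                            c(8L, 8L, 4L, 3L), FALSE), 1e-12),
              1 - 1e-12)
    mean(-(y * log(p) + (1 - y) * log(1 - p))) +
      0.001 * sum(vapply(seq(1, length(w), 2),
                         function(i) sum(w[[i]]^2), numeric(1)))
  }
  nodulefuse:::cnn_set_weights(net$ptr, w)
  g <- nodulefuse:::cnn_gradients(net$ptr, as.numeric(x), c(8L, 8L, 4L, 3L), y)
  set.seed(9)
  h <- 1e-6
  for (ti in seq_along(w)) {
    j <- sample(length(w[[ti]]), 1)
    wp <- w; wp[[ti]][j] <- wp[[ti]][j] + h
    wm <- w; wm[[ti]][j] <- wm[[ti]][j] - h
    num <- (lossfn(wp) - lossfn(wm)) / (2 * h)
    expect_equal(g[[ti]][j], num, tolerance = 1e-4)
  }
})

test_that("a zero learning rate leaves weights and loss unchanged", {
  co <- test_cohort_rendered()
  idx <- which(co$biomarkers$malignancy != 3L)[1:8]
  y <- as.integer(co$biomarkers$malignancy[idx] >= 4L)
  b <- cohort_boxes(co, idx)
  net <- malignet_build(malignet_spec_small(), seed = 2L)
  w0 <- nodulefuse:::cnn_get_weights(net$ptr)
  net <- malignet_train(net, b, y,
                        malignet_train_config(epochs = 2L, learning_rate = 0,
                                              seed = 3L))
  expect_identical(nodulefuse:::cnn_get_weights(net$ptr), w0)
  expect_equal(net$history$loss[1], net$history$loss[2])
})

test_that("training memorizes a small set of boxes", {
  co <- test_cohort_rendered()
  idx <- which(co$biomarkers$malignancy != 3L)[1:32]
  y <- as.integer(co$biomarkers$malignancy[idx] >= 4L)
  b <- cohort_boxes(co, idx)
  net <- malignet_build(malignet_spec_small(l2 = 0), seed = 3L)
  net <- malignet_train(net, b, y,
                        malignet_train_config(epochs = 30L, batch_size = 8L,
                                              seed = 5L))
  expect_gte(roc_auc(malignet_predict(net, b), y)$auc, 0.99)
})

test_that("trained networks beat chance on held-out size-driven classes", {
  co <- test_cohort_rendered()
  aucs <- vapply(1:5, function(s) {
    sp <- supervised_split(co, "full", seed = s)
    net <- malignet_build(malignet_spec_small(), seed = s)
    net <- malignet_train(net, cohort_boxes(co, sp$train$index), sp$train$labels,
                          malignet_train_config(epochs = 2L, seed = s))
    roc_auc(malignet_predict(net, cohort_boxes(co, sp$test$index)),
            sp$test$labels)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.5 + 3 * sd(aucs) / sqrt(5))
})

test_that("inference is pure, deterministic and batch-size invariant", {
  net <- malignet_build(malignet_spec_small(), seed = 4L)
  set.seed(12)
  b <- array(rnorm(32 * 32 * 16 * 32), c(32, 32, 16, 32))
  s1 <- malignet_predict(net, b)
  s2 <- malignet_predict(net, b)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  one <- malignet_predict(net, b[, , , 5, drop = FALSE])
  expect_equal(one, s1[5], tolerance = 1e-5)

  f <- malignet_features(net, b)
  expect_equal(ncol(f), 64L)
  expect_true(all(f >= 0))                       # relu range
  expect_gt(nrow(unique(round(f, 10))), 30L)     # distinct boxes, distinct vectors
  expect_error(malignet_predict(net, array(0, c(8, 8, 4, 1))), "32x32x16")
})

test_that("training rejects single-class labels", {
  net <- malignet_build(malignet_spec_small(), seed = 4L)
  b <- array(rnorm(32 * 32 * 16 * 4), c(32, 32, 16, 4))
  expect_error(malignet_train(net, b, rep(1, 4)), "single-class")
})

test_that("checkpoints restore weights and predictions exactly", {
  net <- malignet_build(malignet_spec_small(), seed = 6L)
  set.seed(13)
  b <- array(rnorm(32 * 32 * 16 * 4), c(32, 32, 16, 4))
  path <- withr::local_tempfile(fileext = ".rds")
  malignet_save(net, path)
  back <- malignet_load(path)
  expect_identical(malignet_predict(back, b), malignet_predict(net, b))
})

test_that("identically seeded builds and trainings coincide", {
  co <- test_cohort_rendered()
  idx <- which(co$biomarkers$malignancy != 3L)[1:16]
  y <- as.integer(co$biomarkers$malignancy[idx] >= 4L)
  b <- cohort_boxes(co, idx)
  run <- function() {
    net <- malignet_build(malignet_spec_small(), seed = 5L)
    net <- malignet_train(net, b, y, malignet_train_config(epochs = 1L, seed = 6L))
    malignet_predict(net, b)
  }
  expect_identical(run(), run())
})
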