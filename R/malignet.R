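# R interface to the 3D CNN engine (src/cnn3d.cpp).
#
# The reference architecture is a VGG-style 3D network on 32x32x16 boxes:
# five double-conv blocks of widths (32,32),(64,64),(128,128),(256,256),
# (512,512), all kernels 3x3x3 same-padded with relu, 2x2x2 max-pooling after
# the first four blocks (spatial trace 32x32x16 -> 16x16x8 -> 8x8x4 -> 4x4x2
# -> 2x2x1), then a dense head of 1024, 64 and 1 sigmoid units with an L2
# weight penalty of 0.01. The 64-unit layer is the deep image feature vector.

#' Architecture specification for the 3D CNN
#'
#' Defaults reproduce the reference architecture described above. The
#' penultimate dense width (64) is the deep-feature dimensionality consumed
#' by downstream fusion and should not normally be changed.
#'
#' @param conv_blocks List of integer vectors; element b gives the filter
#'   widths of the conv layers in block b. Max-pooling (2,2,2) follows every
#'   block except the last.
#' @param dense Integer vector of dense widths; the last must be 1 (sigmoid
#'   output), the second-to-last is the deep-feature width.
#' @param input_shape Integer triple, the box shape (default 32,32,16).
#' @param l2 L2 regularization factor on all weight matrices (default 0.01).
#' @return A `malignet_spec`.
#' @export
malignet_spec <- function(conv_blocks = list(c(32L, 32L), c(64L, 64L),
                                             c(128L, 128L), c(256L, 256L),
                                             c(512L, 512L)),
                          dense = c(1024L, 64L, 1L),
                          input_shape = c(32L, 32L, 16L),
                          l2 = 0.01) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stopf("input_shape must be three positive integers")
  conv_blocks <- lapply(conv_blocks, as.integer)
  if (length(conv_blocks) < 1L || any(vapply(conv_blocks, function(b)
    length(b) < 1L || any(b < 1L), logical(1))))
    stopf("conv_blocks must be a non-empty list of positive integer vectors")
  dense <- as.integer(dense)
  if (length(dense) < 2L || dense[length(dense)] != 1L)
    stopf("dense must end in a single output unit")
  if (l2 < 0) stopf("l2 must be non-negative")
  structure(list(conv_blocks = conv_blocks, dense = dense,
                 input_shape = input_shape, l2 = l2),
            class = "malignet_spec")
}

#' Scaled-down architecture for desk-scale runs
#'
#' Same topology as [malignet_spec()] but with narrow filters
#' ((4,4),(8,8),(8,8),(16,16)) and a compact dense head (128, 64, 1). The
#' deep-feature width stays 64. Intended for simulation studies and tests
#' where the full-width network would be needlessly expensive on a CPU.
#'
#' @param l2 L2 regularization factor (default 0.001; the full-width default
#'   of 0.01 over-regularizes a network this small).
#' @return A `malignet_spec`.
#' @export
malignet_spec_small <- function(l2 = 0.001) {
  malignet_spec(conv_blocks = list(c(4L, 4L), c(8L, 8L), c(8L, 8L), c(16L, 16L)),
                dense = c(128L, 64L, 1L), l2 = l2)
}

#' Training configuration for the 3D CNN
#'
#' None of these are dictated by the classification protocol itself; the
#' defaults are conventional Adam settings for a small 3D network.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed Integer seed controlling weight initialization order-free
#'   shuffling; `NULL` leaves the caller's RNG in charge.
#' @param verbose Print per-epoch mean loss.
#' @return A `malignet_train_config`.
#' @export
malignet_train_config <- function(epochs = 5L, batch_size = 16L,
                                  learning_rate = 1e-3, beta1 = 0.9,
                                  beta2 = 0.999, eps = 1e-8,
                                  seed = NULL, verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = seed, verbose = isTRUE(verbose)),
            class = "malignet_train_config")
}

# He-normal initial weights drawn from R's RNG for reproducibility
malignet_init_weights <- function(ptr) {
  w <- cnn_get_weights(ptr)
  for (i in seq(1L, length(w), by = 2L)) {
    fan_in <- nrow(w[[i]])
    w[[i]][] <- rnorm(length(w[[i]]), sd = sqrt(2 / fan_in))
  }
  w
}

#' Build a 3D CNN model
#'
#' @param spec A [malignet_spec()]; default the full reference architecture.
#' @param seed Integer seed for He-normal weight initialization.
#' @return A `malignet` model handle.
#' @export
malignet_build <- function(spec = malignet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "malignet_spec"))
  ptr <- cnn_create(spec$input_shape, spec$conv_blocks, spec$dense, spec$l2)
  w <- with_seed(seed, malignet_init_weights(ptr))
  cnn_set_weights(ptr, w)
  structure(list(ptr = ptr, spec = spec, seed = as.integer(seed),
                 history = NULL),
            class = "malignet")
}

#' @export
print.malignet <- function(x, ...) {
  widths <- vapply(x$spec$conv_blocks, function(b) paste(b, collapse = ","),
                   character(1))
  cat(sprintf("<malignet> input %s | conv blocks (%s) | dense %s | %s parameters\n",
              paste(x$spec$input_shape, collapse = "x"),
              paste(widths, collapse = ")("),
              paste(x$spec$dense, collapse = "/"),
              format(malignet_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `malignet`.
#' @return Total count of weights and biases.
#' @export
malignet_param_count <- function(model) cnn_param_count(model$ptr)

#' Spatial/channel shape after each conv block
#' @param model A `malignet`.
#' @return Integer matrix, one row per block: X, Y, Z (post-pool where a pool
#'   follows the block) and channels.
#' @export
malignet_shape_trace <- function(model) {
  tr <- cnn_shape_trace(model$ptr)
  matrix(tr, ncol = 4L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z", "channels")))
}

# Accept a list of 3-D arrays or a 4-D array; returns 4-D array normalized
# per box to zero mean / unit variance (constant boxes are left centered).
prepare_boxes <- function(boxes, input_shape) {
  if (is.list(boxes)) {
    arr <- array(0, c(input_shape, length(boxes)))
    for (i in seq_along(boxes)) arr[, , , i] <- boxes[[i]]
    boxes <- arr
  }
  d <- dim(boxes)
  if (length(d) == 3L) { dim(boxes) <- c(d, 1L); d <- dim(boxes) }
  if (length(d) != 4L || !all(d[1:3] == input_shape))
    stopf("boxes must be %s arrays", paste(input_shape, collapse = "x"))
  nvox <- prod(d[1:3])
  m <- matrix(boxes, nvox, d[4])
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  sdv[sdv < 1e-8] <- 1
  m <- sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  array(m, d)
}

#' Train the 3D CNN
#'
#' Minimizes mean binary cross-entropy plus the architecture's L2 penalty
#' with Adam, shuffling minibatches each epoch. Boxes are normalized to zero
#' mean / unit variance per box before entering the network (the same
#' normalization [malignet_predict()] and [malignet_features()] apply).
#'
#' @param model A `malignet`.
#' @param boxes 4-D array (X x Y x Z x n) or list of 3-D arrays of raw box
#'   intensities.
#' @param labels Binary 0/1 vector with both classes present.
#' @param config A [malignet_train_config()].
#' @return The model, with a `history` data.frame (epoch, mean loss).
#' @export
malignet_train <- function(model, boxes, labels,
                           config = malignet_train_config()) {
  stopifnot(inherits(model, "malignet"))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stopf("training labels are single-class")
  x <- prepare_boxes(boxes, model$spec$input_shape)
  n <- dim(x)[4]
  if (length(labels) != n) stopf("labels length (%d) != boxes (%d)", length(labels), n)
  nvox <- prod(model$spec$input_shape)
  xm <- matrix(x, nvox, n)
  run <- function() {
    hist <- data.frame(epoch = integer(0), loss = numeric(0))
    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- xm[, ix, drop = FALSE]
        l <- cnn_train_batch(model$ptr, as.numeric(batch),
                             c(model$spec$input_shape, length(ix)),
                             labels[ix], config$learning_rate,
                             config$beta1, config$beta2, config$eps)
        losses <- c(losses, l)
      }
      hist <- rbind(hist, data.frame(epoch = e, loss = mean(losses)))
      if (config$verbose)
        message(sprintf("epoch %d/%d: loss %.4f", e, config$epochs, mean(losses)))
    }
    hist
  }
  model$history <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  model
}

#' Predict malignancy-suspicion scores
#'
#' @param model A trained `malignet`.
#' @param boxes 4-D array or list of 3-D arrays of raw box intensities.
#' @return Numeric vector of sigmoid scores in `[0, 1]`, one per box.
#'   Inference is pure and deterministic.
#' @export
malignet_predict <- function(model, boxes) {
  x <- prepare_boxes(boxes, model$spec$input_shape)
  as.numeric(cnn_forward(model$ptr, as.numeric(x),
                         c(model$spec$input_shape, dim(x)[4]), FALSE))
}

#' Extract deep image features
#'
#' Post-relu activations of the second-to-last dense layer (width 64 in the
#' standard architecture), one row per box.
#'
#' @param model A trained `malignet`.
#' @param boxes 4-D array or list of 3-D arrays of raw box intensities.
#' @return n x 64 numeric matrix (n x penultimate width in general).
#' @export
malignet_features <- function(model, boxes) {
  x <- prepare_boxes(boxes, model$spec$input_shape)
  cnn_forward(model$ptr, as.numeric(x),
              c(model$spec$input_shape, dim(x)[4]), TRUE)
}

#' Serialize / restore a model
#'
#' The checkpoint holds the architecture spec and all weight tensors, so the
#' evaluation harness can reload per-iteration models.
#'
#' @param model A `malignet`.
#' @param path Checkpoint file path (RDS).
#' @return `malignet_save` returns `path` invisibly; `malignet_load` the
#'   restored model.
#' @export
malignet_save <- function(model, path) {
  saveRDS(list(spec = model$spec, weights = cnn_get_weights(model$ptr),
               seed = model$seed, history = model$history), path)
  invisible(path)
}

#' @rdname malignet_save
#' @export
malignet_load <- function(path) {
  ck <- readRDS(path)
  ptr <- cnn_create(ck$spec$input_shape, ck$spec$conv_blocks, ck$spec$dense,
                    ck$spec$l2)
  cnn_set_weights(ptr, ck$weights)
  structure(list(ptr = ptr, spec = ck$spec, seed = ck$seed,
                 history = ck$history),
            class = "malignet")
}

#' Stack cohort volumes into a 4-D box array
#'
#' @param cohort A `nodule_cohort` with rendered volumes.
#' @param indices Optional row indices (default all).
#' @return X x Y x Z x n numeric array of raw intensities.
#' @export
cohort_boxes <- function(cohort, indices = NULL) {
  if (is.null(cohort$volumes)) stopf("cohort has no rendered volumes")
  indices <- indices %||% seq_along(cohort$volumes)
  shp <- dim(cohort$volumes[[1]])
  arr <- array(0, c(shp, length(indices)))
  for (j in seq_along(indices)) arr[, , , j] <- cohort$volumes[[indices[j]]]
  arr
}
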