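# ROC/AUC computation, classifier fitting, repeated-split experiment
# harness, and two-tailed Student's t comparison of AUC samples.

#' ROC curve and AUC
#'
#' Builds the ROC curve over all distinct score thresholds (sensitivity vs
#' 1 - specificity) and computes the AUC by trapezoidal integration, which
#' for a step curve with tied scores equals the pairwise concordance
#' statistic (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n1 n0).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A `roc_curve`: list with `thresholds`, `fpr`, `tpr` (monotone,
#'   endpoints (0,0) and (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC is undefined: labels contain a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # last index of each run of tied scores
  idx <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[idx] / n1)
  fpr <- c(0, cumsum(1L - y)[idx] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[idx]), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Vertically average ROC curves
#'
#' Interpolates each curve's tpr onto a fixed 101-point fpr grid and
#' averages pointwise; the AUC is recomputed on the averaged curve.
#'
#' @param curves List of `roc_curve` objects (at least one).
#' @return A `roc_curve` on the fpr grid `seq(0, 1, 0.01)`.
#' @export
average_roc <- function(curves) {
  if (length(curves) == 0L) stopf("no curves to average")
  grid <- seq(0, 1, by = 0.01)
  # evaluate the ROC polyline at a given fpr; vertical segments (duplicated
  # fpr values) take their upper end when hit exactly, and interpolation
  # between distinct fpr values uses the segment actually joining them
  eval_polyline <- function(fpr, tpr, g) {
    vapply(g, function(x) {
      hit <- fpr == x
      if (any(hit)) return(max(tpr[hit]))
      i <- max(which(fpr < x))   # top of the preceding vertical run
      j <- min(which(fpr > x))   # bottom of the following one
      tpr[i] + (x - fpr[i]) / (fpr[j] - fpr[i]) * (tpr[j] - tpr[i])
    }, numeric(1))
  }
  tprs <- vapply(curves, function(cv) {
    eval_polyline(cv$fpr, cv$tpr, grid)
  }, numeric(length(grid)))
  tpr <- rowMeans(tprs)
  auc <- sum(diff(grid) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = NULL, fpr = grid, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' Two-tailed Student's t test between two AUC samples
#'
#' Pooled-variance two-sample statistic with df = na + nb - 2 and a
#' two-sided p value; significance is declared at `alpha`. When both samples
#' are constant the test degenerates: equal means give t = 0, p = 1;
#' different means give p = 0 with a warning.
#'
#' @param auc_a,auc_b Numeric AUC samples, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A `t_test_result`: `t_stat`, `df`, `p_value`, `alpha`,
#'   `significant` (`p_value < alpha`).
#' @export
t_test_auc <- function(auc_a, auc_b, alpha = 0.05) {
  if (length(auc_a) < 2L || length(auc_b) < 2L)
    stopf("each AUC sample must have length >= 2")
  na <- length(auc_a); nb <- length(auc_b)
  df <- na + nb - 2
  if (sd(auc_a) == 0 && sd(auc_b) == 0) {
    if (mean(auc_a) == mean(auc_b)) {
      t_stat <- 0; p <- 1
    } else {
      warnf("degenerate samples with zero variance and different means; p -> 0")
      t_stat <- sign(mean(auc_a) - mean(auc_b)) * Inf; p <- 0
    }
  } else {
    tt <- t.test(auc_a, auc_b, var.equal = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(t_stat = t_stat, df = df, p_value = p, alpha = alpha,
                 significant = p < alpha),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test> t = %.3f, df = %d, p = %.3g (%ssignificant at %.2f)\n",
              x$t_stat, x$df, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Fit a probabilistic binary classifier
#'
#' @param features Numeric feature matrix.
#' @param labels Binary 0/1 labels with both classes present.
#' @param kind `"logistic"` (unpenalized logistic regression) or
#'   `"random_forest"` (100-tree probability forest, seeded and
#'   single-threaded for determinism).
#' @param seed Integer seed for the forest.
#' @param num_trees Forest size (default 100).
#' @return A `nodule_classifier`; score new data with [predict_scores()].
#' @export
fit_classifier <- function(features, labels,
                           kind = c("logistic", "random_forest"),
                           seed = 1L, num_trees = 100L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  fit <- if (kind == "logistic") {
    df <- as.data.frame(features)
    names(df) <- paste0("f", seq_len(ncol(df)))
    suppressWarnings(glm(y ~ ., data = cbind(df, y = labels),
                         family = binomial()))
  } else {
    ranger::ranger(x = features, y = factor(labels, levels = c(0L, 1L)),
                   probability = TRUE, num.trees = num_trees,
                   seed = seed, num.threads = 1L)
  }
  structure(list(kind = kind, fit = fit, p = ncol(features)),
            class = "nodule_classifier")
}

#' Class-1 probability scores from a fitted classifier
#'
#' @param object A `nodule_classifier`.
#' @param features Numeric feature matrix with the training column count.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_scores <- function(object, features) {
  stopifnot(inherits(object, "nodule_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != object$p)
    stopf("feature count (%d) differs from training (%d)", ncol(features), object$p)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (object$kind == "logistic") {
    df <- as.data.frame(features)
    names(df) <- paste0("f", seq_len(ncol(df)))
    as.numeric(predict(object$fit, newdata = df, type = "response"))
  } else {
    as.numeric(predict(object$fit, data = features,
                       num.threads = 1L)$predictions[, "1"])
  }
}

new_experiment_result <- function(experiment_id, supervision, model_name,
                                  auc_samples, curves, n_repeats, seed) {
  structure(list(experiment_id = experiment_id, supervision = supervision,
                 model_name = model_name, auc_samples = auc_samples,
                 mean_auc = mean(auc_samples), mean_roc = average_roc(curves),
                 n_repeats = n_repeats, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> exp %d / %s / %s: mean AUC %.4f over %d repeats\n",
              x$experiment_id, x$supervision, x$model_name, x$mean_auc,
              x$n_repeats))
  invisible(x)
}

#' Run one experiment of the repeated-split protocol
#'
#' Per repeat: a fresh 80:20 cohort split under the requested supervision
#' mode ("full": Distribution A on both sides; "semi": Distribution B with
#' KNN pseudo-labeled train-side R3, R3 dropped from the test side), feature
#' preparation per experiment, model fitting, and test-set AUC.
#'
#' Experiments: 1 biomarkers only (logistic regression + random forest);
#' 2 images only (3D CNN direct + CNN features -> random forest); 3 fused
#' image+biomarker features (length 128); 4 fused image+radiomic features
#' (length 127); 5 fused image+biomarker+radiomic features (length 130).
#' Repeat r always uses the same split seed for a given `seed`, whatever the
#' experiment or mode, so comparisons across experiments are paired.
#'
#' @param cohort A `nodule_cohort` (rendered volumes/masks required for
#'   experiments 2-5).
#' @param experiment_id Integer 1-5.
#' @param supervision `"full"` or `"semi"`.
#' @param n_repeats Number of repeated splits; defaults to 1000 for
#'   experiment 1 and 30 for experiments 2-5.
#' @param seed Master seed; repeat r derives its split seed from it.
#' @param k Pseudo-labeling K (semi mode).
#' @param ratio Train fraction.
#' @param cnn_spec Architecture for experiments 2-5 (default
#'   [malignet_spec_small()]).
#' @param cnn_train Training configuration (default 2 epochs at the small
#'   spec's defaults).
#' @param cnn_models Optional list of pre-trained `malignet` models, one per
#'   repeat (as when experiments 3-5 reuse the networks trained in
#'   experiment 2); if `NULL` a network is trained per repeat.
#' @param num_trees Random-forest size.
#' @param keep_models Return the per-repeat CNN models (experiments 2-5).
#' @return List of `experiment_result`, one per model, with attributes
#'   `repeat_seeds` and (optionally) `cnn_models`.
#' @export
run_experiment <- function(cohort, experiment_id,
                           supervision = c("full", "semi"),
                           n_repeats = NULL, seed = 1L, k = 21L, ratio = 0.8,
                           cnn_spec = NULL, cnn_train = NULL,
                           cnn_models = NULL, num_trees = 100L,
                           keep_models = FALSE) {
  supervision <- match.arg(supervision)
  experiment_id <- as.integer(experiment_id)
  if (!experiment_id %in% 1:5) stopf("experiment_id must be in 1..5")
  n_repeats <- as.integer(n_repeats %||% if (experiment_id == 1L) 1000L else 30L)
  needs_images <- experiment_id >= 2L
  if (needs_images && is.null(cohort$volumes))
    stopf("experiment %d needs rendered volumes; generate the cohort with render = TRUE",
          experiment_id)
  if (experiment_id %in% c(4L, 5L) && is.null(cohort$masks))
    stopf("experiment %d needs masks for radiomic features", experiment_id)

  bm_all <- as.matrix(cohort_records(cohort)[, biomarker_names()])
  rad_all <- if (experiment_id %in% c(4L, 5L)) as.matrix(compute_radiomics(cohort)) else NULL
  boxes_all <- if (needs_images) cohort_boxes(cohort) else NULL
  if (needs_images) {
    cnn_spec <- cnn_spec %||% malignet_spec_small()
    cnn_train <- cnn_train %||% malignet_train_config(epochs = 2L)
  }

  model_names <- switch(as.character(experiment_id),
                        "1" = c("logistic", "random_forest"),
                        "2" = c("cnn", "cnn_rf"),
                        c("cnn_rf_fused"))
  aucs <- matrix(NA_real_, n_repeats, length(model_names),
                 dimnames = list(NULL, model_names))
  curves <- lapply(model_names, function(m) vector("list", n_repeats))
  names(curves) <- model_names
  repeat_seeds <- integer(n_repeats)
  models_out <- if (keep_models) vector("list", n_repeats) else NULL

  for (r in seq_len(n_repeats)) {
    rs <- child_seed(seed, r)
    repeat_seeds[r] <- rs
    sp <- supervised_split(cohort, mode = supervision, k = k, ratio = ratio,
                           seed = rs)
    tr <- sp$train; te <- sp$test
    y_tr <- tr$labels; y_te <- te$labels

    if (experiment_id == 1L) {
      x_tr <- bm_all[tr$index, , drop = FALSE]
      x_te <- bm_all[te$index, , drop = FALSE]
      for (m in model_names) {
        kind <- if (m == "logistic") "logistic" else "random_forest"
        fit <- fit_classifier(x_tr, y_tr, kind, seed = child_seed(rs, 7L))
        rc <- roc_auc(predict_scores(fit, x_te), y_te)
        aucs[r, m] <- rc$auc
        curves[[m]][[r]] <- rc
      }
      next
    }

    net <- if (!is.null(cnn_models)) cnn_models[[r]] else {
      mdl <- malignet_build(cnn_spec, seed = child_seed(rs, 11L))
      cfg <- cnn_train
      cfg$seed <- cfg$seed %||% child_seed(rs, 13L)
      malignet_train(mdl, boxes_all[, , , tr$index, drop = FALSE], y_tr, cfg)
    }
    if (keep_models) models_out[[r]] <- net

    if (experiment_id == 2L) {
      sc <- malignet_predict(net, boxes_all[, , , te$index, drop = FALSE])
      rc <- roc_auc(sc, y_te)
      aucs[r, "cnn"] <- rc$auc
      curves[["cnn"]][[r]] <- rc
    }
    f_tr <- malignet_features(net, boxes_all[, , , tr$index, drop = FALSE])
    f_te <- malignet_features(net, boxes_all[, , , te$index, drop = FALSE])
    recipe <- switch(as.character(experiment_id), "2" = "image_only",
                     "3" = "image_biomarker", "4" = "image_radiomic",
                     "5" = "image_both")
    x_tr <- fuse_cohort(f_tr, bm_all[tr$index, , drop = FALSE],
                        if (!is.null(rad_all)) rad_all[tr$index, , drop = FALSE],
                        recipe = recipe)
    x_te <- fuse_cohort(f_te, bm_all[te$index, , drop = FALSE],
                        if (!is.null(rad_all)) rad_all[te$index, , drop = FALSE],
                        recipe = recipe)
    mname <- model_names[length(model_names)]
    fit <- fit_classifier(x_tr, y_tr, "random_forest", seed = child_seed(rs, 7L),
                          num_trees = num_trees)
    rc <- roc_auc(predict_scores(fit, x_te), y_te)
    aucs[r, mname] <- rc$auc
    curves[[mname]][[r]] <- rc
  }

  out <- lapply(model_names, function(m) {
    new_experiment_result(experiment_id, supervision, m, aucs[, m],
                          curves[[m]], n_repeats, seed)
  })
  names(out) <- model_names
  attr(out, "repeat_seeds") <- repeat_seeds
  if (keep_models) attr(out, "cnn_models") <- models_out
  out
}
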