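# Semi-supervised stage: KNN pseudo-labeling of intermediate (R3) nodules in
# biomarker space, and the repeated-split best-K selection procedure.
#
# Biomarkers are used raw (unstandardized) in the Euclidean metric: all eight
# share a ~1-5 ordinal range, and the reference protocol applies no scaling.

#' K-nearest-neighbour classification in biomarker space
#'
#' Majority vote over the `k` Euclidean-nearest training points. `k` must be
#' odd so votes cannot tie. Distance ties at the k-th neighbour are resolved
#' by including the earlier-indexed training record (stable order), which
#' makes the result independent of any RNG.
#'
#' @param train_x Numeric matrix of training feature vectors (rows).
#' @param train_y Binary 0/1 labels, one per training row.
#' @param query_x Numeric matrix of query feature vectors.
#' @param k Odd positive integer, `k <= nrow(train_x)`.
#' @return Integer vector of 0/1 labels, one per query row.
#' @export
knn_classify <- function(train_x, train_y, query_x, k) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  storage.mode(train_x) <- "double"; storage.mode(query_x) <- "double"
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stopf("k must be a positive odd integer, got %s", k)
  if (k > nrow(train_x))
    stopf("k = %d exceeds the number of training points (%d)", k, nrow(train_x))
  if (length(train_y) != nrow(train_x)) stopf("train_y length mismatch")
  train_y <- as.integer(train_y)

  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(query_x, train_x)
  votes <- apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]  # order() is stable: earlier index wins ties
    sum(train_y[nn])
  })
  as.integer(votes * 2L > k)
}

#' Select the best K for KNN pseudo-labeling by repeated validation
#'
#' Repeats `n_runs` times: split Distribution A 80:20, evaluate every odd K
#' in `k_grid` on the validation part, and record the run-best K (highest
#' validation accuracy, smallest K on ties). The final `best_k` is the K
#' most frequently run-best; ties are broken by higher mean validation
#' accuracy, then by smaller K. Runs whose training side ends up
#' single-class are resampled (with a message).
#'
#' @param dist_a A `labeled_dataset` of kind "A" containing both classes.
#' @param k_grid Candidate K values; default the 26 odd values 1..51.
#' @param n_runs Number of repeated splits (default 1000).
#' @param ratio Train fraction per run (default 0.8).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @return A `k_selection` list: `best_k`, `accuracy_table` (n_runs x K
#'   matrix of validation accuracies), `frequency_table` (data.frame with
#'   per-K run-best counts and mean accuracy), `n_runs`.
#' @export
select_best_k <- function(dist_a, k_grid = seq(1L, 51L, by = 2L),
                          n_runs = 1000L, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(dist_a, "labeled_dataset"))
  if (length(unique(dist_a$labels)) < 2L)
    stopf("distribution A must contain both classes")
  k_grid <- as.integer(k_grid)
  if (any(k_grid %% 2L == 0L)) stopf("k_grid must contain odd values only")
  x <- as.matrix(dist_a$records[, biomarker_names()])
  storage.mode(x) <- "double"
  y <- dist_a$labels
  n <- length(y)
  kmax <- max(k_grid)

  acc <- matrix(NA_real_, n_runs, length(k_grid),
                dimnames = list(NULL, paste0("K", k_grid)))
  best <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    attempt <- 0L
    repeat {
      idx <- split_indices(n, ratio, child_seed(seed, r * 131L + attempt))
      if (length(unique(y[idx$train])) == 2L && length(idx$test) >= 1L) break
      attempt <- attempt + 1L
      message(sprintf("run %d: single-class training split, resampling", r))
      if (attempt > 20L) stopf("could not draw a two-class training split")
    }
    xt <- x[idx$train, , drop = FALSE]; yt <- y[idx$train]
    xv <- x[idx$test, , drop = FALSE]; yv <- y[idx$test]
    kk <- min(kmax, nrow(xt))
    d2 <- outer(rowSums(xv^2), rowSums(xt^2), "+") - 2 * tcrossprod(xv, xt)
    # one stable sort per validation point serves every K
    votes <- apply(d2, 1L, function(row) cumsum(yt[order(row)])[seq_len(kk)])
    for (j in seq_along(k_grid)) {
      k <- k_grid[j]
      if (k > kk) next
      pred <- as.integer(votes[k, ] * 2L > k)
      acc[r, j] <- mean(pred == yv)
    }
    best[r] <- k_grid[which.max(acc[r, ])]  # which.max: smallest index on ties
  }

  freq <- vapply(k_grid, function(k) sum(best == k), integer(1))
  mean_acc <- colMeans(acc, na.rm = TRUE)
  # frequency first, then mean accuracy, then smaller K
  ord <- order(-freq, -mean_acc, k_grid)
  best_k <- k_grid[ord[1L]]
  structure(list(
    best_k = best_k,
    accuracy_table = acc,
    frequency_table = data.frame(k = k_grid, frequency = freq,
                                 mean_accuracy = as.numeric(mean_acc)),
    n_runs = n_runs
  ), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> best K = %d over %d runs (%d candidates)\n",
              x$best_k, x$n_runs, nrow(x$frequency_table)))
  invisible(x)
}

#' Build Distribution B (semi-supervised, R123 vs R345)
#'
#' Splits the full cohort 80:20 at record level, pseudo-labels the
#' train-side R3 nodules with [knn_classify()] trained on the train-side
#' R12/R45 biomarkers, and removes R3 from the test side. Pseudo-labeling
#' uses biomarkers only, whatever features downstream models consume.
#'
#' @param cohort A `nodule_cohort` or annotation data.frame.
#' @param k Odd K for the pseudo-labeler (default 21).
#' @param ratio Train fraction (default 0.8).
#' @param seed Integer split seed. The underlying cohort-level split is the
#'   same one [supervised_split()] uses in "full" mode for the same seed, so
#'   the semi-supervised train set is a superset of the fully supervised one.
#' @return A `split_pair` whose train side is a kind-"B" `labeled_dataset`
#'   with `provenance == "pseudo"` for R3 records.
#' @export
build_distribution_b <- function(cohort, k = 21L, ratio = 0.8, seed = 1L) {
  rec <- cohort_records(cohort)
  n <- nrow(rec)
  if (n < 5L) stopf("cohort too small to split (n = %d < 5)", n)
  idx <- split_indices(n, ratio, seed)

  mk_side <- function(ix, side) {
    mal <- rec$malignancy[ix]
    if (side == "test") {
      keep <- ix[mal != 3L]
      return(new_labeled_dataset(rec[keep, , drop = FALSE],
                                 as.integer(rec$malignancy[keep] >= 4L),
                                 rep("original", length(keep)), "B", keep))
    }
    orig <- ix[mal != 3L]
    r3 <- ix[mal == 3L]
    if (length(orig) == 0L || length(unique(rec$malignancy[orig] >= 4L)) < 2L)
      stopf("train side has no labeled R12/R45 nodules of both classes to pseudo-label from")
    y_orig <- as.integer(rec$malignancy[orig] >= 4L)
    bm <- as.matrix(rec[, biomarker_names()])
    labels <- c(y_orig,
                if (length(r3) > 0L) {
                  kk <- min(k, if (length(orig) %% 2L == 0L) length(orig) - 1L else length(orig))
                  knn_classify(bm[orig, , drop = FALSE], y_orig,
                               bm[r3, , drop = FALSE], kk)
                } else integer(0))
    all_ix <- c(orig, r3)
    new_labeled_dataset(rec[all_ix, , drop = FALSE], labels,
                        c(rep("original", length(orig)), rep("pseudo", length(r3))),
                        "B", all_ix)
  }

  structure(list(train = mk_side(idx$train, "train"),
                 test = mk_side(idx$test, "test"),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_pair")
}

#' Split a cohort under a supervision mode
#'
#' "full" builds Distribution A on both sides of a cohort-level 80:20 split
#' (R3 dropped everywhere); "semi" builds Distribution B (train-side R3
#' pseudo-labeled, test-side R3 dropped). Both modes share the same
#' cohort-level split for a given seed, so they are evaluated on identical
#' test sets.
#'
#' @param cohort A `nodule_cohort` or annotation data.frame.
#' @param mode `"full"` or `"semi"`.
#' @param k Pseudo-labeling K (semi mode only).
#' @param ratio Train fraction.
#' @param seed Integer split seed.
#' @return A `split_pair`.
#' @export
supervised_split <- function(cohort, mode = c("full", "semi"), k = 21L,
                             ratio = 0.8, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "semi") return(build_distribution_b(cohort, k, ratio, seed))
  rec <- cohort_records(cohort)
  n <- nrow(rec)
  if (n < 5L) stopf("cohort too small to split (n = %d < 5)", n)
  idx <- split_indices(n, ratio, seed)
  mk_side <- function(ix) {
    keep <- ix[rec$malignancy[ix] != 3L]
    if (length(keep) == 0L) stopf("no R12/R45 records on one split side")
    new_labeled_dataset(rec[keep, , drop = FALSE],
                        as.integer(rec$malignancy[keep] >= 4L),
                        rep("original", length(keep)), "A", keep)
  }
  structure(list(train = mk_side(idx$train), test = mk_side(idx$test),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_pair")
}
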