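# Binary-label dataset construction (Distributions A and B) and seeded
# train/test splitting.
#
# Distribution A (fully supervised): R1/R2 -> label 0, R4/R5 -> label 1,
# intermediate (R3) nodules excluded. Distribution B (semi-supervised):
# train-side R3 nodules receive KNN pseudo-labels in biomarker space; R3 is
# always removed from test sets so both distributions are evaluated on the
# same ground.

new_labeled_dataset <- function(records, labels, provenance, kind, index) {
  stopifnot(length(labels) == nrow(records),
            length(provenance) == nrow(records),
            kind %in% c("A", "B"))
  if (kind == "A" && any(records$malignancy == 3L))
    stopf("distribution A must not contain malignancy-3 records")
  if (kind == "A" && any(provenance == "pseudo"))
    stopf("pseudo-labeled records are only allowed in distribution B")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  structure(list(records = records, labels = as.integer(labels),
                 provenance = provenance, kind = kind,
                 index = as.integer(index)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> distribution %s: %d records (%d benign / %d malignant, %d pseudo)\n",
              x$kind, length(x$labels), sum(x$labels == 0L), sum(x$labels == 1L),
              sum(x$provenance == "pseudo")))
  invisible(x)
}

cohort_records <- function(cohort) {
  if (inherits(cohort, "nodule_cohort")) cohort$biomarkers
  else if (is.data.frame(cohort)) cohort
  else stopf("expected a nodule_cohort or a data.frame of annotations")
}

#' Build Distribution A (fully supervised, R12 vs R45)
#'
#' Groups R1/R2 nodules as class 0 ("Benign") and R4/R5 as class 1
#' ("Malignant"); intermediate (R3) nodules are excluded.
#'
#' @param cohort A `nodule_cohort` or annotation data.frame with a
#'   `malignancy` column in 1..5.
#' @return A `labeled_dataset` of kind "A". The `index` field maps records
#'   back to cohort rows.
#' @export
build_distribution_a <- function(cohort) {
  rec <- cohort_records(cohort)
  if (!all(rec$malignancy %in% 1:5)) stopf("malignancy scores must be in 1..5")
  keep <- which(rec$malignancy != 3L)
  if (length(keep) == 0L)
    stopf("no records remain after excluding intermediate (R3) nodules")
  labels <- as.integer(rec$malignancy[keep] >= 4L)
  new_labeled_dataset(rec[keep, , drop = FALSE], labels,
                      rep("original", length(keep)), "A", keep)
}

# deterministic index split used everywhere; train gets round(ratio * n)
split_indices <- function(n, ratio, seed, strata = NULL) {
  if (ratio <= 0 || ratio >= 1) stopf("split ratio must lie in (0, 1)")
  with_seed(seed, {
    if (is.null(strata)) {
      n_train <- round(ratio * n)
      train <- sort(sample.int(n, n_train))
    } else {
      train <- sort(unlist(lapply(split(seq_len(n), strata), function(ix) {
        sample(ix, round(ratio * length(ix)))
      }), use.names = FALSE))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Split a labeled dataset into train and test parts
#'
#' Record-level uniform 80:20 split by default. Optionally stratified by
#' class, or grouped by patient so no patient spans both sides (a stricter
#' protocol than record-level splitting; off by default).
#'
#' @param dataset A `labeled_dataset`.
#' @param ratio Train fraction in (0, 1); default 0.8.
#' @param seed Integer seed; identical seeds give identical membership.
#' @param stratify Stratify the split by the binary label.
#' @param by_patient Keep each patient's records on one side of the split.
#' @return A `split_pair`: list with `train`, `test` (both `labeled_dataset`),
#'   `ratio`, `seed`.
#' @export
split_dataset <- function(dataset, ratio = 0.8, seed = 1L,
                          stratify = FALSE, by_patient = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$labels)
  if (n < 5L) stopf("dataset too small to split (n = %d < 5)", n)
  if (by_patient) {
    pats <- unique(dataset$records$patient_id)
    ps <- split_indices(length(pats), ratio, seed)
    tr <- which(dataset$records$patient_id %in% pats[ps$train])
    te <- setdiff(seq_len(n), tr)
    idx <- list(train = tr, test = te)
  } else {
    strata <- if (stratify) dataset$labels else NULL
    idx <- split_indices(n, ratio, seed, strata)
  }
  take <- function(ix) new_labeled_dataset(
    dataset$records[ix, , drop = FALSE], dataset$labels[ix],
    dataset$provenance[ix], dataset$kind, dataset$index[ix])
  structure(list(train = take(idx$train), test = take(idx$test),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("<split_pair> distribution %s: train %d / test %d (ratio %.2f, seed %d)\n",
              x$train$kind, length(x$train$labels), length(x$test$labels),
              x$ratio, x$seed))
  invisible(x)
}
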