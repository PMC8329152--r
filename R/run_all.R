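# End-to-end experiment grid runner: configuration, execution, persistence
# of per-iteration artifacts, the summary table, and deterministic replay
# from a run manifest.

#' Configuration for a full experiment run
#'
#' All protocol constants (box 32x32x16, K = 21, alpha = 0.05, the 80:20
#' ratio, per-experiment repeat counts, tiling counts) live here with their
#' reference defaults.
#'
#' @param cohort A `nodule_cohort`, or `NULL` to generate one from
#'   `synth`.
#' @param synth A [generator_config()] used when `cohort` is `NULL`.
#' @param experiments Subset of 1:5.
#' @param modes Subset of `c("full", "semi")`.
#' @param n_repeats Named or unnamed overrides of the per-experiment repeat
#'   counts; a single value applies to all requested experiments. Defaults:
#'   1000 for experiment 1, 30 for experiments 2-5.
#' @param k Pseudo-labeling K (default 21); set `select_k = TRUE` to
#'   re-derive it with [select_best_k()] before running.
#' @param select_k Re-derive K from the cohort's Distribution A.
#' @param select_k_runs Repeated splits for the K scan (default 1000).
#' @param ratio Train fraction.
#' @param alpha Significance level for the pairwise t tests.
#' @param cnn_spec,cnn_train CNN architecture/training configuration for
#'   experiments 2-5 (defaults: [malignet_spec_small()], 2 epochs).
#' @param num_trees Random-forest size.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param save_models Persist per-iteration CNN checkpoints and split seeds.
#' @param seed Global seed; fixes the whole run.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = NULL, synth = generator_config(300L),
                       experiments = 1:5, modes = c("full", "semi"),
                       n_repeats = NULL, k = 21L, select_k = FALSE,
                       select_k_runs = 1000L, ratio = 0.8, alpha = 0.05,
                       cnn_spec = malignet_spec_small(),
                       cnn_train = malignet_train_config(epochs = 2L),
                       num_trees = 100L, out_dir = NULL,
                       save_models = FALSE, seed = 1L) {
  experiments <- sort(unique(as.integer(experiments)))
  if (length(experiments) == 0L || !all(experiments %in% 1:5))
    stopf("experiments must be a non-empty subset of 1..5")
  modes <- match.arg(modes, c("full", "semi"), several.ok = TRUE)
  structure(list(cohort = cohort, synth = synth, experiments = experiments,
                 modes = modes, n_repeats = n_repeats, k = as.integer(k),
                 select_k = isTRUE(select_k),
                 select_k_runs = as.integer(select_k_runs),
                 ratio = ratio, alpha = alpha, cnn_spec = cnn_spec,
                 cnn_train = cnn_train, num_trees = as.integer(num_trees),
                 out_dir = out_dir, save_models = isTRUE(save_models),
                 seed = as.integer(seed)),
            class = "run_config")
}

repeats_for <- function(config, exp_id) {
  nr <- config$n_repeats
  if (is.null(nr)) return(if (exp_id == 1L) 1000L else 30L)
  if (!is.null(names(nr)) && as.character(exp_id) %in% names(nr))
    return(as.integer(nr[[as.character(exp_id)]]))
  as.integer(nr[[1L]])
}

#' Run the full experiment grid
#'
#' Executes every requested (experiment, supervision mode) cell. Experiments
#' 2-5 within a mode share the per-repeat CNNs trained for the
#' lowest-numbered image experiment (identical split seeds make this exact
#' reuse, mirroring the protocol of loading the saved iteration models).
#' Writes, under `out_dir`: `summary.csv` (experiment x model x supervision
#' -> mean AUC), `auc_samples.csv` (per-repeat AUCs), `roc_curves.csv`
#' (averaged ROC per cell), `ttests.csv` (pairwise comparisons), and
#' `manifest.json` (full configuration + seed) from which [run_all()] can
#' replay the run byte-identically.
#'
#' @param config A [run_config()]; ignored when `manifest` is given.
#' @param manifest Path to a `manifest.json` from a previous run; the run is
#'   reproduced from it.
#' @return Invisibly, a `run_bundle`: list with `results` (list of
#'   `experiment_result`), `summary`, `ttests`, `k`, `config`.
#' @export
run_all <- function(config = run_config(), manifest = NULL) {
  if (!is.null(manifest)) config <- config_from_manifest(manifest)
  stopifnot(inherits(config, "run_config"))

  cohort <- config$cohort %||% generate_cohort(config$synth)
  needs_images <- any(config$experiments >= 2L)
  if (needs_images && is.null(cohort$volumes))
    stopf("experiments %s need rendered volumes",
          paste(config$experiments[config$experiments >= 2L], collapse = ","))

  k <- config$k
  k_sel <- NULL
  if (config$select_k) {
    k_sel <- select_best_k(build_distribution_a(cohort),
                           n_runs = config$select_k_runs,
                           ratio = config$ratio,
                           seed = child_seed(config$seed, 997L))
    k <- k_sel$best_k
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (mode in config$modes) {
    cnn_models <- NULL
    for (exp_id in config$experiments) {
      nrep <- repeats_for(config, exp_id)
      res <- run_experiment(cohort, exp_id, supervision = mode,
                            n_repeats = nrep, seed = config$seed, k = k,
                            ratio = config$ratio, cnn_spec = config$cnn_spec,
                            cnn_train = config$cnn_train,
                            cnn_models = if (!is.null(cnn_models) &&
                                             length(cnn_models) == nrep) cnn_models,
                            num_trees = config$num_trees,
                            keep_models = exp_id >= 2L && is.null(cnn_models))
      if (exp_id >= 2L && is.null(cnn_models))
        cnn_models <- attr(res, "cnn_models")
      for (r in res) {
        results[[sprintf("exp%d_%s_%s", exp_id, mode, r$model_name)]] <- r
      }
      if (!is.null(out_dir) && config$save_models && exp_id >= 2L &&
          !is.null(attr(res, "cnn_models"))) {
        mdir <- file.path(out_dir, sprintf("models_exp%d_%s", exp_id, mode))
        dir.create(mdir, showWarnings = FALSE)
        for (i in seq_along(attr(res, "cnn_models")))
          malignet_save(attr(res, "cnn_models")[[i]],
                        file.path(mdir, sprintf("iter%03d.rds", i)))
      }
    }
  }

  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(experiment = r$experiment_id, model = r$model_name,
               supervision = r$supervision, n_repeats = r$n_repeats,
               mean_auc = r$mean_auc, stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  summary_df <- summary_df[order(summary_df$experiment, summary_df$model,
                                 summary_df$supervision), , drop = FALSE]

  ttests <- run_ttests(results, config$alpha)

  if (!is.null(out_dir)) {
    sf <- summary_df
    sf$mean_auc <- sprintf("%.6f", sf$mean_auc)
    write.csv(sf, file.path(out_dir, "summary.csv"), row.names = FALSE)

    samples <- do.call(rbind, lapply(results, function(r) {
      data.frame(experiment = r$experiment_id, model = r$model_name,
                 supervision = r$supervision,
                 repeat_index = seq_along(r$auc_samples),
                 auc = sprintf("%.6f", r$auc_samples),
                 stringsAsFactors = FALSE)
    }))
    rownames(samples) <- NULL
    write.csv(samples, file.path(out_dir, "auc_samples.csv"), row.names = FALSE)

    rocs <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      data.frame(cell = nm, fpr = r$mean_roc$fpr,
                 tpr = sprintf("%.6f", r$mean_roc$tpr),
                 stringsAsFactors = FALSE)
    }))
    write.csv(rocs, file.path(out_dir, "roc_curves.csv"), row.names = FALSE)
    if (!is.null(ttests)) {
      tf <- ttests
      tf$p_value <- sprintf("%.6g", tf$p_value)
      write.csv(tf, file.path(out_dir, "ttests.csv"), row.names = FALSE)
    }
    write_manifest(config, file.path(out_dir, "manifest.json"))
  }

  invisible(structure(list(results = results, summary = summary_df,
                           ttests = ttests, k = k, k_selection = k_sel,
                           config = config),
                      class = "run_bundle"))
}

# pairwise two-tailed Student's t tests: full-vs-semi per (experiment,
# model), and model-vs-model within (experiment, mode)
run_ttests <- function(results, alpha) {
  if (length(results) < 2L) return(NULL)
  info <- data.frame(name = names(results),
                     exp = vapply(results, function(r) r$experiment_id, 0L),
                     model = vapply(results, function(r) r$model_name, ""),
                     mode = vapply(results, function(r) r$supervision, ""),
                     stringsAsFactors = FALSE)
  rows <- list()
  add <- function(a, b, what) {
    tt <- t_test_auc(results[[a]]$auc_samples, results[[b]]$auc_samples, alpha)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = what, a = a, b = b,
      mean_a = results[[a]]$mean_auc, mean_b = results[[b]]$mean_auc,
      t_stat = tt$t_stat, p_value = tt$p_value,
      significant = tt$significant, stringsAsFactors = FALSE)
  }
  for (e in unique(info$exp)) {
    for (m in unique(info$model[info$exp == e])) {
      sel <- info$name[info$exp == e & info$model == m]
      if (length(sel) == 2L) add(sel[1], sel[2], "full_vs_semi")
    }
    for (md in unique(info$mode[info$exp == e])) {
      sel <- info$name[info$exp == e & info$mode == md]
      if (length(sel) == 2L) add(sel[1], sel[2], "model_vs_model")
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

write_manifest <- function(config, path) {
  m <- list(
    package_version = as.character(utils::packageVersion("nodulefuse")),
    seed = config$seed,
    experiments = config$experiments,
    modes = config$modes,
    n_repeats = config$n_repeats,
    k = config$k, select_k = config$select_k,
    select_k_runs = config$select_k_runs,
    ratio = config$ratio, alpha = config$alpha,
    num_trees = config$num_trees,
    save_models = config$save_models,
    cnn_spec = list(conv_blocks = config$cnn_spec$conv_blocks,
                    dense = config$cnn_spec$dense,
                    input_shape = config$cnn_spec$input_shape,
                    l2 = config$cnn_spec$l2),
    cnn_train = unclass(config$cnn_train),
    synth = if (is.null(config$cohort)) unclass(config$synth)
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$synth))
    stopf("manifest has no synthetic cohort parameters; supply the cohort explicitly")
  synth <- do.call(generator_config,
                   m$synth[c("n_nodules", "r3_fraction", "class_balance",
                             "biomarker_effect", "noise_sd", "driver_noise",
                             "size_jitter", "volume_shape", "spacing_mm",
                             "render", "seed")])
  cb <- m$cnn_spec$conv_blocks
  if (is.matrix(cb)) cb <- lapply(seq_len(nrow(cb)), function(i) cb[i, ])
  m$cnn_spec$conv_blocks <- lapply(cb, as.integer)
  spec <- malignet_spec(conv_blocks = m$cnn_spec$conv_blocks,
                        dense = m$cnn_spec$dense,
                        input_shape = m$cnn_spec$input_shape,
                        l2 = m$cnn_spec$l2)
  tc <- m$cnn_train
  train <- malignet_train_config(epochs = tc$epochs, batch_size = tc$batch_size,
                                 learning_rate = tc$learning_rate,
                                 beta1 = tc$beta1, beta2 = tc$beta2,
                                 eps = tc$eps, seed = tc$seed,
                                 verbose = isTRUE(tc$verbose))
  run_config(cohort = NULL, synth = synth, experiments = m$experiments,
             modes = m$modes, n_repeats = m$n_repeats, k = m$k,
             select_k = isTRUE(m$select_k), select_k_runs = m$select_k_runs,
             ratio = m$ratio, alpha = m$alpha, cnn_spec = spec,
             cnn_train = train, num_trees = m$num_trees,
             out_dir = NULL, save_models = isTRUE(m$save_models), seed = m$seed)
}

#' Plot averaged ROC curves
#'
#' @param results List of `experiment_result` (e.g. `bundle$results`).
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @return Invisibly, `NULL`.
#' @export
plot_mean_roc <- function(results, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 720)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "Averaged ROC curves")
  cols <- grDevices::hcl.colors(max(2L, length(results)), "Dark 3")
  for (i in seq_along(results)) {
    r <- results[[i]]
    graphics::lines(r$mean_roc$fpr, r$mean_roc$tpr, col = cols[i],
                    lty = if (r$supervision == "full") 2 else 1, lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = sprintf("exp%d %s %s (AUC %.3f)",
                                    vapply(results, function(r) r$experiment_id, 0L),
                                    vapply(results, function(r) r$model_name, ""),
                                    vapply(results, function(r) r$supervision, ""),
                                    vapply(results, function(r) r$mean_roc$auc, 0)),
                   col = cols[seq_along(results)], lwd = 2, cex = 0.8)
  invisible(NULL)
}

#' Plot per-repeat AUC distributions
#'
#' @param results List of `experiment_result`.
#' @param file Optional PNG path.
#' @return Invisibly, `NULL`.
#' @export
plot_auc_distributions <- function(results, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  samples <- lapply(results, function(r) r$auc_samples)
  names(samples) <- sprintf("e%d %s\n%s",
                            vapply(results, function(r) r$experiment_id, 0L),
                            vapply(results, function(r) r$model_name, ""),
                            vapply(results, function(r) r$supervision, ""))
  graphics::boxplot(samples, ylab = "test AUC", las = 2, cex.axis = 0.8,
                    main = "AUC distributions over repeated splits")
  invisible(NULL)
}
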