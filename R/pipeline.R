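# End-to-end pipeline orchestration and the command-line entry point.

#' Default demo-scale run configuration
#'
#' A desk-scale stated world: 200 subjects on a 24 x 28 x 24 grid, a
#' Cohen's d = 1.2 mean-shift in one gray-matter ROI plus a 1.5-voxel
#' texture-complexity effect in one white-matter ROI, 10 training epochs.
#'
#' @param seed Global seed.
#' @param out Output directory.
#' @return Nested configuration list (serializable to YAML).
#' @export
default_config <- function(seed = 1L, out = "dticnn_run") {
  list(
    seed = as.integer(seed),
    out = out,
    cohort = list(n_subjects = 200L, group_fraction = 0.5,
                  volume_shape = c(24L, 28L, 24L), n_gray = 6L, n_white = 4L,
                  noise_sd = 0.1, subject_sd = 0.02,
                  base_fa = list(gray = 0.25, white = 0.55),
                  effects = list(
                    list(kind = "mean_shift", target_roi_ids = 2L,
                         magnitude = 1.2, direction = 1),
                    list(kind = "texture_complexity", target_roi_ids = 9L,
                         magnitude = 1.5, direction = 1))),
    prep = list(target_shape = c(24L, 28L, 24L), order = 3L),
    model = list(batch_size = 45L, learning_rate = 0.001, epochs = 10L,
                 init_sd = 0.1),
    features = list(alpha = 0.05),
    roi = list(k = 5L, epochs = 3L),
    stages = c("simulate", "prepare", "evaluate", "features", "roi"))
}

# Validate a config list and materialize the per-module objects. Errors here
# fire before any computation (fail-fast contract).
validate_config <- function(config) {
  need <- c("seed", "out", "cohort", "prep", "model")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  ch <- config$cohort
  effects <- lapply(ch$effects %||% list(), function(e)
    group_effect(e$kind, as.integer(unlist(e$target_roi_ids)),
                 e$magnitude, e$direction %||% 1))
  spec <- cohort_spec(
    n_subjects = ch$n_subjects, group_fraction = ch$group_fraction %||% 0.5,
    volume_shape = unlist(ch$volume_shape), effects = effects,
    noise_sd = ch$noise_sd %||% 0.1, seed = derive_seed(config$seed, "simulate"),
    n_gray = ch$n_gray %||% 6L, n_white = ch$n_white %||% 4L,
    base_fa = unlist(ch$base_fa %||% list(gray = 0.25, white = 0.55)),
    subject_sd = ch$subject_sd %||% 0.02)
  m <- config$model
  tcfg <- training_config(
    batch_size = m$batch_size %||% 45L,
    learning_rate = m$learning_rate %||% 0.001,
    epochs = m$epochs %||% 50L, init_sd = m$init_sd %||% 0.1,
    seed = derive_seed(config$seed, "train"))
  target_shape <- as.integer(unlist(config$prep$target_shape))
  if (length(target_shape) != 3 || any(target_shape < 8))
    stop("prep$target_shape must be a triple with all dimensions >= 8")
  list(spec = spec, tcfg = tcfg, target_shape = target_shape,
       order = config$prep$order %||% 3L,
       alpha = (config$features %||% list())$alpha %||% 0.05,
       roi_k = (config$roi %||% list())$k %||% 5L,
       roi_epochs = (config$roi %||% list())$epochs %||% 3L,
       stages = config$stages %||% c("simulate", "prepare", "evaluate",
                                     "features", "roi"))
}

.log <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full pipeline
#'
#' simulate -> prepare -> nested CV (CNN and SVM) -> first-layer feature
#' analysis -> per-ROI discriminability map, with per-stage seeds derived
#' deterministically from the global seed, a run log, and a machine-readable
#' `results.json` summary. Identical config + seed gives identical results.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @return Summary list (also written to `<out>/results.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  v <- validate_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  t0 <- Sys.time()
  .log(logfile, "run start; seed=", config$seed, " config_hash=", cfg_hash)
  summary <- list(seed = config$seed, config_hash = cfg_hash)

  .log(logfile, "[simulate] seed=", v$spec$seed)
  cohort <- generate_cohort(v$spec, file.path(out, "cohort"))
  summary$manifest <- cohort$manifest_path
  summary$atlas <- cohort$atlas_path

  store <- file.path(out, "store.h5")
  if ("prepare" %in% v$stages) {
    .log(logfile, "[prepare] target_shape=", paste(v$target_shape, collapse = "x"))
    build_record_store(cohort$manifest_path, v$target_shape, store, v$order)
    summary$store <- store
  }
  data <- prepare_cohort(cohort, v$target_shape, v$order)
  plan <- make_fold_plan(data$subject_ids, derive_seed(config$seed, "folds"))
  jsonlite::write_json(unclass(plan), file.path(out, "fold_plan.json"),
                       auto_unbox = TRUE)

  best_model <- NULL
  if ("evaluate" %in% v$stages) {
    .log(logfile, "[evaluate] CNN nested CV, epochs=", v$tcfg$epochs)
    cv <- run_nested_cv(data, v$tcfg, plan)
    best_model <- cv$model
    .log(logfile, "[evaluate] SVM baseline")
    sv <- svm_baseline(data, plan, seed = derive_seed(config$seed, "svm"))
    res <- data.frame(fold = rep(1:10, 2),
                      model = rep(c("cnn3d", "svm"), each = 10),
                      accuracy = c(cv$fold_accuracies, sv$fold_accuracies))
    write.table(res, file.path(out, "cv_results.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    summary$cnn_mean_accuracy <- cv$mean_accuracy
    summary$cnn_sd_accuracy <- cv$sd_accuracy
    summary$svm_mean_accuracy <- sv$mean_accuracy
    if (!is.null(best_model)) {
      save_model(best_model, file.path(out, "best_model.h5"))
      summary$model <- file.path(out, "best_model.h5")
    }
    .log(logfile, sprintf("[evaluate] CNN %.3f  SVM %.3f",
                          cv$mean_accuracy, sv$mean_accuracy))
  }

  if ("features" %in% v$stages && !is.null(best_model)) {
    .log(logfile, "[features] first-layer statistics")
    ft <- feature_group_analysis(best_model, data, v$alpha)
    write.table(ft, file.path(out, "feature_stats.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    summary$n_sig_mean <- sum(ft$sig_mean)
    summary$n_sig_entropy <- sum(ft$sig_H)
    summary$entropy_direction_A_larger <- mean(ft$H_A > ft$H_B)
  }

  if ("roi" %in% v$stages) {
    .log(logfile, "[roi] per-ROI classification, epochs=", v$roi_epochs)
    rcfg <- v$tcfg
    rcfg$epochs <- as.integer(v$roi_epochs)
    results <- lapply(cohort$atlas$roi_table$roi_id, function(id)
      per_roi_accuracy(data, cohort$atlas, id, rcfg, plan))
    ranking <- rank_rois(results, v$roi_k)
    write.table(ranking, file.path(out, "roi_ranking.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    amap <- build_accuracy_map(cohort$atlas, results)
    write_nifti(amap, file.path(out, "accuracy_map.nii.gz"))
    summary$roi_ranking <- ranking
    summary$accuracy_map <- file.path(out, "accuracy_map.nii.gz")
  }

  summary$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(logfile, sprintf("run complete in %.1fs", summary$wall_time_s))
  invisible(summary)
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1])) {
        flags[[key]] <- args[i + 1]; i <- i + 2
      } else { flags[[key]] <- TRUE; i <- i + 1 }
    } else i <- i + 1
  }
  flags
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `prepare`, `train`, `evaluate`,
#' `analyze-features`, `roi-map`, `run-all`. Invoke via
#' `Rscript -e 'dticnn::dticnn_cli()' <subcommand> --config ... --out ...`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status 0 on success, invisibly.
#' @export
dticnn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: dticnn_cli <simulate|prepare|train|evaluate|analyze-features|roi-map|run-all> [--config f] [--seed n] [--out p] ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  fl <- .parse_flags(args[-1])
  read_cfg <- function() {
    cfg <- if (!is.null(fl$config)) yaml::read_yaml(fl$config) else default_config()
    if (!is.null(fl$seed)) cfg$seed <- as.integer(fl$seed)
    if (!is.null(fl$out)) cfg$out <- fl$out
    cfg
  }
  switch(cmd,
    simulate = {
      cfg <- read_cfg()
      v <- validate_config(cfg)
      generate_cohort(v$spec, cfg$out)
      message("cohort written to ", cfg$out)
    },
    prepare = {
      shape <- as.integer(strsplit(fl$shape, ",")[[1]])
      build_record_store(fl$manifest, shape, fl$out)
      message("record store written to ", fl$out)
    },
    train = {
      cfg <- read_cfg()
      v <- validate_config(cfg)
      data <- load_prepared(fl$data)
      n <- length(data$subject_ids)
      ntr <- max(1, floor(0.9 * n))
      tr <- .subset_dataset(data, data$subject_ids[1:ntr])
      va <- .subset_dataset(data, data$subject_ids[(ntr + 1):n])
      fit <- train_cnn3d(build_cnn3d(data$target_shape, v$tcfg), tr, va, v$tcfg)
      save_model(fit$model, fl$out)
      write.table(fit$history, sub("\\.h5$", "_history.csv", fl$out),
                  sep = ",", row.names = FALSE, quote = FALSE)
      message("model written to ", fl$out)
    },
    evaluate = {
      cfg <- read_cfg()
      v <- validate_config(cfg)
      data <- load_prepared(fl$data)
      plan <- make_fold_plan(data$subject_ids, derive_seed(cfg$seed, "folds"))
      res <- if (identical(fl$model, "svm"))
        svm_baseline(data, plan, seed = derive_seed(cfg$seed, "svm"))
      else run_nested_cv(data, v$tcfg, plan)
      message(sprintf("mean accuracy %.4f (sd %.4f)",
                      res$mean_accuracy, res$sd_accuracy))
    },
    `analyze-features` = {
      model <- load_model(fl$model)
      data <- load_prepared(fl$data)
      ft <- feature_group_analysis(model, data)
      write.table(ft, fl$out, sep = ",", row.names = FALSE, quote = FALSE)
      message("feature table written to ", fl$out)
    },
    `roi-map` = {
      cfg <- read_cfg()
      run_pipeline(within_list(cfg, stages = c("simulate", "prepare", "roi")))
    },
    `run-all` = {
      run_pipeline(read_cfg())
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

within_list <- function(x, ...) {
  mods <- list(...)
  for (k in names(mods)) x[[k]] <- mods[[k]]
  x
}
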