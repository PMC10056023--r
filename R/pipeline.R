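#' Pipeline configuration
#'
#' Bundles every stage's parameters: cohort generation, preprocessing,
#' windowing, model architecture, training, and output paths. One global
#' seed deterministically derives every stage seed. Fully serialisable to
#' YAML; a run writes its exact config next to its outputs.
#'
#' @param cohort List of [generate_cohort()] arguments (without `seed`).
#' @param preprocess List: `smooth_window`, `knot_stride`, `filter`
#'   (list of [design_butterworth()] arguments).
#' @param window_s Window length (s).
#' @param spec A [model_spec()].
#' @param train A [train_config()] (its `rng_seed` is overridden by the
#'   derived stage seed).
#' @param kinds Neural model kinds to train.
#' @param classical Classical baselines to fit (`"svm"`, `"knn"`).
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(n_per_class = 3, sessions = 2,
                                          duration_s = 120, fs = 100),
                            preprocess = list(smooth_window = 5L,
                                              knot_stride = 2L,
                                              filter = list(N = 2, cutoff = 0.6,
                                                            band_mode = "highpass")),
                            window_s = 10,
                            spec = model_spec(),
                            train = train_config(),
                            kinds = "lstm_attention",
                            classical = c("svm", "knn"),
                            seed = 1L) {
  if (!is.null(cohort$n_per_class) && cohort$n_per_class < 1)
    stop("pipeline_config: cohort must have at least one subject per class")
  structure(list(cohort = cohort, preprocess = preprocess,
                 window_s = window_s, spec = spec, train = train,
                 kinds = kinds, classical = classical,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stage seeds derived from the global seed, fixed offsets
stage_seed <- function(seed, stage) {
  offs <- c(cohort = 101L, split = 211L, train = 307L, reliability = 401L)
  (seed * 7919L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full screening pipeline
#'
#' Generates the synthetic cohort, preprocesses it, builds window and
#' feature datasets, trains the configured classifiers, and evaluates the
#' test, robustness (raw windows) and reliability (two-subject holdout)
#' protocols. All outputs — cohort manifest, feature table, discard log,
#' training history, evaluation reports and the config itself — are
#' written under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the datasets, models and reports.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ppgscreen_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg, t0) {
    message(sprintf("[%s] seed %d  %.1fs  %s", stage, config$seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }

  t0 <- Sys.time()
  co_args <- config$cohort
  co_args$seed <- stage_seed(config$seed, "cohort")
  cohort <- do.call(generate_cohort, co_args)
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_line("simulate", sprintf("%d records", length(cohort$records)), t0)

  fspec_args <- config$preprocess$filter
  fspec_args$fs <- cohort$params$fs
  fspec <- do.call(design_butterworth, fspec_args)
  ds <- tryCatch(
    build_window_dataset_pp(cohort, config$window_s, fspec,
                            config$preprocess$smooth_window,
                            config$preprocess$knot_stride),
    error = function(e) stop("preprocess stage failed: ", conditionMessage(e)))
  ds_raw <- build_window_dataset(cohort, config$window_s, preprocess = FALSE)
  log_line("preprocess", sprintf("%d windows", nrow(ds$X)), t0)

  ft <- build_feature_table(cohort, config$window_s)
  utils::write.csv(ft$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(ft$discards, file.path(out_dir, "discards.csv"),
                   row.names = FALSE)
  log_line("features", sprintf("%d kept, %d discarded",
                               NROW(ft$features), nrow(ft$discards)), t0)

  split <- split_dataset(ds, config$train$fractions,
                         seed = stage_seed(config$seed, "split"))
  cfg <- config$train
  cfg$rng_seed <- stage_seed(config$seed, "train")

  reports <- list(); models <- list()
  for (kind in config$kinds) {
    tr <- tryCatch(train_model(kind, ds, split, config$spec, cfg),
                   error = function(e) stop("train stage (", kind,
                                            ") failed: ", conditionMessage(e)))
    utils::write.csv(tr$history,
                     file.path(out_dir, paste0("history_", kind, ".csv")),
                     row.names = FALSE)
    Xte <- ds$X[split == "test", , drop = FALSE]
    yte <- ds$label[split == "test"]
    pred <- tr$model$classes[max.col(predict_proba(tr$model, Xte))]
    reports[[paste0(kind, "_test")]] <-
      evaluation_report(pred, yte, protocol = "test")
    reports[[paste0(kind, "_robustness")]] <-
      robustness_protocol(tr$model, ds_raw, split)
    models[[kind]] <- tr$model
    log_line("train", sprintf("%s test acc %.3f", kind,
                              reports[[paste0(kind, "_test")]]$accuracy), t0)
  }

  rel_cfg <- cfg
  rel_cfg$rng_seed <- stage_seed(config$seed, "reliability")
  reports$reliability <- tryCatch(
    reliability_protocol(ds, config$spec, rel_cfg, kind = config$kinds[1L]),
    error = function(e) stop("evaluate stage (reliability) failed: ",
                             conditionMessage(e)))
  log_line("evaluate", sprintf("reliability acc %.3f",
                               reports$reliability$accuracy), t0)

  if (length(config$classical) && NROW(ft$features) > 0 &&
      length(unique(ft$features$label)) == 2L) {
    fsplit <- split_windows_like(ft$features, config$train$fractions,
                                 stage_seed(config$seed, "split"))
    for (kind in config$classical) {
      fit <- fit_classical(ft$features[fsplit == "train", , drop = FALSE],
                           kind)
      pred <- predict(fit, ft$features[fsplit == "test", , drop = FALSE])
      reports[[paste0(kind, "_test")]] <- evaluation_report(
        pred, ft$features$label[fsplit == "test"], protocol = "test")
      log_line("evaluate", sprintf("%s test acc %.3f", kind,
               reports[[paste0(kind, "_test")]]$accuracy), t0)
    }
  }

  report_df <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(model = nm, report_to_row(reports[[nm]]))
  }))
  utils::write.csv(report_df, file.path(out_dir, "reports.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_df, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(yaml::as.yaml(config_to_list(config)),
             file.path(out_dir, "config.yaml"))
  invisible(list(cohort = cohort, dataset = ds, raw_dataset = ds_raw,
                 features = ft, split = split, models = models,
                 reports = reports, out_dir = out_dir))
}

# window dataset with explicit preprocessing parameters
build_window_dataset_pp <- function(cohort, window_s, fspec, smooth_window,
                                    knot_stride) {
  rows <- list(); meta <- list()
  for (res in cohort$records) {
    rec <- preprocess_record(res$record, fspec, smooth_window, knot_stride)
    for (w in segment_windows(rec, window_s)) {
      rows[[length(rows) + 1L]] <- w$samples
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = w$subject_id, label = w$label, session = w$session,
        window_index = w$window_index, stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, meta)
  structure(list(X = do.call(rbind, rows), label = md$label,
                 subject_id = md$subject_id, session = md$session,
                 window_index = md$window_index),
            class = "window_dataset")
}

split_windows_like <- function(features, fractions, seed) {
  fake <- structure(list(label = features$label,
                         subject_id = features$subject_id),
                    class = "window_dataset")
  split_dataset(fake, fractions, unit = "window", seed = seed)
}

config_to_list <- function(config) {
  list(cohort = config$cohort, preprocess = config$preprocess,
       window_s = config$window_s, spec = unclass(config$spec),
       train = unclass(config$train), kinds = config$kinds,
       classical = config$classical, seed = config$seed)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (is.null(y$spec)) model_spec() else do.call(model_spec, y$spec)
  train <- if (is.null(y$train)) train_config() else {
    y$train$fractions <- unlist(y$train$fractions)
    do.call(train_config, y$train[setdiff(names(y$train), "verbose")])
  }
  pipeline_config(
    cohort = if (is.null(y$cohort)) list() else y$cohort,
    preprocess = if (is.null(y$preprocess))
      list(smooth_window = 5L, knot_stride = 2L,
           filter = list(N = 2, cutoff = 0.6, band_mode = "highpass"))
      else y$preprocess,
    window_s = if (is.null(y$window_s)) 10 else y$window_s,
    spec = spec, train = train,
    kinds = if (is.null(y$kinds)) "lstm_attention" else unlist(y$kinds),
    classical = if (is.null(y$classical)) c("svm", "knn")
      else unlist(y$classical),
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Write a PPG record to CSV
#'
#' The file carries the record metadata as `# key: value` header lines
#' (fs, subject_id, label, session, processed) followed by
#' `sample_index,value` rows, so a record round-trips losslessly.
#'
#' @param record A `ppg_record`.
#' @param path Output file path.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.10g", record$fs),
               sprintf("# subject_id: %s", record$subject_id),
               sprintf("# label: %s", record$label),
               sprintf("# session: %s", record$session),
               sprintf("# processed: %s", record$processed)), con)
  utils::write.csv(data.frame(sample_index = seq_along(record$samples),
                              value = record$samples),
                   con, row.names = FALSE)
}

#' Read a PPG record written by [write_record()]
#'
#' @param path CSV file path.
#' @return A `ppg_record`.
#' @export
read_record <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) stop("read_record: missing metadata field '", key, "'")
    sub(paste0("^# ", key, ": "), "", m[1L])
  }
  fs <- suppressWarnings(as.numeric(get("fs")))
  if (!is.finite(fs)) stop("read_record: field 'fs' is not numeric")
  body <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  if (!all(c("sample_index", "value") %in% names(body)))
    stop("read_record: missing column 'sample_index' or 'value'")
  new_ppg_record(body$value[order(body$sample_index)], fs,
                 get("subject_id"), get("label"), get("session"),
                 processed = identical(get("processed"), "TRUE"))
}
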