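# Train/predict pipeline runners behind the command-line wrapper. Each stage
# failure is reported with its stage name; every output file carries the
# seed, format version and winning parameters so it can be regenerated.

#' Write ROC points as tab-separated text
#'
#' Columns: threshold, FPR, TPR, one row per distinct threshold.
#'
#' @param roc A `pse_roc` (or a `pse_metrics`/`pse_model`, whose ROC is
#'   taken).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  if (inherits(roc, "pse_model")) roc <- roc$cv_report
  if (inherits(roc, "pse_metrics")) roc <- roc$roc
  stopifnot(inherits(roc, "pse_roc"))
  p <- roc$points
  utils::write.table(
    data.frame(threshold = sprintf("%.10g", p$threshold),
               fpr = sprintf("%.10g", p$fpr),
               tpr = sprintf("%.10g", p$tpr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a ROC curve to PNG
#'
#' @inheritParams write_roc_points
#' @param path Output PNG path.
#' @param title Plot title.
#' @return `path`, invisibly.
#' @export
roc_png <- function(roc, path, title = "ROC curve") {
  if (inherits(roc, "pse_model")) roc <- roc$cv_report
  if (inherits(roc, "pse_metrics")) roc <- roc$roc
  stopifnot(inherits(roc, "pse_roc"))
  grDevices::png(path, width = 720, height = 720, res = 120)
  on.exit(grDevices::dev.off())
  plot(roc, main = title)
  invisible(path)
}

#' Export a feature matrix as tab-separated text
#'
#' Debug output: columns are named after k-mers and pseudo components
#' (`pse.<j>` for parallel, `pse.<j>.<xi>` for series).
#'
#' @param features An [extract_features()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  d <- data.frame(id = rownames(features$x), label = features$y,
                  features$x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stamp_lines <- function(model) {
  p <- model$pse_params; s <- model$svm_params
  c(sprintf("# psepred format_version=%s seed=%d molecule=%s",
            model$format_version, model$seed, model$molecule),
    sprintf("# selected k=%d lambda=%d w=%g mode=%s C=%g gamma=%g objective=%s",
            p$k, p$lambda, p$w, p$mode, s$C, s$gamma, model$objective))
}

write_stamped_tsv <- function(writer, model, path) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writer(tmp)
  writeLines(c(stamp_lines(model), readLines(tmp)), path)
  invisible(path)
}

log_msg <- function(level, ..., log_file = NULL) {
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), paste0(...))
  cat(line, "\n", file = stderr())
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

#' Run the full training pipeline and write its artifacts
#'
#' Executes benchmark loading, grid construction, fold assignment, the CV
#' grid search, the final refit and model serialization, writing the model
#' archive, grid report, CV metric report, ROC points and ROC PNG into
#' `out_dir`. This is the engine behind the `train` subcommand of the
#' bundled CLI script.
#'
#' @param pos,neg Positive/negative FASTA paths.
#' @param molecule Molecule type.
#' @param out_dir Output directory (created if missing).
#' @param grid Optional [build_grid()] override.
#' @param cv Folds (integer or `"jackknife"`).
#' @param seed Master seed.
#' @param n_workers Grid-search workers.
#' @param properties Optional property table (path to TSV or a table
#'   object).
#' @param skip_invalid Drop out-of-alphabet records instead of failing.
#' @return The fitted `pse_model`, invisibly; artifacts on disk.
#' @export
run_train <- function(pos, neg, molecule, out_dir = ".", grid = NULL,
                      cv = 5, seed = 1L, n_workers = 1L, properties = NULL,
                      skip_invalid = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  log_msg("info", "loading benchmark", log_file = log_file)
  dataset <- stage("load_benchmark",
                   load_benchmark(pos, neg, molecule,
                                  skip_invalid = skip_invalid))
  if (is.character(properties))
    properties <- stage("read_property_table",
                        read_property_table(properties, molecule))
  log_msg("info", sprintf("benchmark: %d pos / %d neg",
                          sum(dataset$labels == 1L),
                          sum(dataset$labels == -1L)),
          log_file = log_file)
  model <- stage("train", withCallingHandlers(
    pse_fit(dataset, grid = grid, cv = cv, seed = seed,
            n_workers = n_workers, properties = properties),
    message = function(m) {
      log_msg("warn", sub("\n$", "", conditionMessage(m)),
              log_file = log_file)
      invokeRestart("muffleMessage")
    }))
  save_model(model, file.path(out_dir, "model.psepred"))
  write_stamped_tsv(function(p) write_grid_report(model$grid_result, p),
                    model, file.path(out_dir, "grid_report.tsv"))
  r <- model$cv_report
  write_stamped_tsv(function(p) {
    utils::write.table(
      data.frame(metric = c("TP", "FP", "TN", "FN",
                            "Acc", "MCC", "Sn", "Sp", "AUC"),
                 value = c(r$counts["TP"], r$counts["FP"], r$counts["TN"],
                           r$counts["FN"],
                           sprintf("%.6f", c(r$acc, r$mcc, r$sn, r$sp,
                                             r$auc)))),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, model, file.path(out_dir, "cv_metrics.tsv"))
  write_stamped_tsv(function(p) write_roc_points(r, p), model,
                    file.path(out_dir, "roc_points.tsv"))
  roc_png(r, file.path(out_dir, "roc.png"),
          title = sprintf("Pooled CV ROC (%s, seed %d)", model$molecule,
                          model$seed))
  log_msg("info", "training artifacts written to ", normalizePath(out_dir),
          log_file = log_file)
  invisible(model)
}

#' Run the prediction pipeline and write its artifacts
#'
#' Loads a saved model archive, predicts a query FASTA and writes the
#' predictions table; when a labeled truth benchmark is supplied, also
#' writes an evaluation metric report, ROC points and ROC PNG. The engine
#' behind the `predict` subcommand of the bundled CLI script.
#'
#' @param model_path Archive written by [save_model()].
#' @param query Query FASTA path.
#' @param out_dir Output directory.
#' @param truth_pos,truth_neg Optional labeled FASTA pair; when given, the
#'   query is taken from them instead of `query` and metrics are computed.
#' @param skip_invalid Drop invalid/too-short query records instead of
#'   aborting.
#' @return The predictions data.frame, invisibly; artifacts on disk.
#' @export
run_predict <- function(model_path, query = NULL, out_dir = ".",
                        truth_pos = NULL, truth_neg = NULL,
                        skip_invalid = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_model(model_path)
  truth <- NULL
  if (!is.null(truth_pos) || !is.null(truth_neg)) {
    if (is.null(truth_pos) || is.null(truth_neg))
      stop("truth requires both a positive and a negative FASTA",
           call. = FALSE)
    ds <- load_benchmark(truth_pos, truth_neg, model$molecule,
                         skip_invalid = skip_invalid)
    newdata <- ds$seqs
    truth <- ds$labels
  } else {
    if (is.null(query)) stop("query FASTA required", call. = FALSE)
    newdata <- read_fasta(query, model$molecule,
                          skip_invalid = skip_invalid)
  }
  pred <- predict(model, newdata, type = "table", truth = truth,
                  skip_invalid = skip_invalid)
  write_stamped_tsv(function(p) {
    tab <- pred
    tab$decision_score <- sprintf("%.10g", tab$decision_score)
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, model, file.path(out_dir, "predictions.tsv"))
  m <- attr(pred, "metrics")
  if (!is.null(m)) {
    write_stamped_tsv(function(p) {
      utils::write.table(
        data.frame(metric = c("TP", "FP", "TN", "FN",
                              "Acc", "MCC", "Sn", "Sp", "AUC"),
                   value = c(m$counts["TP"], m$counts["FP"], m$counts["TN"],
                             m$counts["FN"],
                             sprintf("%.6f", c(m$acc, m$mcc, m$sn, m$sp,
                                               m$auc)))),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, model, file.path(out_dir, "eval_metrics.tsv"))
    write_stamped_tsv(function(p) write_roc_points(m, p), model,
                      file.path(out_dir, "eval_roc_points.tsv"))
    roc_png(m, file.path(out_dir, "eval_roc.png"),
            title = sprintf("Query evaluation ROC (%s)", model$molecule))
  }
  invisible(pred)
}
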