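#' Fit a pseudo-component RBF-SVM sequence classifier
#'
#' The full training pipeline: load the two-class benchmark, build the joint
#' parameter grid, assign cross-validation folds once, score every candidate
#' by pooled CV, then refit on the complete benchmark with the winning
#' parameters. The reported metrics remain the winning candidate's CV
#' metrics (the refit is never scored on its own training data).
#'
#' @param x A `pse_dataset` (from [load_benchmark()], [make_dataset()] or
#'   [synth_benchmark()]), or the positive-class FASTA path.
#' @param neg Negative-class FASTA path when `x` is a path.
#' @param molecule Molecule type when `x` is a path.
#' @param grid A [build_grid()] object; defaults to the molecule's default
#'   grid.
#' @param cv Number of CV folds, or `"jackknife"`.
#' @param seed Integer seed governing fold assignment.
#' @param n_workers Parallel workers for the grid search (result invariant).
#' @param properties A property table/index; defaults to
#'   [builtin_properties()] for the molecule. Raw tables are standardized.
#' @return A `pse_model` with `print`, `summary`, `predict` and `plot`
#'   methods.
#' @export
#' @examples
#' bench <- synth_benchmark("DNA", n_per_class = 15, length = 60,
#'                          signal = "motif", insertion_prob = 1, seed = 7)
#' grid <- build_grid("DNA", k = 2, lambda = 2, w = 0.5, C = 1, gamma = 0.25)
#' fit <- pse_fit(bench$dataset, grid = grid, cv = 3, seed = 7)
#' fit
pse_fit <- function(x, neg = NULL, molecule = NULL, grid = NULL, cv = 5,
                    seed = 1L, n_workers = 1L, properties = NULL) {
  dataset <- if (inherits(x, "pse_dataset")) {
    x
  } else if (is.character(x)) {
    if (is.null(neg) || is.null(molecule))
      stop("when x is a FASTA path, neg and molecule are required",
           call. = FALSE)
    load_benchmark(x, neg, molecule)
  } else stop("x must be a pse_dataset or a FASTA path", call. = FALSE)
  molecule <- dataset$molecule
  if (is.null(grid)) grid <- build_grid(molecule)
  if (is.null(properties)) properties <- builtin_properties(molecule)
  if (!inherits(properties, "pse_property_index"))
    properties <- standardize_properties(properties)
  if (!identical(properties$molecule, molecule))
    stop("property table molecule does not match the benchmark",
         call. = FALSE)
  folds <- make_folds(dataset$labels, cv, seed)
  result <- grid_search(dataset, grid, folds, properties,
                        n_workers = n_workers)
  b <- result$table[result$best, ]
  best_pse <- pse_params(b$k, b$lambda, b$w, b$mode)
  best_svm <- svm_params(b$C, b$gamma)
  feats <- extract_features(dataset, best_pse, properties)
  svm <- train_svm(feats$x, feats$y, best_svm)
  structure(list(
    svm = svm,
    svm_params = best_svm,
    pse_params = best_pse,
    properties = properties,
    molecule = molecule,
    cv_report = result$best_report,
    grid_result = result,
    objective = result$objective,
    n_pos = sum(dataset$labels == 1L),
    n_neg = sum(dataset$labels == -1L),
    cv = if (folds$jackknife) "jackknife" else folds$K,
    seed = as.integer(seed),
    format_version = MODEL_FORMAT_VERSION,
    call = match.call()
  ), class = "pse_model")
}

min_length <- function(model) {
  # shortest query admissible under the recipe
  lam <- model$pse_params$lambda
  need_corr <- if (model$molecule == "PROTEIN") lam + 1L else lam + 2L
  max(model$pse_params$k, need_corr,
      if (model$molecule == "PROTEIN") 1L else 2L)
}

#' @export
print.pse_model <- function(x, ...) {
  p <- x$pse_params; s <- x$svm_params
  cat(sprintf("pseudo-component RBF-SVM classifier (%s)\n", x$molecule))
  cat(sprintf("  benchmark: %d positive / %d negative, %s CV, seed %d\n",
              x$n_pos, x$n_neg,
              if (identical(x$cv, "jackknife")) "jackknife"
              else paste0(x$cv, "-fold"), x$seed))
  cat(sprintf("  selected:  k=%d lambda=%d w=%g mode=%s C=%g gamma=%g (by %s)\n",
              p$k, p$lambda, p$w, p$mode, s$C, s$gamma, x$objective))
  r <- x$cv_report
  cat(sprintf("  CV:        Acc=%.4f MCC=%.4f Sn=%.4f Sp=%.4f AUC=%.4f\n",
              r$acc, r$mcc, r$sn, r$sp, r$auc))
  invisible(x)
}

#' @export
summary.pse_model <- function(object, ...) {
  structure(list(model = object), class = "summary.pse_model")
}

#' @export
print.summary.pse_model <- function(x, ...) {
  m <- x$model
  print(m)
  cnt <- m$cv_report$counts
  cat(sprintf("  CV confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cnt["TP"], cnt["FP"], cnt["TN"], cnt["FN"]))
  cat(sprintf("  support vectors: %d; feature dimension: %d\n",
              nrow(m$svm$sv), m$svm$dim))
  tab <- m$grid_result$table
  tab <- tab[tab$evaluated, , drop = FALSE]
  top <- tab[order(-tab[[m$objective]]), , drop = FALSE]
  cat(sprintf("  grid: %d candidates evaluated; top by %s:\n",
              nrow(tab), m$objective))
  print(utils::head(top, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot the cross-validation ROC curve of a fitted model
#'
#' @param x A `pse_model`.
#' @param ... Passed on to [plot.pse_roc()].
#' @export
plot.pse_model <- function(x, ...) {
  plot(x$cv_report$roc,
       main = sprintf("%s classifier, pooled CV ROC", x$molecule), ...)
}

#' Predict query sequences with a fitted model
#'
#' @param object A `pse_model`.
#' @param newdata Query sequences: a `pse_seqs`, a `pse_dataset`, or a FASTA
#'   path.
#' @param type `"table"` (default: data.frame of id, decision score and
#'   predicted label), `"class"` or `"score"`.
#' @param truth Optional +1/-1 vector; when given, a `pse_metrics` report is
#'   attached as attribute `"metrics"` of the result.
#' @param skip_invalid Drop query records too short for the model's recipe
#'   (with a logged count) instead of aborting.
#' @param ... Ignored.
#' @return See `type`.
#' @export
predict.pse_model <- function(object, newdata, type = c("table", "class", "score"),
                              truth = NULL, skip_invalid = FALSE, ...) {
  type <- match.arg(type)
  seqs <- if (inherits(newdata, "pse_dataset")) newdata$seqs
          else if (inherits(newdata, "pse_seqs")) newdata
          else if (is.character(newdata) && length(newdata) == 1L &&
                   file.exists(newdata))
            read_fasta(newdata, object$molecule, skip_invalid = skip_invalid)
          else stop("newdata must be a pse_seqs, pse_dataset or FASTA path",
                    call. = FALSE)
  if (!identical(attr(seqs, "molecule"), object$molecule))
    stop("query molecule type does not match the model", call. = FALSE)
  L <- nchar(unclass(seqs))
  short <- L < min_length(object)
  if (any(short)) {
    if (skip_invalid) {
      message("skipped ", sum(short), " query record(s) shorter than the ",
              "model minimum length ", min_length(object))
      seqs <- new_seqs(unclass(seqs)[!short], names(seqs)[!short],
                       object$molecule)
      if (!is.null(truth)) truth <- truth[!short]
    } else {
      stop("query sequence(s) too short for the model recipe (min L=",
           min_length(object), "): ",
           paste(names(seqs)[short], collapse = ", "), call. = FALSE)
    }
  }
  if (length(seqs) == 0L) stop("no query records to predict", call. = FALSE)
  ds <- new_dataset(seqs, rep(1L, length(seqs)))
  x <- extract_features(ds, object$pse_params, object$properties)$x
  score <- decision_scores(object$svm, x)
  label <- ifelse(score >= 0, 1L, -1L)
  out <- switch(type,
                class = structure(label, names = names(seqs)),
                score = structure(score, names = names(seqs)),
                table = data.frame(id = names(seqs), decision_score = score,
                                   predicted_label = label,
                                   stringsAsFactors = FALSE))
  if (!is.null(truth)) {
    if (length(truth) != length(seqs))
      stop("truth length does not match query count", call. = FALSE)
    attr(out, "metrics") <- metric_report(as.integer(truth), score)
  }
  out
}

# ---- persistence -----------------------------------------------------------

SVM_MARKER <- "---libsvm-model---"

#' Save a fitted model to a versioned single-file archive
#'
#' The archive is a gzip-compressed text file: a JSON metadata document
#' (format version, feature recipe, property index, SVM parameters and the
#' CV training summary) followed by the classifier state in the LIBSVM text
#' model dialect, written at full double precision so that reloading
#' reproduces decision scores bit-identically.
#'
#' @param model A `pse_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pse_model"))
  r <- model$cv_report
  meta <- list(
    format_version = model$format_version,
    molecule = model$molecule,
    pse_params = unclass(model$pse_params),
    svm_params = unclass(model$svm_params),
    property_set = list(
      name = model$properties$name,
      unit = model$properties$unit,
      symbols = rownames(model$properties$values),
      properties = colnames(model$properties$values),
      # %.17g strings: doubles survive the JSON round trip bit-exactly
      values = matrix(fmt_full(model$properties$values),
                      nrow = nrow(model$properties$values))),
    feature_names = model$svm$feature_names,
    training_summary = list(
      objective = model$objective,
      n_pos = model$n_pos, n_neg = model$n_neg,
      cv = model$cv, seed = model$seed,
      counts = as.list(r$counts),
      acc = r$acc, mcc = r$mcc, sn = r$sn, sp = r$sp, auc = r$auc,
      roc = list(threshold = r$roc$points$threshold,
                 fpr = r$roc$points$fpr, tpr = r$roc$points$tpr)))
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(as.character(json), SVM_MARKER, svm_to_text(model$svm)), con)
  invisible(path)
}

#' Load a model archive
#'
#' Refuses archives from an unknown (future) format version and reports
#' missing members by name.
#'
#' @param path Archive path written by [save_model()].
#' @return A `pse_model` whose predictions are bit-identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  at <- match(SVM_MARKER, lines)
  if (is.na(at) || at < 2L)
    stop("corrupt model archive: missing ",
         if (is.na(at)) "SVM member" else "metadata member", call. = FALSE)
  meta <- tryCatch(
    jsonlite::fromJSON(paste(lines[1:(at - 1L)], collapse = "\n"),
                       simplifyVector = TRUE),
    error = function(e) stop("corrupt model archive: unparsable metadata (",
                             conditionMessage(e), ")", call. = FALSE))
  for (member in c("format_version", "molecule", "pse_params", "svm_params",
                   "property_set", "training_summary"))
    if (is.null(meta[[member]]))
      stop("model archive missing member '", member, "'", call. = FALSE)
  if (!identical(meta$format_version, MODEL_FORMAT_VERSION))
    stop("model archive has format_version '", meta$format_version,
         "'; this build reads only '", MODEL_FORMAT_VERSION, "'",
         call. = FALSE)
  ps <- meta$property_set
  vals <- ps$values
  if (is.list(vals)) vals <- do.call(rbind, vals)
  vals <- matrix(as.numeric(vals), nrow = length(ps$symbols),
                 dimnames = list(ps$symbols, ps$properties))
  properties <- new_property_table(vals, meta$molecule, standardized = TRUE,
                                   name = ps$name)
  svm <- svm_from_text(lines[(at + 1L):length(lines)], meta$feature_names)
  svm$C <- meta$svm_params$C
  ts <- meta$training_summary
  roc <- structure(list(points = data.frame(threshold = as.numeric(ts$roc$threshold),
                                            fpr = ts$roc$fpr,
                                            tpr = ts$roc$tpr),
                        auc = ts$auc), class = "pse_roc")
  report <- structure(list(counts = unlist(ts$counts), acc = ts$acc,
                           sn = ts$sn, sp = ts$sp, mcc = ts$mcc,
                           auc = ts$auc, roc = roc, scores = NULL,
                           pred = NULL, truth = NULL),
                      class = "pse_metrics")
  structure(list(
    svm = svm,
    svm_params = svm_params(meta$svm_params$C, meta$svm_params$gamma),
    pse_params = pse_params(meta$pse_params$k, meta$pse_params$lambda,
                            meta$pse_params$w, meta$pse_params$mode),
    properties = properties,
    molecule = meta$molecule,
    cv_report = report,
    grid_result = NULL,
    objective = ts$objective,
    n_pos = ts$n_pos, n_neg = ts$n_neg,
    cv = ts$cv, seed = ts$seed,
    format_version = meta$format_version,
    call = NULL
  ), class = "pse_model")
}
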