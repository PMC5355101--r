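# Joint (k, lambda, w, mode, C, gamma) grid search, scored by pooled
# cross-validation on one shared fold assignment so candidate comparisons
# are paired. Results are independent of the worker count: candidates are
# enumerated in a fixed lexicographic order and collected in that order.

#' Build the joint feature/SVM parameter grid
#'
#' Defaults (used for any unset list): DNA/RNA `k` in \{2, 3\}, protein
#' `k = 1`; `lambda` in 1..5; `w` in \{0.1, 0.3, 0.5, 0.7, 0.9\};
#' `mode = "parallel"`; `C` in \{2^-2, 2^0, 2^2, 2^4, 2^6\}; `gamma` in
#' \{2^-6, 2^-4, 2^-2, 2^0, 2^2\}. Candidates are ordered lexicographically
#' in (k, lambda, w, mode, C, gamma) with each list sorted ascending, which
#' also fixes the tie-break: of equally scoring candidates the simpler
#' (earlier) one wins.
#'
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"` (sets the `k` default).
#' @param k,lambda,w,mode,C,gamma Optional candidate vectors overriding the
#'   defaults.
#' @param objective Selection score: `"acc"` (default), `"auc"` or `"mcc"`.
#' @return A `pse_grid`: data.frame of candidates plus the objective.
#' @export
build_grid <- function(molecule, k = NULL, lambda = NULL, w = NULL,
                       mode = NULL, C = NULL, gamma = NULL,
                       objective = c("acc", "auc", "mcc")) {
  molecule <- match_molecule(molecule)
  objective <- match.arg(objective)
  dflt <- list(
    k = if (molecule == "PROTEIN") 1L else c(2L, 3L),
    lambda = 1:5,
    w = c(0.1, 0.3, 0.5, 0.7, 0.9),
    mode = "parallel",
    C = 2^c(-2, 0, 2, 4, 6),
    gamma = 2^c(-6, -4, -2, 0, 2))
  pick <- function(user, name) {
    if (is.null(user)) return(dflt[[name]])
    if (length(user) == 0L) stop("empty candidate list for ", name,
                                 call. = FALSE)
    user
  }
  k <- sort(unique(as.integer(pick(k, "k"))))
  lambda <- sort(unique(as.integer(pick(lambda, "lambda"))))
  w <- sort(unique(as.numeric(pick(w, "w"))))
  mode <- unique(match.arg(pick(mode, "mode"), c("parallel", "series"),
                           several.ok = TRUE))
  C <- sort(unique(as.numeric(pick(C, "C"))))
  gamma <- sort(unique(as.numeric(pick(gamma, "gamma"))))
  if (any(k < 1L)) stop("k must be >= 1", call. = FALSE)
  if (any(lambda < 0L)) stop("lambda must be >= 0", call. = FALSE)
  if (any(w <= 0)) stop("w must be > 0", call. = FALSE)
  if (any(C <= 0)) stop("C must be > 0", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be > 0", call. = FALSE)
  g <- expand.grid(gamma = gamma, C = C, mode = mode, w = w,
                   lambda = lambda, k = k,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("k", "lambda", "w", "mode", "C", "gamma")]
  rownames(g) <- NULL
  structure(list(candidates = g, objective = objective, molecule = molecule),
            class = "pse_grid")
}

#' @export
print.pse_grid <- function(x, ...) {
  cat(sprintf("parameter grid: %d candidates, objective = %s\n",
              nrow(x$candidates), x$objective))
  for (col in c("k", "lambda", "w", "mode", "C", "gamma"))
    cat(sprintf("  %-6s %s\n", col,
                paste(format(unique(x$candidates[[col]]), digits = 6),
                      collapse = " ")))
  invisible(x)
}

candidate_admissible <- function(cand, min_L, molecule) {
  min_L >= cand$k && cand$lambda <= max_lambda(min_L, molecule)
}

score_field <- function(report, objective) {
  switch(objective, acc = report$acc, auc = report$auc, mcc = report$mcc)
}

#' Grid search by shared-fold cross-validation
#'
#' Evaluates every admissible candidate with [cross_validate()] on one fixed
#' fold assignment. Candidates inadmissible for the dataset's shortest
#' sequence (lambda or k too large) are skipped with a logged reason. The
#' winner maximizes the grid objective; ties go to the lexicographically
#' earlier (simpler) candidate. The result is identical for any `n_workers`.
#'
#' @param dataset A `pse_dataset`.
#' @param grid A [build_grid()] object.
#' @param folds A [make_folds()] assignment, reused by every candidate.
#' @param index A standardized property index.
#' @param n_workers Number of parallel worker processes (fork-based).
#' @return A `pse_grid_result`: `table` (one row per candidate with the five
#'   scores), `best` (winning row index), `best_report` (its pooled CV
#'   metrics), `n_evaluated`.
#' @export
grid_search <- function(dataset, grid, folds, index, n_workers = 1L) {
  stopifnot(inherits(grid, "pse_grid"), inherits(dataset, "pse_dataset"))
  if (!identical(grid$molecule, dataset$molecule))
    stop("grid and dataset molecule types differ", call. = FALSE)
  cands <- grid$candidates
  min_L <- min(nchar(unclass(dataset$seqs)))
  adm <- vapply(seq_len(nrow(cands)), function(i)
    candidate_admissible(cands[i, ], min_L, dataset$molecule), logical(1))
  if (!any(adm))
    stop("no admissible candidate for shortest sequence length ", min_L,
         call. = FALSE)
  if (any(!adm))
    message(sum(!adm), " candidate(s) skipped: inadmissible for shortest ",
            "sequence (L=", min_L, ")")
  # candidates sharing (k, lambda, w, mode) reuse one feature matrix
  fkey <- paste(cands$k, cands$lambda, cands$w, cands$mode)
  groups <- split(which(adm), fkey[adm])
  groups <- groups[order(vapply(groups, min, integer(1)))]
  eval_group <- function(rows) {
    c0 <- cands[rows[1], ]
    pp <- pse_params(c0$k, c0$lambda, c0$w, c0$mode)
    feats <- extract_features(dataset, pp, index)
    lapply(rows, function(i) {
      rep <- cross_validate(dataset, pp, svm_params(cands$C[i], cands$gamma[i]),
                            folds, index, features = feats)
      list(row = i, report = rep)
    })
  }
  res <- if (n_workers > 1L) {
    parallel::mclapply(groups, eval_group, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(groups, eval_group)
  }
  res <- unlist(res, recursive = FALSE, use.names = FALSE)
  rows <- vapply(res, `[[`, integer(1), "row")
  res <- res[order(rows)]  # candidate order, independent of scheduling
  tab <- cands
  tab$acc <- tab$mcc <- tab$sn <- tab$sp <- tab$auc <- NA_real_
  tab$evaluated <- FALSE
  reports <- vector("list", nrow(cands))
  for (r in res) {
    i <- r$row
    tab$acc[i] <- r$report$acc; tab$mcc[i] <- r$report$mcc
    tab$sn[i] <- r$report$sn; tab$sp[i] <- r$report$sp
    tab$auc[i] <- r$report$auc
    tab$evaluated[i] <- TRUE
    reports[[i]] <- r$report
  }
  tab <- tab[, c("k", "lambda", "w", "mode", "C", "gamma",
                 "acc", "mcc", "sn", "sp", "auc", "evaluated")]
  obj <- vapply(seq_len(nrow(tab)), function(i)
    if (tab$evaluated[i]) score_field(reports[[i]], grid$objective)
    else -Inf, numeric(1))
  best <- which.max(obj)  # first maximum = lexicographically earliest
  structure(list(table = tab, best = best, best_report = reports[[best]],
                 objective = grid$objective, n_evaluated = sum(tab$evaluated),
                 folds = folds),
            class = "pse_grid_result")
}

#' @export
print.pse_grid_result <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf("grid search: %d/%d candidates evaluated (objective %s)\n",
              x$n_evaluated, nrow(x$table), x$objective))
  cat(sprintf("best: k=%d lambda=%d w=%g mode=%s C=%g gamma=%g  %s=%.4f\n",
              b$k, b$lambda, b$w, b$mode, b$C, b$gamma, x$objective,
              b[[x$objective]]))
  invisible(x)
}

#' Write a grid report as tab-separated text
#'
#' One row per candidate with its parameters and the five CV scores.
#'
#' @param result A `pse_grid_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(result, path) {
  stopifnot(inherits(result, "pse_grid_result"))
  tab <- result$table
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.6g", v))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
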