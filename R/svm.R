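# RBF-kernel SVM over pseudo-component feature matrices. Training is
# delegated to libsvm (via e1071); the fitted state is reduced to support
# vectors, coefficients and the bias, from which this package computes
# decision values itself. That keeps prediction independent of solver object
# internals and makes save/load round trips reproduce scores bit-identically.

MODEL_FORMAT_VERSION <- "1.0"

#' RBF-SVM hyperparameters
#'
#' The kernel is \eqn{K(x,y) = \exp(-\gamma \lVert x-y\rVert^2)}; `C` is the
#' soft-margin cost.
#'
#' @param C Positive cost.
#' @param gamma Positive RBF width.
#' @return An `svm_params` object.
#' @export
svm_params <- function(C = 1, gamma = 0.25) {
  if (!is.finite(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  structure(list(C = as.numeric(C), gamma = as.numeric(gamma)),
            class = "svm_params")
}

#' Train an RBF-kernel SVM
#'
#' Features are used as-is (no internal rescaling: pseudo-component vectors
#' are already jointly normalized to sum 1). Training is deterministic given
#' the matrix, labels and parameters.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels, +1/-1, one per row.
#' @param params An [svm_params()] object.
#' @return A `pse_svm`: support vectors, coefficients and bias, with the sign
#'   convention that a positive decision value predicts class +1.
#' @export
train_svm <- function(x, y, params) {
  stopifnot(inherits(params, "svm_params"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (!all(y %in% c(1L, -1L))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training requires both classes; got a single-class label vector",
         call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  fit <- e1071::svm(x, factor(y, levels = c("-1", "1")), scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    cost = params$C, gamma = params$gamma)
  # libsvm decision values are oriented "first internal label vs second";
  # flip so that positive score always means class +1
  first <- fit$levels[fit$labels[1]]
  flip <- if (identical(first, "1")) 1 else -1
  structure(list(
    sv = unname(as.matrix(fit$SV)),
    coefs = flip * as.numeric(fit$coefs),
    rho = flip * as.numeric(fit$rho),
    gamma = params$gamma,
    C = params$C,
    dim = ncol(x),
    feature_names = colnames(x)
  ), class = "pse_svm")
}

#' SVM decision values
#'
#' Signed decision values \eqn{f(x) = \sum_i \alpha_i K(s_i, x) - \rho};
#' positive predicts class +1. Used as the ROC ranking statistic.
#'
#' @param model A `pse_svm` (or a fitted [pse_fit()] model).
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric score vector, one per row of `x`.
#' @export
decision_scores <- function(model, x) {
  if (inherits(model, "pse_model")) model <- model$svm
  stopifnot(inherits(model, "pse_svm"))
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    stop("feature dimension mismatch: expected ", model$dim, ", got ",
         ncol(x), call. = FALSE)
  sv <- model$sv
  # squared cross distances, row-wise independent so scores are
  # sample-order invariant
  d2 <- outer(rowSums(x * x), rowSums(sv * sv), "+") - 2 * tcrossprod(x, sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-model$gamma * d2) %*% model$coefs - model$rho)
}

#' Predicted class labels
#'
#' Label is the sign of the decision value; an exact 0 is mapped to +1.
#'
#' @inheritParams decision_scores
#' @return Integer +1/-1 vector.
#' @export
predict_labels <- function(model, x) {
  s <- decision_scores(model, x)
  ifelse(s >= 0, 1L, -1L)
}

fmt_full <- function(x) sprintf("%.17g", x)

svm_to_text <- function(m) {
  n_pos <- sum(m$coefs > 0)
  sv_lines <- vapply(seq_len(nrow(m$sv)), function(i) {
    paste(fmt_full(m$coefs[i]),
          paste(paste0(seq_len(m$dim), ":", fmt_full(m$sv[i, ])),
                collapse = " "))
  }, character(1))
  c("svm_type c_svc",
    "kernel_type rbf",
    paste("gamma", fmt_full(m$gamma)),
    "nr_class 2",
    paste("total_sv", nrow(m$sv)),
    paste("rho", fmt_full(m$rho)),
    "label 1 -1",
    paste("nr_sv", n_pos, nrow(m$sv) - n_pos),
    "SV",
    sv_lines)
}

svm_from_text <- function(lines, feature_names) {
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) stop("model archive missing SVM field '", key, "'",
                          call. = FALSE)
    sub(paste0("^", key, " "), "", ln[1])
  }
  gamma <- as.numeric(kv("gamma"))
  rho <- as.numeric(kv("rho"))
  total_sv <- as.integer(kv("total_sv"))
  sv_at <- match("SV", lines)
  if (is.na(sv_at)) stop("model archive missing SV block", call. = FALSE)
  sv_lines <- lines[(sv_at + 1L):(sv_at + total_sv)]
  parts <- strsplit(sv_lines, " ", fixed = TRUE)
  coefs <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  sv <- t(vapply(parts, function(p)
    as.numeric(sub("^[0-9]+:", "", p[-1])), numeric(length(parts[[1]]) - 1L)))
  structure(list(sv = sv, coefs = coefs, rho = rho, gamma = gamma,
                 C = NA_real_, dim = ncol(sv), feature_names = feature_names),
            class = "pse_svm")
}
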