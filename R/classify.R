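# ---- leave-one-out SVM over cluster-feature combinations ----

#' SVM classifier configuration
#'
#' The grid is specified in log2 units, the convention of RBF-kernel grid
#' searches over cost `c` and kernel width `g`.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param log2c_range `c(lo, hi, step)` for `log2(C)`.
#' @param log2g_range `c(lo, hi, step)` for `log2(gamma)` (ignored for the
#'   linear kernel).
#' @param cv_mode `"paper_loocv"` selects the `(C, gamma)` maximizing the
#'   whole-set LOOCV accuracy (the single-loop procedure commonly reported
#'   with LIBSVM, optimistically biased); `"nested_loocv"` selects
#'   parameters per outer fold with an inner LOOCV (unbiased).
#' @return A validated `svm_config` list.
#' @export
svm_config <- function(kernel = c("rbf", "linear"),
                       log2c_range = c(-5, 15, 2),
                       log2g_range = c(-15, 3, 2),
                       cv_mode = c("paper_loocv", "nested_loocv")) {
  kernel <- match.arg(kernel)
  cv_mode <- match.arg(cv_mode)
  stopifnot(length(log2c_range) == 3, log2c_range[3] > 0,
            log2c_range[2] >= log2c_range[1],
            length(log2g_range) == 3, log2g_range[3] > 0,
            log2g_range[2] >= log2g_range[1])
  structure(list(kernel = kernel, log2c_range = log2c_range,
                 log2g_range = log2g_range, cv_mode = cv_mode),
            class = "svm_config")
}

svm_grid <- function(config) {
  cs <- seq(config$log2c_range[1], config$log2c_range[2],
            by = config$log2c_range[3])
  gs <- if (config$kernel == "linear") 0
        else seq(config$log2g_range[1], config$log2g_range[2],
                 by = config$log2g_range[3])
  expand.grid(log2c = cs, log2g = gs, KEEP.OUT.ATTRS = FALSE)
}

# Train-fold scaler: center/scale from the training rows only, so the
# held-out subject never influences the standardization.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$s, "/")
}

fit_svm <- function(x, y, log2c, log2g, kernel) {
  e1071::svm(x = x, y = y,
             kernel = if (kernel == "rbf") "radial" else "linear",
             cost = 2^log2c, gamma = 2^log2g, scale = FALSE)
}

# LOOCV predictions at fixed hyperparameters over the given subject set.
loocv_predict <- function(x, y, log2c, log2g, kernel) {
  n <- nrow(x)
  pred <- factor(rep(NA, n), levels = levels(y))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2) next
    scaler <- fit_scaler(x[tr, , drop = FALSE])
    xt <- apply_scaler(x[tr, , drop = FALSE], scaler)
    fit <- fit_svm(xt, y[tr], log2c, log2g, kernel)
    pred[i] <- predict(fit, apply_scaler(x[i, , drop = FALSE], scaler))
  }
  pred
}

#' Confusion-matrix metrics
#'
#' Patients are the positive class: sensitivity is patient detection,
#' specificity control detection. Percentages are reported at 2-decimal
#' precision with raw counts retained.
#'
#' @param predictions factor/character of predicted labels.
#' @param labels factor/character of true labels
#'   (`"patient"`/`"control"`).
#' @return `list(accuracy_pct, sensitivity_pct, specificity_pct, counts)`.
#' @export
confusion_metrics <- function(predictions, labels) {
  if (!length(labels)) stop("empty input", call. = FALSE)
  stopifnot(length(predictions) == length(labels))
  labels <- as.character(labels); predictions <- as.character(predictions)
  pos <- labels == "patient"
  tp <- sum(predictions == "patient" & pos, na.rm = TRUE)
  tn <- sum(predictions == "control" & !pos, na.rm = TRUE)
  counts <- list(correct_total = tp + tn, total = length(labels),
                 true_pos = tp, pos = sum(pos),
                 true_neg = tn, neg = sum(!pos))
  list(accuracy_pct = round(100 * counts$correct_total / counts$total, 2),
       sensitivity_pct = round(100 * tp / counts$pos, 2),
       specificity_pct = round(100 * tn / counts$neg, 2),
       counts = counts)
}

#' Leave-one-out SVM with hyperparameter grid search
#'
#' In `paper_loocv` mode the `(C, gamma)` grid point maximizing the
#' whole-set LOOCV accuracy is selected and its fold predictions are
#' reported (the literal single-loop replication; its accuracy is
#' optimistically biased because the selection sees every fold). In
#' `nested_loocv` mode each outer fold's parameters are chosen by an
#' inner LOOCV on its training set (unbiased). Grid ties are broken by
#' grid order (lowest `log2c`, then `log2g`). Feature scaling is fit on
#' training folds only.
#'
#' @param features subjects x features numeric matrix.
#' @param labels group factor (`control`/`patient`) aligned with rows.
#' @param config an [svm_config].
#' @return A `classifier_report`: metrics, counts, per-subject
#'   predictions, best parameters and the cv mode used.
#' @export
loocv_svm <- function(features, labels, config = svm_config()) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (any(!is.finite(features))) stop("non-finite features", call. = FALSE)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  grid <- svm_grid(config)
  n <- nrow(features)
  if (config$cv_mode == "paper_loocv") {
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      pred <- loocv_predict(features, labels, grid$log2c[gi],
                            grid$log2g[gi], config$kernel)
      acc <- mean(pred == labels, na.rm = TRUE)
      if (is.null(best) || acc > best$acc + 1e-12) {
        best <- list(acc = acc, pred = pred, log2c = grid$log2c[gi],
                     log2g = grid$log2g[gi])
      }
    }
    pred <- best$pred
    best_c <- best$log2c; best_g <- best$log2g
  } else {
    pred <- factor(rep(NA, n), levels = levels(labels))
    chosen <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      inner_best <- NULL
      for (gi in seq_len(nrow(grid))) {
        ip <- loocv_predict(features[tr, , drop = FALSE], labels[tr],
                            grid$log2c[gi], grid$log2g[gi], config$kernel)
        acc <- mean(ip == labels[tr], na.rm = TRUE)
        if (is.null(inner_best) || acc > inner_best$acc + 1e-12)
          inner_best <- list(acc = acc, log2c = grid$log2c[gi],
                             log2g = grid$log2g[gi])
      }
      scaler <- fit_scaler(features[tr, , drop = FALSE])
      fit <- fit_svm(apply_scaler(features[tr, , drop = FALSE], scaler),
                     labels[tr], inner_best$log2c, inner_best$log2g,
                     config$kernel)
      pred[i] <- predict(fit, apply_scaler(features[i, , drop = FALSE],
                                           scaler))
      chosen[i, ] <- c(inner_best$log2c, inner_best$log2g)
    }
    tab <- table(paste(chosen[, 1], chosen[, 2]))
    modal <- strsplit(names(tab)[which.max(tab)], " ")[[1]]
    best_c <- as.numeric(modal[1]); best_g <- as.numeric(modal[2])
  }
  metrics <- confusion_metrics(pred, labels)
  structure(c(metrics,
              list(per_subject = data.frame(true = labels,
                                            predicted = pred),
                   best_log2c = best_c, best_log2g = best_g,
                   cv_mode = config$cv_mode, kernel = config$kernel,
                   feature_set = paste(colnames(features),
                                       collapse = "+"))),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> features %s [%s]\n  accuracy %.2f%% (%d/%d), sensitivity %.2f%% (%d/%d), specificity %.2f%% (%d/%d)\n  best log2c=%g log2g=%g%s\n",
    x$feature_set, x$cv_mode, x$accuracy_pct, x$counts$correct_total,
    x$counts$total, x$sensitivity_pct, x$counts$true_pos, x$counts$pos,
    x$specificity_pct, x$counts$true_neg, x$counts$neg, x$best_log2c,
    x$best_log2g,
    if (x$cv_mode == "paper_loocv")
      "\n  note: parameters selected on whole-set LOOCV accuracy; estimate is optimistically biased"
    else ""))
  invisible(x)
}

#' Search single clusters and pairwise combinations
#'
#' Evaluates every single feature and every unordered pair
#' (`K + K(K-1)/2` runs; 6 for K = 3) with [loocv_svm], ranking by
#' accuracy, ties broken by higher sensitivity then fewer features.
#' Combination labels concatenate the feature ids (e.g. `"23"`).
#'
#' @param feature_matrix subjects x K matrix of cluster features (column
#'   names are the feature ids; defaults to 1..K).
#' @param labels group factor aligned with rows.
#' @param config an [svm_config].
#' @return List of `classifier_report`s in rank order, with a summary
#'   data frame in attribute `ranking`.
#' @export
combination_search <- function(feature_matrix, labels,
                               config = svm_config()) {
  feature_matrix <- as.matrix(feature_matrix)
  K <- ncol(feature_matrix)
  stopifnot(K >= 1)
  if (is.null(colnames(feature_matrix)))
    colnames(feature_matrix) <- as.character(seq_len(K))
  sets <- c(as.list(seq_len(K)),
            if (K >= 2) combn(K, 2, simplify = FALSE))
  reports <- lapply(sets, function(sel) {
    rep <- loocv_svm(feature_matrix[, sel, drop = FALSE], labels, config)
    rep$feature_set <- paste(colnames(feature_matrix)[sel], collapse = "")
    rep$n_features <- length(sel)
    rep
  })
  acc <- vapply(reports, `[[`, 0, "accuracy_pct")
  sens <- vapply(reports, `[[`, 0, "sensitivity_pct")
  nf <- vapply(reports, `[[`, 0, "n_features")
  ord <- order(-acc, -sens, nf, seq_along(reports))
  reports <- reports[ord]
  ranking <- data.frame(
    rank = seq_along(reports),
    feature_set = vapply(reports, `[[`, "", "feature_set"),
    accuracy_pct = vapply(reports, `[[`, 0, "accuracy_pct"),
    sensitivity_pct = vapply(reports, `[[`, 0, "sensitivity_pct"),
    specificity_pct = vapply(reports, `[[`, 0, "specificity_pct"),
    best_log2c = vapply(reports, `[[`, 0, "best_log2c"),
    best_log2g = vapply(reports, `[[`, 0, "best_log2g"),
    stringsAsFactors = FALSE)
  attr(reports, "ranking") <- ranking
  reports
}
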