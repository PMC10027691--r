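#' Leave-one-run-out cross-validated six-class decoding
#'
#' Trains a linear support vector machine (C-SVC, cost `cost`, one-vs-one
#' majority vote) on the exemplars of all runs but one and tests on the
#' held-out run, rotating over runs: with 4 runs x 6 classes each fold
#' trains on 18 exemplars and tests on 6. Two engines produce identical
#' predictions: `"libsvm"` fits e1071/libsvm on the raw feature matrix;
#' `"gram"` fits the package's dual solver on the precomputed linear Gram
#' matrix (fast path used by the permutation machinery; the linear SVM dual
#' depends on the features only through their inner products). Features are
#' used as-is; optional z-scoring is fit on the training folds only.
#'
#' @param features A `pattern_features` object (see [assemble_pattern()]).
#' @param cost SVM cost parameter C.
#' @param engine `"libsvm"` or `"gram"`.
#' @param scale_features Z-score features using training-fold statistics?
#' @param label_source Annotation carried into the result.
#' @param subject Subject id carried into the result.
#' @return A `decode_result`: accuracy, 6 x 6 confusion counts (rows = true
#'   class), per-fold accuracies, and metadata.
#' @export
loro_cv_decode <- function(features, cost = 1,
                           engine = c("libsvm", "gram"),
                           scale_features = FALSE,
                           label_source = "wm_item", subject = NA_character_) {
  engine <- match.arg(engine)
  x <- features$x
  y <- features$class
  runs <- features$run
  u_runs <- sort(unique(runs))
  if (length(u_runs) < 2L) abort("leave-one-run-out needs >= 2 runs")
  classes <- sort(unique(y))
  k <- length(classes)
  conf <- matrix(0L, k, k, dimnames = list(true = classes, pred = classes))
  per_fold <- numeric(length(u_runs))
  ord <- order(runs, y)  # canonical exemplar order: run blocks, class-sorted
  x <- x[ord, , drop = FALSE]; y <- y[ord]; runs <- runs[ord]
  K <- if (engine == "gram" && !scale_features) tcrossprod(x) else NULL
  for (fi in seq_along(u_runs)) {
    te <- which(runs == u_runs[fi])
    tr <- which(runs != u_runs[fi])
    if (!all(classes %in% y[tr])) {
      abort(sprintf("fold %d: class missing from training data", fi))
    }
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (scale_features) {
      mu <- colMeans(xtr); s <- apply(xtr, 2, sd); s[s == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, s, "/")
    }
    pred <- if (engine == "libsvm" || scale_features) {
      fit <- e1071::svm(xtr, factor(y[tr], levels = classes),
                        kernel = "linear", cost = cost, scale = FALSE)
      as.integer(as.character(predict(fit, xte)))
    } else {
      as.integer(ovo_predict_cpp(K, as.integer(y), as.integer(tr),
                                 as.integer(te), C = cost))
    }
    for (t in seq_along(te)) {
      conf[match(y[te[t]], classes), match(pred[t], classes)] <-
        conf[match(y[te[t]], classes), match(pred[t], classes)] + 1L
    }
    per_fold[fi] <- mean(pred == y[te])
  }
  structure(
    list(accuracy = sum(diag(conf)) / sum(conf), confusion = conf,
         per_fold = per_fold, folds = u_runs, unit = features$unit,
         subject = subject, label_source = label_source,
         n_exemplars = length(y)),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s%s: accuracy %.3f over %d exemplars (%d folds)\n",
              x$unit, if (is.na(x$subject)) "" else paste0(" / ", x$subject),
              x$accuracy, x$n_exemplars, length(x$per_fold)))
  invisible(x)
}

#' Group mean and standard error of decoding accuracy
#'
#' @param accuracies Numeric vector of per-subject accuracies (>= 2).
#' @return Tibble with `mean`, `sem` (sd / sqrt(n)), `n`.
#' @export
group_mean_accuracy <- function(accuracies) {
  accuracies <- as.numeric(accuracies)
  if (length(accuracies) < 2L) abort("need accuracies from >= 2 subjects")
  tibble::tibble(mean = mean(accuracies),
                 sem = sd(accuracies) / sqrt(length(accuracies)),
                 n = length(accuracies))
}

#' Row-normalize a confusion matrix
#'
#' Divides each row (true class) by its total so rows sum to 1; all-zero
#' rows are left at zero with a warning.
#'
#' @param confusion Non-negative count matrix.
#' @return Row-stochastic matrix.
#' @export
normalize_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) abort("confusion counts must be non-negative")
  rs <- rowSums(confusion)
  if (any(rs == 0)) warn("zero confusion row(s) left at zero")
  out <- confusion
  nz <- rs > 0
  out[nz, ] <- confusion[nz, , drop = FALSE] / rs[nz]
  out
}
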