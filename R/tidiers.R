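#' Tidy a decoding result
#'
#' One row per cross-validation fold.
#'
#' @param x A `decode_result`.
#' @param ... Unused.
#' @return Tibble with unit, subject, label_source, fold (held-out run),
#'   accuracy.
#' @export
tidy.decode_result <- function(x, ...) {
  tibble::tibble(unit = x$unit, subject = x$subject,
                 label_source = x$label_source, fold = x$folds,
                 accuracy = x$per_fold)
}

#' @rdname tidy.decode_result
#' @export
glance.decode_result <- function(x, ...) {
  tibble::tibble(unit = x$unit, subject = x$subject,
                 accuracy = x$accuracy, n_exemplars = x$n_exemplars,
                 n_folds = length(x$per_fold))
}

#' Tidy a permutation null distribution
#'
#' @param x A `wm_null`.
#' @param ... Unused.
#' @return Tibble with permutation index and max_accuracy.
#' @export
tidy.wm_null <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), max_accuracy = x$max_stats)
}

#' @rdname tidy.wm_null
#' @export
glance.wm_null <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, n_units = x$n_units,
                 n_subjects = x$n_subjects, median = median(x$max_stats),
                 q95 = unname(stats::quantile(x$max_stats, 0.95)))
}

#' Tidy a family analysis result
#'
#' @param x A `wm_family_result`.
#' @param ... Unused.
#' @return The per-unit report tibble (unit, size, observed, sem, p,
#'   significant).
#' @export
tidy.wm_family_result <- function(x, ...) x$report

#' @rdname tidy.wm_family_result
#' @export
glance.wm_family_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_units = nrow(x$report),
                 n_significant = sum(x$report$significant),
                 alpha = x$alpha, n_perm = x$n_perm,
                 n_subjects = ncol(x$subject_accuracy),
                 best_unit = x$report$unit[which.max(x$report$observed)],
                 best_accuracy = max(x$report$observed))
}
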