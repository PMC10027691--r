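#' Shuffle class labels within exchangeability blocks (runs)
#'
#' Permutes labels independently and uniformly inside each run block, so each
#' run keeps its label multiset — runs are the exchangeability blocks of the
#' cross-validated decoding null.
#'
#' @param labels Integer class labels.
#' @param runs Run tag per label.
#' @param seed Optional seed (NULL uses the current RNG stream).
#' @return Permuted label vector.
#' @export
permute_labels_within_runs <- function(labels, runs, seed = NULL) {
  with_seed_if(seed, {
    out <- labels
    for (r in unique(runs)) {
      ix <- which(runs == r)
      out[ix] <- labels[ix][sample.int(length(ix))]
    }
    out
  })
}

#' Family-wise maximum-statistic null distribution
#'
#' For each of `n_perm` permutations: every subject's class labels are
#' shuffled within runs once and the *same* shuffled labels are applied to
#' every unit of the family (required for a valid family-wise maximum); each
#' unit x subject is re-decoded with leave-one-run-out CV under the permuted
#' labels; unit-wise group means are formed across subjects; and the maximum
#' group mean over the family is recorded. Features never change under label
#' permutation, so decoding runs on each unit x subject's precomputed linear
#' Gram matrix. The identity permutation is not excluded.
#'
#' @param grams List over units, each a list over subjects of 24 x 24 Gram
#'   matrices (see [run_family_analysis()] for the end-to-end path).
#' @param labels List over subjects of exemplar class labels (run-block
#'   sorted, as produced by the decoder's canonical ordering).
#' @param runs List over subjects of exemplar run tags (same order).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param cost SVM cost.
#' @return A `wm_null`: `max_stats` (length `n_perm`), `n_perm`, `n_units`,
#'   `n_subjects`, `seed`.
#' @export
build_null <- function(grams, labels, runs, n_perm = 500L, seed = 1L,
                       cost = 1) {
  n_units <- length(grams)
  n_subj <- length(labels)
  stopifnot(n_units >= 1L, n_subj >= 2L,
            all(vapply(grams, length, 1L) == n_subj))
  # per subject: matrix of permuted label columns, shared across units
  Y <- with_seed_if(seed, purrr::map(seq_len(n_subj), function(s) {
    vapply(seq_len(n_perm), function(p) {
      permute_labels_within_runs(labels[[s]], runs[[s]])
    }, integer(length(labels[[s]])))
  }))
  acc <- array(NA_real_, dim = c(n_units, n_subj, n_perm))
  for (u in seq_len(n_units)) {
    for (s in seq_len(n_subj)) {
      acc[u, s, ] <- loro_accuracy_batch_cpp(grams[[u]][[s]],
                                             as.integer(runs[[s]]),
                                             Y[[s]], C = cost)
    }
  }
  group <- apply(acc, c(1, 3), mean)          # units x perms
  structure(
    list(max_stats = apply(group, 2, max), n_perm = as.integer(n_perm),
         n_units = n_units, n_subjects = n_subj, seed = as.integer(seed)),
    class = "wm_null"
  )
}

#' @export
print.wm_null <- function(x, ...) {
  cat(sprintf("<wm_null> %d permutations over %d units x %d subjects; max-stat median %.3f\n",
              x$n_perm, x$n_units, x$n_subjects, median(x$max_stats)))
  invisible(x)
}

#' Permutation p-value against a maximum-statistic null
#'
#' `p = max(1, #\{max_stats >= observed\}) / n_perm`: ties count against the
#' observation and the smallest attainable p is `1 / n_perm` (0.002 at 500
#' permutations).
#'
#' @param observed Observed group-mean accuracy (vectorized).
#' @param null A `wm_null` or numeric vector of max statistics.
#' @return p-value(s).
#' @export
assign_pvalue <- function(observed, null) {
  ms <- if (inherits(null, "wm_null")) null$max_stats else as.numeric(null)
  if (length(ms) == 0L) abort("empty null distribution")
  vapply(observed, function(o) {
    max(1L, sum(ms >= o)) / length(ms)
  }, 1, USE.NAMES = FALSE)
}

#' Group-level family analysis with maximum-statistic correction
#'
#' End-to-end inference over a family of units (connectivity networks, the
#' within-ROI control patterns, or per-ROI activation betas): for every
#' subject, residualizes the session, builds each unit's 24-exemplar feature
#' matrix, decodes it with leave-one-run-out CV, then compares each unit's
#' observed group-mean accuracy to the family-wise maximum-statistic
#' permutation null (labels shuffled within runs, shared across units within
#' subject).
#'
#' Modes: `"connectivity"` (default) decodes the supplied ROI networks;
#' `"irrelevant-item"` relabels exemplars by the non-cued item;
#' `"within-roi"` uses each ROI's internal subROI pattern;
#' `"activation"` uses per-ROI content-beta patterns;
#' `"oc-control"` decodes the supplied networks but restricts reporting to
#' occipital-containing, STC-free networks.
#'
#' @param cohort List of `wm_session` objects ([simulate_cohort()]).
#' @param networks Tibble from [enumerate_networks()] (connectivity modes) or
#'   a character vector of ROI names (within-roi / activation modes; defaults
#'   to all registry ROIs).
#' @param mode Analysis mode, see Details.
#' @param n_perm Number of permutations.
#' @param alpha Family-wise significance level.
#' @param seed Seed for the permutation stream.
#' @param cost SVM cost.
#' @param engine Engine for the *observed* decodes ("gram" is exact and
#'   fast; "libsvm" available for cross-checking).
#' @param window_anchor Maintenance-window anchor, see
#'   [extract_maintenance_segments()].
#' @return A `wm_family_result`: `report` tibble (unit, size, observed mean,
#'   sem, p, significant), `null` (`wm_null`), `alpha`, `mode`,
#'   `subject_accuracy` (unit x subject matrix).
#' @export
run_family_analysis <- function(cohort, networks = NULL,
                                mode = c("connectivity", "irrelevant-item",
                                         "within-roi", "activation",
                                         "oc-control"),
                                n_perm = 99L, alpha = 0.05, seed = 1L,
                                cost = 1, engine = "gram",
                                window_anchor = "retrocue") {
  mode <- match.arg(mode)
  registry <- cohort[[1]]$registry
  label_source <- if (mode == "irrelevant-item") "irrelevant_item" else "wm_item"
  conn_mode <- mode %in% c("connectivity", "irrelevant-item", "oc-control")
  if (conn_mode && is.null(networks)) {
    abort("`networks` is required for connectivity-family modes")
  }
  if (!conn_mode && is.null(networks)) networks <- registry$roi
  units <- if (conn_mode) networks$network else networks
  n_units <- length(units)
  rows <- roi_row_index(registry)

  per_subject <- purrr::map(cohort, function(session) {
    if (mode == "activation") {
      betas <- content_betas(session$runs, session$schedule, session$acq)
      feats <- purrr::map(units, function(roi) {
        beta_pattern(betas, rows[[roi]], unit = roi)
      })
    } else {
      segs <- session_segments(session, label_source = label_source,
                               window_anchor = window_anchor)
      if (conn_mode) {
        # one correlation pass over the union of needed rows, then slice
        feats <- family_connectivity_features(segs, networks, registry)
      } else {
        feats <- purrr::map(units, within_roi_pattern, segments = segs,
                            registry = registry)
      }
    }
    purrr::map(feats, function(f) {
      res <- loro_cv_decode(f, cost = cost, engine = engine,
                            label_source = label_source,
                            subject = session$subject)
      ord <- order(f$run, f$class)
      list(acc = res$accuracy,
           gram = tcrossprod(f$x[ord, , drop = FALSE]),
           labels = f$class[ord], runs = f$run[ord])
    })
  })

  obs <- vapply(seq_len(n_units), function(u) {
    vapply(per_subject, function(s) s[[u]]$acc, 1)
  }, numeric(length(cohort)))
  obs <- t(obs)  # units x subjects
  rownames(obs) <- units
  grams <- purrr::map(seq_len(n_units), function(u) {
    purrr::map(per_subject, function(s) s[[u]]$gram)
  })
  labels <- purrr::map(per_subject, function(s) s[[1]]$labels)
  run_tags <- purrr::map(per_subject, function(s) s[[1]]$runs)
  null <- build_null(grams, labels, run_tags, n_perm = n_perm, seed = seed,
                     cost = cost)
  report <- tibble::tibble(
    unit = units,
    size = if (conn_mode) networks$size else NA_integer_,
    observed = rowMeans(obs),
    sem = apply(obs, 1, sd) / sqrt(ncol(obs)),
    p = assign_pvalue(rowMeans(obs), null)
  )
  report$significant <- report$p <= alpha
  if (mode == "oc-control") {
    keep <- filter_networks(networks, include = c("LOC", "ROC"),
                            exclude = c("LSTC", "RSTC"))$network
    report <- report[report$unit %in% keep, , drop = FALSE]
  }
  structure(
    list(report = report, null = null, alpha = alpha, mode = mode,
         subject_accuracy = obs, n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "wm_family_result"
  )
}

# slice every network's features out of one full correlation pass
family_connectivity_features <- function(segs, networks, registry) {
  need <- sort(unique(unlist(networks$members)))
  rows <- roi_row_index(registry)
  sub_rows <- unlist(rows[need], use.names = FALSE)
  # position of each ROI inside the restricted correlation matrix
  pos <- list(); off <- 0L
  for (roi in need) {
    pos[[roi]] <- off + seq_len(length(rows[[roi]]))
    off <- off + length(rows[[roi]])
  }
  conn <- purrr::map(seq_len(nrow(segs)), function(i) {
    seg <- segs$segment[[i]][sub_rows, , drop = FALSE]
    r <- suppressWarnings(cor(t(seg)))
    if (anyNA(r)) {
      warn("zero-variance subROI series: correlations set to 0")
      r[is.na(r)] <- 0
    }
    r
  })
  purrr::map(seq_len(nrow(networks)), function(ni) {
    members <- sort(networks$members[[ni]])
    pairs <- utils::combn(members, 2L, simplify = FALSE)
    x <- do.call(rbind, purrr::map(conn, function(r) {
      unlist(purrr::map(pairs, function(p) {
        as.vector(t(r[pos[[p[1]]], pos[[p[2]]], drop = FALSE]))
      }), use.names = FALSE)
    }))
    new_pattern_features(x, segs$class, segs$run,
                         unit = networks$network[ni], network = members)
  })
}

#' @export
print.wm_family_result <- function(x, ...) {
  n_sig <- sum(x$report$significant)
  cat(sprintf("<wm_family_result> mode %s: %d/%d units significant at alpha = %g (%d perms)\n",
              x$mode, n_sig, nrow(x$report), x$alpha, x$n_perm))
  if (n_sig > 0) {
    top <- dplyr::arrange(x$report[x$report$significant, ], .data$p)
    print(utils::head(top, 10))
  }
  invisible(x)
}
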