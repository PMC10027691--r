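#' Class-specific inter-ROI correlation matrix
#'
#' Pearson correlation between every subROI of ROI A and every subROI of
#' ROI B over one (run, class) concatenated maintenance segment. Zero-
#' variance series would give undefined coefficients; those entries are set
#' to 0 with a warning so degenerate synthetic inputs stay usable.
#'
#' @param segment subROIs x samples matrix (all registry rows present).
#' @param rows_a,rows_b Row indices of the two ROIs.
#' @return N_A x N_B correlation matrix.
#' @export
class_connectivity_matrix <- function(segment, rows_a, rows_b) {
  if (ncol(segment) < 3L) abort("need at least 3 samples to correlate")
  A <- t(segment[rows_a, , drop = FALSE])
  B <- t(segment[rows_b, , drop = FALSE])
  r <- suppressWarnings(cor(A, B))
  if (anyNA(r)) {
    warn("zero-variance subROI series: correlations set to 0")
    r[is.na(r)] <- 0
  }
  r
}

#' Connectivity feature exemplars for one ROI network
#'
#' Builds the 6 classes x 4 runs = 24 connectivity-pattern exemplars of a
#' network from per-(run, class) maintenance segments: for every unordered
#' member pair (in canonical lexicographic order) the inter-ROI correlation
#' matrix is computed and flattened row-major (first member's subROIs outer),
#' and the pair blocks are concatenated into one feature vector of length
#' [pattern_feature_count()].
#'
#' @param network Character vector of member ROI names (2-4).
#' @param segments Segment tibble from [extract_maintenance_segments()].
#' @param registry The registry the segments were generated under.
#' @return A `pattern_features` object: list with `x` (24 x T feature
#'   matrix), `class`, `run`, `network`, `unit` (canonical network id).
#' @export
assemble_pattern <- function(network, segments, registry) {
  network <- sort(network)
  bad <- setdiff(network, registry$roi)
  if (length(bad)) abort(paste0("unknown ROI(s): ", paste(bad, collapse = ", ")))
  rows <- roi_row_index(registry)
  pairs <- utils::combn(network, 2L, simplify = FALSE)
  feats <- purrr::map(seq_len(nrow(segments)), function(i) {
    seg <- segments$segment[[i]]
    unlist(purrr::map(pairs, function(p) {
      r <- class_connectivity_matrix(seg, rows[[p[1]]], rows[[p[2]]])
      as.vector(t(r))  # row-major: first member's subROIs outer
    }), use.names = FALSE)
  })
  x <- do.call(rbind, feats)
  new_pattern_features(x, segments$class, segments$run,
                       unit = paste(network, collapse = "+"),
                       network = network)
}

#' Within-ROI connectivity pattern (control analysis)
#'
#' Features are the upper triangle (diagonal excluded) of the subROI x subROI
#' correlation matrix within a single ROI, per (run, class): N * (N - 1) / 2
#' features for an N-subROI region.
#'
#' @param roi ROI name.
#' @inheritParams assemble_pattern
#' @return A `pattern_features` object.
#' @export
within_roi_pattern <- function(roi, segments, registry) {
  rows <- roi_row_index(registry)[[roi]]
  if (is.null(rows)) abort(paste0("unknown ROI: ", roi))
  if (length(rows) < 2L) abort("within-ROI pattern needs >= 2 subROIs")
  feats <- purrr::map(seq_len(nrow(segments)), function(i) {
    r <- class_connectivity_matrix(segments$segment[[i]], rows, rows)
    r[upper.tri(r)]
  })
  new_pattern_features(do.call(rbind, feats), segments$class, segments$run,
                       unit = paste0("within:", roi), network = roi)
}

new_pattern_features <- function(x, class, run, unit, network) {
  stopifnot(nrow(x) == length(class), length(class) == length(run))
  structure(
    list(x = x, class = as.integer(class), run = as.integer(run),
         unit = unit, network = network),
    class = "pattern_features"
  )
}

#' @export
print.pattern_features <- function(x, ...) {
  cat(sprintf("<pattern_features> %s: %d exemplars x %d features (%d classes, %d runs)\n",
              x$unit, nrow(x$x), ncol(x$x), length(unique(x$class)),
              length(unique(x$run))))
  invisible(x)
}

#' Beta features as decodable exemplars
#'
#' Wraps the per-(run, class) activation betas of one ROI into the same
#' exemplar container the decoder consumes.
#'
#' @param betas Tibble from [content_betas()].
#' @param rows Row indices of the ROI's units within the beta vectors.
#' @param unit Unit label for reporting.
#' @return A `pattern_features` object.
#' @export
beta_pattern <- function(betas, rows, unit) {
  x <- do.call(rbind, purrr::map(betas$beta, function(b) b[rows]))
  new_pattern_features(x, betas$class, betas$run, unit = unit, network = unit)
}

#' End-to-end connectivity features for one session
#'
#' Convenience wrapper: builds per-run design matrices (event + drift
#' blocks), residualizes every run, extracts lag-shifted class segments, and
#' assembles the pattern features of each requested network.
#'
#' @param session A `wm_session` from [simulate_session()].
#' @param networks Tibble from [enumerate_networks()] (or a list of member
#'   vectors).
#' @param label_source,window_anchor Passed to
#'   [extract_maintenance_segments()].
#' @param confounds Optional list of per-run confound matrices.
#' @return Named list of `pattern_features`, one per network.
#' @export
session_connectivity_features <- function(session, networks,
                                          label_source = "wm_item",
                                          window_anchor = "retrocue",
                                          confounds = NULL) {
  members <- if (is.data.frame(networks)) networks$members else networks
  segs <- session_segments(session, label_source, window_anchor, confounds)
  out <- purrr::map(members, assemble_pattern, segments = segs,
                    registry = session$registry)
  names(out) <- vapply(out, function(p) p$unit, "")
  out
}

# residualize all runs of a session and extract class segments
session_segments <- function(session, label_source = "wm_item",
                             window_anchor = "retrocue", confounds = NULL) {
  acq <- session$acq
  resid <- purrr::map(seq_along(session$runs), function(r) {
    ev <- session$events[session$events$run == r, ]
    X <- build_design_matrix(ev, acq,
                             confounds = if (is.null(confounds)) NULL else confounds[[r]])
    residualize(session$runs[[r]], X)
  })
  extract_maintenance_segments(resid, session$schedule, acq,
                               label_source = label_source,
                               window_anchor = window_anchor)
}
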