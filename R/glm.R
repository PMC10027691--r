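#' Legendre polynomial drift basis
#'
#' Orthogonal Legendre polynomials evaluated on n equally spaced points of
#' \[-1, 1\]; column j is order j - 1 (constant, linear, ...). Used as the
#' per-run low-frequency drift block of the design matrix.
#'
#' @param n Number of time points.
#' @param order Highest polynomial order (>= 1).
#' @return n x (order + 1) matrix.
#' @export
legendre_basis <- function(n, order) {
  stopifnot(n >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {  # (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  colnames(P) <- paste0("poly", 0:order)
  P
}

#' Build a single-run GLM design matrix
#'
#' Columns are (1) one HRF-convolved regressor per scheduled event type
#' (alert cue, the two memory items, retro-cue, probe, response cue),
#' (2) a Legendre polynomial drift block whose order implements a high-pass
#' filter at `acq$highpass_hz` — order = max(1, round(2 * cutoff *
#' run_length)) — and (3) any supplied confound channels. With
#' `content_regressors = TRUE` one boxcar per item class is added covering
#' the maintenance period from `content_delay` s after the retro-cue onset
#' until the probe onset; these columns carry the content signal for
#' activation-pattern features and are never included in the connectivity
#' residualization (they would remove the signal of interest).
#'
#' @param events Events tibble for one run (see [schedule_events()]).
#' @param acq An [acq_config()].
#' @param confounds Optional timepoints x channels matrix.
#' @param content_regressors Add per-class maintenance boxcars?
#' @param content_delay Start of the content window after retro-cue onset, s.
#' @param schedule Trial schedule rows for this run (required when
#'   `content_regressors = TRUE`).
#' @return Timepoints x regressors matrix with named columns and attribute
#'   `blocks` listing column indices by role (events, drift, confounds,
#'   content).
#' @export
build_design_matrix <- function(events, acq, confounds = NULL,
                                content_regressors = FALSE,
                                content_delay = 4, schedule = NULL) {
  if (length(unique(events$run)) > 1L) abort("`events` must cover one run")
  if (any(events$onset + events$duration > acq$run_length + 1e-9)) {
    abort("events extend past the end of the run")
  }
  types <- unique(events$trial_type)
  ev_cols <- vapply(types, function(tt) {
    sel <- events$trial_type == tt
    event_regressor(events$onset[sel], events$duration[sel], acq)
  }, numeric(acq$n_timepoints))
  colnames(ev_cols) <- types
  order <- max(1L, round(2 * acq$highpass_hz * acq$run_length))
  drift <- legendre_basis(acq$n_timepoints, order)
  X <- cbind(ev_cols, drift)
  blocks <- list(events = seq_along(types),
                 drift = length(types) + seq_len(order + 1L))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != acq$n_timepoints) {
      abort("`confounds` must have one row per timepoint")
    }
    colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    blocks$confounds <- ncol(X) + seq_len(ncol(confounds))
    X <- cbind(X, confounds)
  }
  if (content_regressors) {
    if (is.null(schedule)) abort("`schedule` is required for content regressors")
    sch <- schedule[schedule$run == unique(events$run), ]
    classes <- sort(unique(sch$class))
    cc <- vapply(classes, function(c0) {
      sel <- sch$class == c0
      event_regressor(sch$retrocue_onset[sel] + content_delay,
                      sch$probe_onset[sel] - sch$retrocue_onset[sel] -
                        content_delay, acq)
    }, numeric(acq$n_timepoints))
    colnames(cc) <- paste0("content", classes)
    blocks$content <- ncol(X) + seq_along(classes)
    X <- cbind(X, cc)
  }
  # prune exactly collinear columns (keeps first occurrence)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    warn(paste("dropping rank-deficient design column(s):",
               paste(dropped, collapse = ", ")))
    old <- seq_len(ncol(X))
    remap <- match(old, keep)
    blocks <- purrr::map(blocks, function(ix) remap[ix][!is.na(remap[ix])])
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "blocks") <- blocks
  X
}

#' Residualize time series against a design matrix
#'
#' Ordinary-least-squares residuals of every subROI row against all design
#' columns; the output is orthogonal to each column up to numerical
#' precision. Applying the operation twice is a no-op.
#'
#' @param ts subROIs x timepoints matrix.
#' @param design Timepoints x regressors matrix from [build_design_matrix()].
#' @return Residual matrix, same shape as `ts`.
#' @export
residualize <- function(ts, design) {
  ts <- as.matrix(ts)
  if (ncol(ts) != nrow(design)) {
    abort("`ts` columns (timepoints) must match design rows")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) abort("design matrix is rank deficient")
  t(qr.resid(qrX, t(ts)))
}

#' Extract lag-shifted maintenance segments, concatenated by class
#'
#' For each trial, takes the TR-grid samples in the half-open window
#' \[anchor + lag, probe onset + lag) — anchor is the retro-cue onset by
#' default, or the maintenance-period onset — and concatenates trials of the
#' same label within each run. The default label is the retro-cued (relevant)
#' item class; `label_source = "irrelevant_item"` relabels trials by the
#' non-cued item for the control analysis. Trials whose shifted window would
#' run past the end of the run are dropped with a warning.
#'
#' @param resid subROIs x timepoints residual matrix for one run, or a list
#'   of such matrices (one per run).
#' @param schedule Trial schedule.
#' @param acq An [acq_config()].
#' @param label_source `"wm_item"` or `"irrelevant_item"`.
#' @param window_anchor `"retrocue"` (default) or `"maintenance"`.
#' @return Tibble with columns run, class, n_samples and a `segment` list
#'   column of subROIs x samples matrices.
#' @export
extract_maintenance_segments <- function(resid, schedule, acq,
                                         label_source = c("wm_item", "irrelevant_item"),
                                         window_anchor = c("retrocue", "maintenance")) {
  label_source <- match.arg(label_source)
  window_anchor <- match.arg(window_anchor)
  if (is.matrix(resid)) resid <- list(resid)
  runs <- sort(unique(schedule$run))
  if (length(resid) != length(runs)) {
    abort("need one residual matrix per run")
  }
  out <- purrr::map(seq_along(runs), function(ri) {
    sch <- schedule[schedule$run == runs[ri], ]
    lab <- if (label_source == "wm_item") sch$class else sch$irrelevant_class
    windows <- purrr::map(seq_len(nrow(sch)), function(k) {
      stop_s <- sch$probe_onset[k] + acq$lag
      if (ceiling(stop_s / acq$tr) > acq$n_timepoints) return(NULL)
      w <- maintenance_window(sch$retrocue_onset[k], sch$probe_onset[k], acq,
                              anchor = window_anchor,
                              maintenance_onset = sch$maintenance_onset[k])
      seq(w[1], w[2])
    })
    dropped <- vapply(windows, is.null, TRUE)
    if (any(dropped)) {
      warn(sprintf("run %d: dropping %d trial(s) whose lagged window exceeds the run",
                   runs[ri], sum(dropped)))
    }
    purrr::map(sort(unique(lab)), function(c0) {
      idx <- unlist(windows[lab == c0 & !dropped])
      tibble::tibble(
        run = runs[ri], class = c0, n_samples = length(idx),
        segment = list(resid[[ri]][, idx, drop = FALSE])
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

#' Content-specific beta features for activation-pattern decoding
#'
#' Fits, separately per run, the full GLM including the per-class maintenance
#' boxcars and returns each class's contrast effect size (the unit-contrast
#' beta) for every subROI: the 6 classes x 4 runs = 24 feature vectors per
#' subject used by the activation-pattern analysis.
#'
#' @param ts_runs List of subROIs x timepoints matrices, one per run.
#' @param schedule Trial schedule.
#' @param acq An [acq_config()].
#' @param confounds Optional list of per-run confound matrices.
#' @param content_delay Content-window start after retro-cue onset, s.
#' @return Tibble with columns run, class and a `beta` list column of
#'   per-subROI effect-size vectors.
#' @export
content_betas <- function(ts_runs, schedule, acq, confounds = NULL,
                          content_delay = 4) {
  events <- schedule_events(schedule)
  runs <- sort(unique(schedule$run))
  purrr::map(seq_along(runs), function(ri) {
    ev <- events[events$run == runs[ri], ]
    X <- build_design_matrix(ev, acq,
                             confounds = if (is.null(confounds)) NULL else confounds[[ri]],
                             content_regressors = TRUE,
                             content_delay = content_delay,
                             schedule = schedule)
    blocks <- attr(X, "blocks")
    B <- t(qr.coef(qr(X), t(as.matrix(ts_runs[[ri]]))))  # units x regressors
    B[is.na(B)] <- 0
    classes <- as.integer(sub("^content", "", colnames(X)[blocks$content]))
    tibble::tibble(
      run = runs[ri], class = classes,
      beta = purrr::map(blocks$content, function(j) unname(B[, j]))
    )
  }) |> dplyr::bind_rows()
}
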