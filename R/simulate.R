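#' Ground-truth specification for the synthetic BOLD generator
#'
#' Declares where and how strongly working-memory content is written into the
#' synthetic data. Content is carried by connectivity, not amplitude: during
#' each trial's (lag-shifted) maintenance window, the subROIs "tuned" to the
#' retro-cued class across the ROIs of each signal network share a latent
#' Gaussian factor. A subROI's tuning is its index modulo the number of
#' classes — a discretized best-velocity topography — so each class raises
#' the correlation of a distinct set of subROI pairs by `coupling` while
#' leaving amplitudes exchangeable across classes.
#'
#' With factor loading `sqrt(coupling)` and residual `sqrt(1 - coupling)`,
#' the implied noise correlation of a class-matched pair is exactly
#' `coupling`; the construction is a one-factor model, hence always positive
#' semi-definite, and `coupling` must lie in \[0, 1\].
#'
#' @param signal_networks Character vector of ROI names forming the
#'   content-carrying network, or a list of such vectors for several networks.
#' @param coupling Correlation increment for class-matched subROI pairs
#'   during maintenance, in \[0, 1\].
#' @param noise_sd White-noise standard deviation.
#' @param noise_ar AR(1) coefficient of the noise (0 = white).
#' @param evoked_amp Amplitude of HRF-convolved event responses.
#' @param drift_amp Amplitude of low-frequency polynomial drifts.
#' @param confound_amp Amplitude of the global confound channels.
#' @param n_confounds Number of global confound channels.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(signal_networks = list(c("LSTC", "LSMG", "RSTC")),
                         coupling = 0.6, noise_sd = 1, noise_ar = 0,
                         evoked_amp = 2, drift_amp = 3, confound_amp = 1,
                         n_confounds = 2L) {
  if (is.character(signal_networks)) signal_networks <- list(signal_networks)
  if (coupling < 0 || coupling > 1) {
    abort("`coupling` must be in [0, 1] (one-factor model stays PSD)")
  }
  if (abs(noise_ar) >= 1) abort("`noise_ar` must be in (-1, 1)")
  structure(
    list(signal_networks = signal_networks, coupling = coupling,
         noise_sd = noise_sd, noise_ar = noise_ar, evoked_amp = evoked_amp,
         drift_amp = drift_amp, confound_amp = confound_amp,
         n_confounds = as.integer(n_confounds)),
    class = "ground_truth"
  )
}

# row indices of a registry's ROIs in the stacked subROI matrix
roi_row_index <- function(registry) {
  ends <- cumsum(registry$n_subrois)
  starts <- ends - registry$n_subrois + 1L
  stats::setNames(purrr::map2(starts, ends, seq), registry$roi)
}

# class tuning of each subROI within one ROI: index mod n_classes
subroi_tuning <- function(n_subrois, n_classes = 6L) {
  ((seq_len(n_subrois) - 1L) %% n_classes) + 1L
}

# lagged maintenance window of one trial as TR-grid indices (half-open)
maintenance_window <- function(retrocue_onset, probe_onset, acq,
                               anchor = c("retrocue", "maintenance"),
                               maintenance_onset = NULL) {
  anchor <- match.arg(anchor)
  start_s <- switch(anchor, retrocue = retrocue_onset,
                    maintenance = maintenance_onset) + acq$lag
  stop_s <- probe_onset + acq$lag
  i0 <- floor(start_s / acq$tr) + 1L   # 1-based grid, floor start
  i1 <- ceiling(stop_s / acq$tr)      # half-open [i0, i1]
  c(max(1L, i0), min(acq$n_timepoints, i1))
}

#' Simulate one subject's session of subROI BOLD time series
#'
#' Generates, per run, a subROIs x timepoints matrix as the sum of
#' (1) HRF-convolved evoked responses to every scheduled event with
#' subROI-specific random loadings, (2) low-frequency Legendre-polynomial
#' drifts, (3) global confound channels with random loadings, and (4) unit-
#' variance noise in which, during each trial's lag-shifted maintenance
#' window, the subROIs tuned to the retro-cued class across each signal
#' network share a latent factor with loading `sqrt(coupling)` (see
#' [ground_truth()]). Everything is reproducible from `seed`.
#'
#' @param registry Connectivity registry from [build_registry()].
#' @param schedule Trial schedule from [generate_trial_schedule()].
#' @param acq An [acq_config()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @param subject Subject identifier.
#' @return A `wm_session` list: `runs` (list of matrices), `events`,
#'   `schedule`, `registry`, `acq`, `truth`, `subject`, `seed`.
#' @export
simulate_session <- function(registry, schedule, acq = acq_config(),
                             truth = ground_truth(), seed = 1L,
                             subject = "sub-01") {
  bad <- setdiff(unlist(truth$signal_networks), registry$roi)
  if (length(bad)) abort(paste0("signal network ROI(s) not in registry: ",
                                paste(bad, collapse = ", ")))
  rows <- roi_row_index(registry)
  n_sub <- sum(registry$n_subrois)
  tuning <- unlist(purrr::map(registry$n_subrois, subroi_tuning,
                              n_classes = nrow(attr(schedule, "stimset")$classes)))
  events <- schedule_events(schedule)
  max_ev <- max(events$onset + events$duration)
  if (max_ev > acq$run_length) {
    abort(sprintf("events extend to %.1f s but runs last %g s", max_ev,
                  acq$run_length))
  }
  run_seeds <- derive_seeds(seed, acq$n_runs * 4L)
  runs <- purrr::map(seq_len(acq$n_runs), function(r) {
    ev_r <- events[events$run == r, ]
    sch_r <- schedule[schedule$run == r, ]
    sd4 <- run_seeds[(r - 1L) * 4L + 1:4]
    # evoked: one regressor per event type, random non-negative loadings
    evoked <- with_seed_if(sd4[1], {
      acc <- matrix(0, n_sub, acq$n_timepoints)
      for (tt in unique(ev_r$trial_type)) {
        sel <- ev_r$trial_type == tt
        reg <- event_regressor(ev_r$onset[sel], ev_r$duration[sel], acq)
        load <- runif(n_sub, 0.2, 1)
        acc <- acc + truth$evoked_amp * outer(load, reg)
      }
      acc
    })
    # drifts: random combination of Legendre polynomials (orders 1..5)
    drift <- with_seed_if(sd4[2], {
      P <- legendre_basis(acq$n_timepoints, 5L)[, -1, drop = FALSE]
      coef <- matrix(rnorm(n_sub * ncol(P)), n_sub)
      truth$drift_amp * coef %*% t(P)
    })
    # global confounds: smooth random channels, per-subROI loadings
    confound <- with_seed_if(sd4[3], {
      ch <- vapply(seq_len(truth$n_confounds), function(i) {
        as.numeric(stats::filter(rnorm(acq$n_timepoints), 0.9,
                                 method = "recursive"))
      }, numeric(acq$n_timepoints))
      ch <- scale(ch)
      load <- matrix(rnorm(n_sub * truth$n_confounds, sd = 1), n_sub)
      truth$confound_amp * load %*% t(ch)
    })
    # noise with class-dependent coupling during lagged maintenance windows
    noise <- with_seed_if(sd4[4], {
      e <- matrix(rnorm(n_sub * acq$n_timepoints), n_sub)
      if (truth$noise_ar != 0) {
        e <- t(apply(e, 1L, function(x) {
          as.numeric(stats::filter(x, truth$noise_ar, method = "recursive"))
        })) * sqrt(1 - truth$noise_ar^2)
      }
      a <- truth$coupling
      if (a > 0) {
        for (k in seq_len(nrow(sch_r))) {
          win <- maintenance_window(sch_r$retrocue_onset[k],
                                    sch_r$probe_onset[k], acq,
                                    maintenance_onset = sch_r$maintenance_onset[k])
          idx <- seq(win[1], win[2])
          z <- rnorm(length(idx))
          for (net in truth$signal_networks) {
            target <- unlist(purrr::map(net, function(roi) {
              rr <- rows[[roi]]
              rr[tuning[rr] == sch_r$class[k]]
            }))
            e[target, idx] <- sqrt(a) * matrix(z, length(target),
                                               length(idx), byrow = TRUE) +
              sqrt(1 - a) * e[target, idx]
          }
        }
      }
      truth$noise_sd * e
    })
    y <- evoked + drift + confound + noise
    rownames(y) <- paste0(rep(registry$roi, registry$n_subrois), "_",
                          unlist(purrr::map(registry$n_subrois, seq_len)))
    y
  })
  structure(
    list(runs = runs, events = events, schedule = schedule,
         registry = registry, acq = acq, truth = truth,
         subject = subject, seed = as.integer(seed)),
    class = "wm_session"
  )
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an independent seed derived from the master seed and an
#' independently randomized trial schedule; ground truth is shared (optionally
#' jittered in coupling strength per subject).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param registry,acq,truth As in [simulate_session()].
#' @param stimset Stimulus set used for every subject's schedule.
#' @param seed Master seed.
#' @param coupling_jitter SD of per-subject Gaussian jitter on `coupling`
#'   (clamped to \[0, 1\]).
#' @param schedule_args Extra arguments for [generate_trial_schedule()]
#'   (e.g. `n_trials_per_class`) applied to every subject.
#' @return List of `wm_session` objects.
#' @export
simulate_cohort <- function(n_subjects = 8L, registry = build_registry(),
                            acq = acq_config(), truth = ground_truth(),
                            stimset = build_stimulus_set(0.2), seed = 1L,
                            coupling_jitter = 0, schedule_args = list()) {
  if (n_subjects < 2L) abort("`n_subjects` must be >= 2")
  seeds <- matrix(derive_seeds(seed, 3L * n_subjects), ncol = 3L)
  jit <- if (coupling_jitter > 0) {
    with_seed_if(seeds[1, 3], rnorm(n_subjects, 0, coupling_jitter))
  } else rep(0, n_subjects)
  purrr::map(seq_len(n_subjects), function(i) {
    tr_i <- truth
    tr_i$coupling <- min(1, max(0, truth$coupling + jit[i]))
    sch <- do.call(generate_trial_schedule,
                   c(list(stimset, n_runs = acq$n_runs, seed = seeds[i, 1]),
                     schedule_args))
    simulate_session(registry, sch, acq, tr_i, seed = seeds[i, 2],
                     subject = sprintf("sub-%02d", i))
  })
}
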