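#' Acquisition and analysis-timing configuration
#'
#' Bundles the scan timing the pipeline needs: repetition time (TR), run
#' length, number of runs, the hemodynamic lag applied before sampling
#' maintenance-period activity, and the canonical double-gamma HRF
#' parameters. The default lag of 4.41 s is exactly 3 TRs of 1.47 s; a lag
#' that is not an integer multiple of TR (within `tol`) is rejected because
#' maintenance windows are shifted on the TR grid.
#'
#' @param tr Repetition time, s.
#' @param run_length Run duration, s.
#' @param n_runs Number of runs.
#' @param lag Hemodynamic lag for maintenance sampling, s.
#' @param highpass_hz Drift high-pass cutoff, Hz.
#' @param hrf_peak,hrf_undershoot,hrf_ratio Double-gamma HRF shape: peak
#'   delay, undershoot delay (s), and undershoot amplitude ratio.
#' @param tol Tolerance for the lag/TR integrality check, s.
#' @return An `acq_config` list; `$lag_samples` holds the integer TR shift.
#' @export
acq_config <- function(tr = 1.47, run_length = 620, n_runs = 4L, lag = 4.41,
                       highpass_hz = 0.006, hrf_peak = 6, hrf_undershoot = 16,
                       hrf_ratio = 1 / 6, tol = 1e-6) {
  assert_scalar_num(tr, "tr", min = 1e-6)
  assert_scalar_num(run_length, "run_length", min = tr)
  k <- lag / tr
  if (abs(k - round(k)) > tol / tr) {
    abort(sprintf("lag (%g s) must be an integer multiple of TR (%g s)", lag, tr))
  }
  structure(
    list(tr = tr, run_length = run_length, n_runs = as.integer(n_runs),
         lag = lag, lag_samples = as.integer(round(k)),
         highpass_hz = highpass_hz,
         hrf = list(peak = hrf_peak, undershoot = hrf_undershoot,
                    ratio = hrf_ratio),
         n_timepoints = as.integer(floor(run_length / tr))),
    class = "acq_config"
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time points, s.
#' @param peak,undershoot Delays of response peak and undershoot, s.
#' @param ratio Undershoot amplitude relative to the peak gamma.
#' @return HRF values at `t`, peak-normalized to 1.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    ratio * dgamma(t, shape = undershoot, rate = 1)
  h / max(dgamma(seq(0, 30, by = 0.01), shape = peak, rate = 1))
}

# HRF-convolved event regressor sampled on the TR grid; the boxcar is built
# on an oversampled grid so sub-TR events are not lost between TR samples
event_regressor <- function(onsets, durations, acq, oversample = 16L) {
  dt <- acq$tr / oversample
  n_fine <- acq$n_timepoints * oversample
  tfine <- (seq_len(n_fine) - 1L) * dt
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    sel <- tfine >= onsets[i] - 1e-9 & tfine < onsets[i] + durations[i] - 1e-9
    x[sel] <- 1
  }
  h <- hrf_double_gamma(seq(0, ceiling(32 / dt)) * dt, acq$hrf$peak,
                        acq$hrf$undershoot, acq$hrf$ratio)
  y <- convolve(x, rev(h), type = "open")[seq_len(n_fine)] * dt
  y[(seq_len(acq$n_timepoints) - 1L) * oversample + 1L]
}
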