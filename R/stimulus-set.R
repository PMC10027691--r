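#' Build an individualized ripple-velocity stimulus set
#'
#' From a listener's just-noticeable difference (JND, in log2 ripple-velocity
#' units) builds the task's stimulus pool: 17 velocities spaced 0.5 * JND in
#' log2 units starting at the lowest velocity (4 cycles/s by default), with
#' the 6 memory-item classes placed every 1.5 * JND — i.e. at pool grid
#' indices 0, 3, 6, 9, 12, 15. Irrelevant items sit a half-JND off the class
#' velocities so relevant and irrelevant items never coincide physically.
#'
#' @param jnd JND in log2 ripple-velocity units (> 0).
#' @param omega_min Lowest pool velocity, cycles/s.
#' @param bounds Allowed velocity range, cycles/s; the pool must fit inside.
#' @param n_pool Pool size (17).
#' @param n_classes Number of memory-item classes (6).
#' @return A `stimulus_set` list with `jnd`, `pool` (tibble: index, omega,
#'   log2_omega), `classes` (tibble: class, pool_index, omega), and
#'   `irrelevant_offset` (log2 units).
#' @export
build_stimulus_set <- function(jnd, omega_min = 4, bounds = c(3, 48),
                               n_pool = 17L, n_classes = 6L) {
  assert_scalar_num(jnd, "jnd", min = 1e-8)
  grid <- log2(omega_min) + 0.5 * jnd * (seq_len(n_pool) - 1L)
  omega <- 2^grid
  if (any(omega < bounds[1] | omega > bounds[2])) {
    abort(sprintf(
      "pool velocities span %.2f-%.2f cycles/s, outside the allowed [%g, %g]",
      min(omega), max(omega), bounds[1], bounds[2]))
  }
  class_idx <- 3L * (seq_len(n_classes) - 1L)        # 1.5 JND = 3 grid steps
  if (max(class_idx) >= n_pool) abort("class spacing exceeds the pool")
  structure(
    list(
      jnd = jnd,
      pool = tibble::tibble(index = seq_len(n_pool) - 1L, omega = omega,
                            log2_omega = grid),
      classes = tibble::tibble(class = seq_len(n_classes),
                               pool_index = class_idx,
                               omega = omega[class_idx + 1L]),
      irrelevant_offset = 0.5 * jnd
    ),
    class = "stimulus_set"
  )
}

#' Generate a retro-cue trial schedule
#'
#' Builds the four-run working-memory task: each run has 24 trials, each of
#' the 6 item classes retro-cued exactly 4 times per run, with the retro-cue
#' pointing at item 1 or item 2 equally often within each class. Per run the
#' probe matches the relevant item on 50% of trials, matches neither item on
#' 25% (`nonmatch_neither`), and matches the irrelevant item on 25%
#' (`irrelevant_match`). The irrelevant item is drawn from a different class
#' and offset by half a JND in log2 velocity. Trial order is shuffled by
#' `seed`; the same seed reproduces the schedule exactly.
#'
#' Within-trial timing (seconds from trial onset): alert cue at 0 (0.5 s),
#' items at 1.0 and 2.5 (1 s each), retro-cue at 4.0 (1 s), a 15-s
#' maintenance period from 5.0, probe at 20.0 (1 s), response cue at 21.5;
#' trials are `trial_dur` apart after an initial `lead_in`.
#'
#' @param stimset A [build_stimulus_set()] result.
#' @param n_runs Number of runs.
#' @param n_trials_per_class Retro-cued repetitions of each class per run.
#' @param seed Integer seed.
#' @param trial_dur Trial-to-trial spacing, s.
#' @param lead_in Silence before the first trial of each run, s.
#' @param maintenance_dur Maintenance (retro-cue to probe gap) duration, s.
#' @return A `trial_schedule`: tibble with one row per trial (run, trial,
#'   class, irrelevant_class, retrocue, probe_type, probe_omega, item and
#'   event onsets) plus attributes `timing` and `stimset`.
#' @export
generate_trial_schedule <- function(stimset, n_runs = 4L,
                                    n_trials_per_class = 4L, seed = 1L,
                                    trial_dur = 25, lead_in = 10,
                                    maintenance_dur = 15) {
  stopifnot(inherits(stimset, "stimulus_set"))
  n_classes <- nrow(stimset$classes)
  n_trials <- n_classes * n_trials_per_class
  if (n_trials_per_class %% 2L != 0L) {
    abort("`n_trials_per_class` must be even to balance retro-cue position")
  }
  # probe mix: 50% match / 25% neither / 25% irrelevant must fit n_trials
  if (n_trials %% 4L != 0L) abort("trials per run must be divisible by 4")
  timing <- list(
    alert_onset = 0, alert_dur = 0.5,
    item1_onset = 1.0, item2_onset = 2.5, item_dur = 1.0,
    retrocue_onset = 4.0, retrocue_dur = 1.0,
    maintenance_onset = 5.0, maintenance_dur = maintenance_dur,
    probe_onset = 5.0 + maintenance_dur, probe_dur = 1.0,
    response_onset = 6.5 + maintenance_dur,
    trial_dur = trial_dur, lead_in = lead_in
  )
  cls <- stimset$classes
  runs <- with_seed_if(seed, purrr::map(seq_len(n_runs), function(r) {
    class_seq <- rep(cls$class, each = n_trials_per_class)
    retrocue <- as.vector(vapply(seq_len(n_classes), function(i) {
      sample(rep(1:2, n_trials_per_class / 2L))
    }, integer(n_trials_per_class)))
    probe_type <- sample(rep(
      c("match", "nonmatch_neither", "irrelevant_match"),
      times = n_trials * c(0.5, 0.25, 0.25)
    ))
    ord <- sample.int(n_trials)
    tb <- tibble::tibble(
      run = r, trial = seq_len(n_trials),
      class = class_seq[ord], retrocue = retrocue[ord],
      probe_type = probe_type
    )
    # irrelevant item: another class, offset half a JND in log2 velocity
    tb$irrelevant_class <- vapply(tb$class, function(c0) {
      sample(setdiff(cls$class, c0), 1L)
    }, 1L)
    off <- sample(c(-1, 1), n_trials, replace = TRUE) * stimset$irrelevant_offset
    tb$irrelevant_omega <- 2^(log2(cls$omega[tb$irrelevant_class]) + off)
    tb$relevant_omega <- cls$omega[tb$class]
    tb$item1_class <- ifelse(tb$retrocue == 1L, tb$class, tb$irrelevant_class)
    tb$item2_class <- ifelse(tb$retrocue == 2L, tb$class, tb$irrelevant_class)
    tb$probe_omega <- dplyr::case_when(
      tb$probe_type == "match" ~ tb$relevant_omega,
      tb$probe_type == "irrelevant_match" ~ tb$irrelevant_omega,
      TRUE ~ purrr::map_dbl(tb$irrelevant_omega, function(w_irr) {
        cand <- stimset$pool$omega[-(cls$pool_index + 1L)]
        sample(cand[abs(log2(cand) - log2(w_irr)) > 1e-9], 1L)
      })
    )
    tb$trial_onset <- lead_in + (tb$trial - 1L) * trial_dur
    tb
  }))
  sched <- dplyr::bind_rows(runs)
  sched$retrocue_onset <- sched$trial_onset + timing$retrocue_onset
  sched$maintenance_onset <- sched$trial_onset + timing$maintenance_onset
  sched$probe_onset <- sched$trial_onset + timing$probe_onset
  attr(sched, "timing") <- timing
  attr(sched, "stimset") <- stimset
  attr(sched, "seed") <- as.integer(seed)
  class(sched) <- c("trial_schedule", class(sched))
  sched
}

#' Expand a trial schedule into a long events table
#'
#' One row per stimulus/cue event in the BIDS `events.tsv` convention
#' (onset, duration, trial_type), carrying run, trial, class and probe-type
#' columns for downstream modeling.
#'
#' @param schedule A [generate_trial_schedule()] result.
#' @return Tibble with columns onset, duration, trial_type, run, trial,
#'   class, probe_type.
#' @export
schedule_events <- function(schedule) {
  tm <- attr(schedule, "timing")
  ev_def <- tibble::tribble(
    ~trial_type, ~offset,             ~duration,
    "alert",     tm$alert_onset,      tm$alert_dur,
    "item1",     tm$item1_onset,      tm$item_dur,
    "item2",     tm$item2_onset,      tm$item_dur,
    "retrocue",  tm$retrocue_onset,   tm$retrocue_dur,
    "probe",     tm$probe_onset,      tm$probe_dur,
    "response",  tm$response_onset,   0.5
  )
  tidyr::crossing(
    dplyr::select(tibble::as_tibble(schedule), "run", "trial", "trial_onset",
                  "class", "probe_type"),
    ev_def
  ) |>
    dplyr::mutate(onset = .data$trial_onset + .data$offset) |>
    dplyr::select("onset", "duration", "trial_type", "run", "trial", "class",
                  "probe_type") |>
    dplyr::arrange(.data$run, .data$onset)
}

#' Write/read an events table as tab-separated text
#'
#' @param events Tibble from [schedule_events()].
#' @param path File path.
#' @return `path` / the events tibble.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
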