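# shared fixtures: everything is generated in code at test time

# a small registry with controllable subROI counts
toy_registry <- function(counts = c(A = 3, B = 4, C = 2)) {
  tibble::tibble(
    roi = names(counts),
    area = names(counts),
    hemisphere = rep_len(c("left", "right"), length(counts)),
    n_subrois = as.integer(counts),
    inferred = FALSE
  )
}

# pattern_features with a given feature matrix (24 exemplars by default)
toy_features <- function(x, classes = rep(1:6, 4), runs = rep(1:4, each = 6),
                         unit = "toy") {
  wmconn:::new_pattern_features(x, classes, runs, unit = unit, network = unit)
}

# linearly separable features: orthogonal class codes plus small noise
separable_features <- function(n_classes = 6, n_runs = 4, noise = 0.01,
                               seed = 1) {
  withr::with_seed(seed, {
    classes <- rep(seq_len(n_classes), n_runs)
    runs <- rep(seq_len(n_runs), each = n_classes)
    x <- diag(n_classes)[classes, ] * 5 +
      matrix(rnorm(length(classes) * n_classes, sd = noise), length(classes))
    toy_features(x, classes, runs)
  })
}

# signal-free random features (chance decodable only)
noise_features <- function(n_feat = 10, seed = 1) {
  withr::with_seed(seed, toy_features(matrix(rnorm(24 * n_feat), 24)))
}

# fast small-session settings used across tests: short runs, few trials
toy_acq <- function(...) acq_config(run_length = 310, ...)

# 12 trials/run (2 per class) so sessions fit the short toy_acq runs
toy_schedule <- function(seed = 1, n_runs = 4, n_trials_per_class = 2) {
  generate_trial_schedule(build_stimulus_set(0.2), n_runs = n_runs,
                          n_trials_per_class = n_trials_per_class,
                          seed = seed, trial_dur = 25, lead_in = 5)
}

# brute-force subset enumerator used as the independent combinatorics oracle
brute_subsets <- function(items, sizes) {
  out <- list()
  n <- length(items)
  for (mask in seq_len(2^n) - 1L) {
    sel <- items[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(sel) %in% sizes) out[[length(out) + 1L]] <- sort(sel)
  }
  out
}
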