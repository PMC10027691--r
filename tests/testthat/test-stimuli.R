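test_that("ripple synthesis has the right length, Nyquist guard and seeding", {
  spec <- ripple_spec(omega = 4, seed = 11)
  w <- synthesize_ripple(spec, sample_rate = 16000)
  expect_length(w, 16000L)
  expect_equal(max(abs(w)), 10^(-3 / 20), tolerance = 1e-12)
  expect_identical(as.numeric(w),
                   as.numeric(synthesize_ripple(spec, sample_rate = 16000)))
  expect_error(synthesize_ripple(spec, sample_rate = 3000), "Nyquist|sample_rate")
  expect_error(ripple_spec(omega = 4, depth = 1.5, base = 1), "depth")
})

test_that("zero spectral density reduces the envelope to a pure omega sinusoid", {
  # with Omega = 0 every carrier shares the envelope D0 + D cos(2 pi w t + psi),
  # so the modulated wave divided by the unmodulated wave recovers it exactly
  sr <- 8000
  base <- ripple_spec(omega = 4, Omega = 0, f_hi = 800, depth = 0, seed = 5)
  mod <- ripple_spec(omega = 4, Omega = 0, f_hi = 800, depth = 0.9, seed = 5)
  w0 <- synthesize_ripple(base, sr, peak = 1)
  w1 <- synthesize_ripple(mod, sr, peak = 1)
  t <- (seq_along(w0) - 1) / sr
  keep <- abs(w0) > 0.05 * max(abs(w0))
  ratio <- w1[keep] / w0[keep]
  expected <- 1 + 0.9 * cos(2 * pi * 4 * t[keep])
  expect_gt(cor(ratio, expected), 0.9999)
})

test_that("modulation off gives near-zero envelope flux; on gives omega-rate flux", {
  # band-limited envelope oracle: FFT band isolation around one carrier, then
  # the dominant envelope frequency should equal the ripple velocity
  sr <- 8000
  spec <- ripple_spec(omega = 4, Omega = 1, f_hi = 800, depth = 0.9, seed = 3)
  w <- as.numeric(synthesize_ripple(spec, sr))
  n <- length(w)
  freqs <- (seq_len(n) - 1) * sr / n
  band_env <- function(w, lo, hi) {
    X <- fft(w)
    keep <- (freqs >= lo & freqs <= hi) | (freqs >= sr - hi & freqs <= sr - lo)
    X[!keep] <- 0
    abs(Re(fft(X, inverse = TRUE)) / n) # rectified band signal ~ envelope
  }
  env <- band_env(w, 350, 450)
  E <- Mod(fft(env - mean(env)))[2:40]          # bins 1..39 -> 1..39 Hz
  expect_equal(which.max(E), 4L + 1L - 1L)       # dominant envelope bin at 4 Hz
  # depth 0: no envelope modulation anywhere near the ripple rate
  w0 <- as.numeric(synthesize_ripple(
    ripple_spec(omega = 4, Omega = 1, f_hi = 800, depth = 0, seed = 3), sr))
  env0 <- band_env(w0, 350, 450)
  E0 <- Mod(fft(env0 - mean(env0)))[2:40]
  # at the ripple rate itself, the unmodulated envelope carries ~no energy
  expect_lt(E0[4] / E[4], 0.1)
})

test_that("WAV files round-trip through the PCM writer", {
  spec <- ripple_spec(omega = 8, f_hi = 800, seed = 2)
  w <- synthesize_ripple(spec, 4000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(attr(back, "sample_rate"), 4000L)
  expect_lt(max(abs(as.numeric(back) - as.numeric(w))), 1 / 32767)
  expect_equal(file.size(path), 44 + 2 * length(w))
})

test_that("staircase converges to the rule's analytic target", {
  expect_equal(staircase_target("2d1u"), sqrt(0.5))
  expect_equal(staircase_target("1d2u"), 1 - sqrt(0.5))
  expect_equal(staircase_target("1d1u"), 0.5)

  # 2-down/1-up with a logistic listener: reversals hover at the 70.7% point
  thr <- 0.4; slope <- 6; guess <- 0.5
  target_p <- staircase_target("2d1u")
  x_star <- thr - log((1 - guess) / (target_p - guess) - 1) / slope
  run <- withr::with_seed(42, run_staircase(
    logistic_listener(thr, slope, guess), rule = "2d1u", start = 1.2,
    step = 0.15, n_reversals = 250, n_final = 220
  ))
  expect_true(run$converged)
  # reversal mean lands near the analytic point; the observed proportion
  # correct in the converged tail matches the rule's 70.7% target
  expect_equal(run$jnd, x_star, tolerance = 0.15)
  tail_track <- run$track[run$track$trial > nrow(run$track) / 3, ]
  expect_equal(mean(tail_track$correct), target_p, tolerance = 0.05)

  # printed-but-unconventional rule warns and targets 29.3%
  expect_warning(
    run_staircase(logistic_listener(0.4), rule = "1d2u", n_reversals = 4,
                  seed = 1),
    "29.3"
  )
})

test_that("staircase is monotone for a perfect listener and deterministic", {
  always_right <- function(interval) TRUE
  run <- run_staircase(always_right, rule = "2d1u", start = 1, step = 0.1,
                       n_reversals = 5, max_trials = 300, quiet = TRUE)
  # no up-steps ever: interval decreases to the floor and never reverses
  expect_false(run$converged)
  expect_true(all(diff(run$track$interval) <= 0))
  expect_equal(min(run$track$interval), 0.01)

  noisy <- logistic_listener(0.5, 4)
  r1 <- run_staircase(noisy, rule = "2d1u", n_reversals = 20, seed = 7)
  r2 <- run_staircase(noisy, rule = "2d1u", n_reversals = 20, seed = 7)
  expect_identical(r1$track, r2$track)
})

test_that("stimulus set spaces the pool and classes on the JND grid", {
  ss <- build_stimulus_set(0.2)
  expect_equal(nrow(ss$pool), 17L)
  expect_equal(nrow(ss$classes), 6L)
  expect_equal(ss$classes$pool_index, c(0L, 3L, 6L, 9L, 12L, 15L))
  expect_equal(diff(log2(ss$classes$omega)), rep(1.5 * 0.2, 5))
  expect_equal(diff(ss$pool$log2_omega), rep(0.5 * 0.2, 16))
  expect_equal(ss$pool$omega[1], 4)
  expect_equal(ss$irrelevant_offset, 0.1)
  # a JND so large the pool escapes the allowed velocity range
  expect_error(build_stimulus_set(1.0), "outside")
})

test_that("trial schedules satisfy the design contract", {
  ss <- build_stimulus_set(0.2)
  sch <- generate_trial_schedule(ss, seed = 9)
  expect_equal(nrow(sch), 96L)
  expect_equal(unname(table(sch$run)), rep(24L, 4), ignore_attr = TRUE)
  # retro-cued class appears exactly 4 times per run
  for (r in 1:4) {
    expect_equal(unname(table(sch$class[sch$run == r])), rep(4L, 6),
                 ignore_attr = TRUE)
  }
  expect_equal(sum(sch$probe_type == "match"), 48L)
  expect_equal(sum(sch$probe_type == "nonmatch_neither"), 24L)
  expect_equal(sum(sch$probe_type == "irrelevant_match"), 24L)
  tm <- attr(sch, "timing")
  expect_equal(tm$maintenance_dur, 15)
  expect_equal(sch$probe_onset - sch$retrocue_onset, rep(16, 96))
})

test_that("schedule generation is a seed-determined bijection with held invariants", {
  ss <- build_stimulus_set(0.25)
  for (seed in c(1, 7, 23, 101, 4242)) {
    sch <- generate_trial_schedule(ss, seed = seed)
    expect_equal(nrow(sch), 96L)
    for (r in 1:4) {
      sub <- sch[sch$run == r, ]
      expect_equal(unname(table(sub$class)), rep(4L, 6), ignore_attr = TRUE)
      # retro-cue position balanced within class and run
      expect_true(all(tapply(sub$retrocue == 2L, sub$class, sum) == 2))
      expect_equal(sum(sub$probe_type == "match"), 12L)
    }
    # the cued item matches the class; the other item is the irrelevant one
    cued <- ifelse(sch$retrocue == 1L, sch$item1_class, sch$item2_class)
    other <- ifelse(sch$retrocue == 1L, sch$item2_class, sch$item1_class)
    expect_equal(cued, sch$class)
    expect_equal(other, sch$irrelevant_class)
    expect_true(all(sch$irrelevant_class != sch$class))
    # probe never matches the irrelevant item except on irrelevant_match trials
    nm <- sch$probe_type == "nonmatch_neither"
    expect_true(all(abs(log2(sch$probe_omega[nm]) -
                          log2(sch$irrelevant_omega[nm])) > 1e-9))
    expect_true(all(abs(log2(sch$probe_omega[nm]) -
                          log2(sch$relevant_omega[nm])) > 1e-9))
  }
  s1 <- generate_trial_schedule(ss, seed = 5)
  s2 <- generate_trial_schedule(ss, seed = 5)
  s3 <- generate_trial_schedule(ss, seed = 6)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_false(identical(tibble::as_tibble(s1), tibble::as_tibble(s3)))
})

test_that("events tables expand trials and round-trip through TSV", {
  sch <- toy_schedule(seed = 2)
  ev <- schedule_events(sch)
  expect_equal(nrow(ev), nrow(sch) * 6L)
  expect_setequal(unique(ev$trial_type),
                  c("alert", "item1", "item2", "retrocue", "probe", "response"))
  expect_true(all(diff(ev$onset[ev$run == 1]) >= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
})
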