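test_that("drift order follows the high-pass cutoff rule", {
  acq600 <- acq_config(run_length = 600.6, tr = 1.47)  # ~600 s run
  ev <- schedule_events(toy_schedule())
  X <- build_design_matrix(ev[ev$run == 1, ], acq600)
  blocks <- attr(X, "blocks")
  # order = max(1, round(2 * 0.006 * 600.6)) = 7 -> 8 polynomial columns
  expect_length(blocks$drift, 8L)
  expect_length(blocks$events, 6L)
  # drift-only design when there are no events
  empty <- ev[0, ]
  X0 <- build_design_matrix(empty, toy_acq())
  expect_equal(ncol(X0), length(attr(X0, "blocks")$drift))
  # content flag adds exactly one column per class
  sch <- toy_schedule()
  Xc <- build_design_matrix(ev[ev$run == 1, ], toy_acq(),
                            content_regressors = TRUE, schedule = sch)
  expect_length(attr(Xc, "blocks")$content, 6L)
  expect_error(build_design_matrix(ev, toy_acq()), "one run")
})

test_that("legendre basis matches the closed-form low orders", {
  P <- legendre_basis(101, 3)
  x <- seq(-1, 1, length.out = 101)
  expect_equal(P[, 1], rep(1, 101))
  expect_equal(P[, 2], x)
  expect_equal(P[, 3], (3 * x^2 - 1) / 2)
  expect_equal(P[, 4], (5 * x^3 - 3 * x) / 2)
})

test_that("residualization is orthogonal, exact on design columns, idempotent", {
  acq <- toy_acq()
  ev <- schedule_events(toy_schedule())
  X <- build_design_matrix(ev[ev$run == 1, ], acq)
  set.seed(3)
  ts <- matrix(rnorm(5 * nrow(X)), 5)
  # a row equal to a design column residualizes to ~0
  ts[1, ] <- X[, 2]
  res <- residualize(ts, X)
  expect_lt(max(abs(res[1, ])), 1e-10)
  # residuals orthogonal to every column
  for (j in seq_len(ncol(X))) {
    cs <- abs(res %*% X[, j]) / (sqrt(rowSums(res^2)) * sqrt(sum(X[, j]^2)))
    expect_lt(max(cs[is.finite(cs)]), 1e-10)
  }
  expect_equal(residualize(res, X), res, tolerance = 1e-12)
})

test_that("the drift block removes slow oscillations below the cutoff", {
  acq <- acq_config(run_length = 620)
  ev <- schedule_events(toy_schedule())[0, ]
  X <- build_design_matrix(ev, acq)
  t <- (seq_len(acq$n_timepoints) - 1) * acq$tr
  slow <- sin(2 * pi * 0.003 * t)
  ts <- rbind(slow + rnorm(length(t), sd = 0.1))
  res <- residualize(ts, X)
  power_at <- function(x, f) {
    Mod(sum(x * exp(-2i * pi * f * t)))^2
  }
  expect_lt(power_at(res[1, ], 0.003) / power_at(ts[1, ], 0.003), 0.05)
})

test_that("maintenance segments shift by the lag and conserve samples", {
  acq <- toy_acq()
  expect_equal(acq$lag_samples, 3L)  # 4.41 s / 1.47 s
  expect_error(acq_config(lag = 4.0), "integer multiple")

  sch <- toy_schedule(seed = 4)
  n_sub <- 7
  resid <- purrr::map(1:4, function(r) {
    matrix(seq_len(n_sub * acq$n_timepoints), n_sub)
  })
  segs <- extract_maintenance_segments(resid, sch, acq)
  expect_equal(nrow(segs), 4L * 6L)
  expect_true(all(segs$n_samples > 0))
  # per run: sum of class segment lengths equals sum of trial window lengths
  for (r in 1:4) {
    sub <- sch[sch$run == r, ]
    win_len <- vapply(seq_len(nrow(sub)), function(k) {
      i0 <- floor((sub$retrocue_onset[k] + acq$lag) / acq$tr) + 1
      i1 <- ceiling((sub$probe_onset[k] + acq$lag) / acq$tr)
      i1 - i0 + 1
    }, 1)
    expect_equal(sum(segs$n_samples[segs$run == r]), sum(win_len))
  }
  # all trials of one class share the same window length here, so 2 trials/class
  expect_true(all(segs$n_samples %% 2 == 0))

  # the lag literally shifts the sampled columns by 3 TRs
  segs0 <- extract_maintenance_segments(resid, sch,
                                        acq_config(run_length = 310, lag = 0))
  shift <- segs$segment[[1]][1, 1] - segs0$segment[[1]][1, 1]
  expect_equal(shift %% n_sub, 0)
  expect_equal((shift / n_sub), 3)
})

test_that("irrelevant-item relabeling permutes classes but conserves samples", {
  acq <- toy_acq()
  sch <- toy_schedule(seed = 8)
  resid <- purrr::map(1:4, function(r) matrix(rnorm(5 * acq$n_timepoints), 5))
  wm <- extract_maintenance_segments(resid, sch, acq, label_source = "wm_item")
  irr <- extract_maintenance_segments(resid, sch, acq,
                                      label_source = "irrelevant_item")
  expect_equal(sum(wm$n_samples), sum(irr$n_samples))
  # within a run the irrelevant labels redistribute trials across classes
  expect_false(identical(wm$n_samples, irr$n_samples) &&
                 identical(purrr::map(wm$segment, dim),
                           purrr::map(irr$segment, dim)) &&
                 isTRUE(all.equal(wm$segment, irr$segment)))
})

test_that("trials whose lagged window leaves the run are dropped with a warning", {
  acq <- acq_config(run_length = 300)  # too short for the last trials
  sch <- toy_schedule(seed = 1)
  resid <- purrr::map(1:4, function(r) matrix(rnorm(3 * acq$n_timepoints), 3))
  warns <- testthat::capture_warnings(
    segs <- extract_maintenance_segments(resid, sch, acq)
  )
  expect_gte(length(warns), 1L)
  expect_true(all(grepl("dropping", warns)))
  expect_true(all(segs$n_samples >= 0))
})

test_that("content betas recover injected class responses", {
  acq <- toy_acq()
  sch <- toy_schedule(seed = 6)
  ev <- schedule_events(sch)
  # unit 1 follows the class-3 content regressor; unit 2 is silent
  ts_runs <- purrr::map(1:4, function(r) {
    Xr <- build_design_matrix(ev[ev$run == r, ], acq,
                              content_regressors = TRUE, schedule = sch)
    j <- attr(Xr, "blocks")$content[3]
    rbind(5 * Xr[, j] + rnorm(nrow(Xr), sd = 0.05),
          rep(0, nrow(Xr)))
  })
  bet <- content_betas(ts_runs, sch, acq)
  expect_equal(nrow(bet), 24L)  # 4 runs x 6 classes
  b3 <- do.call(rbind, bet$beta[bet$class == 3])
  b_other <- do.call(rbind, bet$beta[bet$class != 3])
  expect_gt(min(b3[, 1]), 4)          # recovered amplitude near 5
  expect_lt(max(abs(b_other[, 1])), 1)
  expect_lt(max(abs(c(b3[, 2], b_other[, 2]))), 0.5)  # silent unit ~ 0
})
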