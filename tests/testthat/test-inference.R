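test_that("within-run shuffles conserve per-run label multisets", {
  labels <- rep(1:6, 4)
  runs <- rep(1:4, each = 6)
  for (seed in 1:20) {
    p <- permute_labels_within_runs(labels, runs, seed = seed)
    for (r in 1:4) {
      expect_equal(sort(p[runs == r]), 1:6)
    }
  }
  expect_identical(permute_labels_within_runs(labels, runs, seed = 3),
                   permute_labels_within_runs(labels, runs, seed = 3))
})

test_that("within-block arrangements are uniform (exact 3! enumeration)", {
  labels <- c(1L, 2L, 3L)
  runs <- c(1L, 1L, 1L)
  draws <- withr::with_seed(99, {
    vapply(1:10000, function(i) {
      paste(permute_labels_within_runs(labels, runs), collapse = "")
    }, "")
  })
  tab <- table(factor(draws, levels = c("123", "132", "213", "231", "312", "321")))
  expect_length(tab, 6L)
  chi <- stats::chisq.test(tab, p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 1e-4)
})

test_that("p-value convention floors at 1/n_perm with ties against the observation", {
  null <- structure(list(max_stats = seq(0.1, 0.6, length.out = 500),
                         n_perm = 500L, n_units = 1L, n_subjects = 2L,
                         seed = 1L), class = "wm_null")
  expect_equal(assign_pvalue(0.99, null), 1 / 500)
  expect_equal(assign_pvalue(0.99, null), 0.002)
  expect_equal(assign_pvalue(median(null$max_stats), null), 0.5, tolerance = 0.01)
  expect_equal(assign_pvalue(0.0, null), 1.0)
  # ties count toward the null
  tied <- structure(list(max_stats = rep(0.5, 10), n_perm = 10L, n_units = 1L,
                         n_subjects = 2L, seed = 1L), class = "wm_null")
  expect_equal(assign_pvalue(0.5, tied), 1.0)
})

test_that("a single-unit family's null is the unit's own permutation distribution", {
  withr::with_seed(21, {
    grams1 <- list(list(tcrossprod(matrix(rnorm(24 * 10), 24)),
                        tcrossprod(matrix(rnorm(24 * 10), 24))))
  })
  labels <- list(rep(1:6, 4), rep(1:6, 4))
  runs <- list(rep(1:4, each = 6), rep(1:4, each = 6))
  n1 <- build_null(grams1, labels, runs, n_perm = 50, seed = 5)
  expect_length(n1$max_stats, 50L)
  # duplicating the unit leaves the family maximum unchanged
  n2 <- build_null(c(grams1, grams1), labels, runs, n_perm = 50, seed = 5)
  expect_equal(n1$max_stats, n2$max_stats)
  expect_true(all(n1$max_stats >= 0 & n1$max_stats <= 1))
})

test_that("the family maximum stochastically dominates single-unit nulls", {
  withr::with_seed(33, {
    grams <- purrr::map(1:10, function(u) {
      purrr::map(1:3, function(s) tcrossprod(matrix(rnorm(24 * 8), 24)))
    })
  })
  labels <- purrr::map(1:3, function(s) rep(1:6, 4))
  runs <- purrr::map(1:3, function(s) rep(1:4, each = 6))
  fam <- build_null(grams, labels, runs, n_perm = 100, seed = 2)
  one <- build_null(grams[1], labels, runs, n_perm = 100, seed = 2)
  # same seed -> same shuffles, so the max over 10 units dominates pointwise
  expect_true(all(fam$max_stats >= one$max_stats))
  # order-statistic effect: family null is centered above chance
  expect_gt(mean(fam$max_stats), 1 / 6)
})

test_that("family analysis flags a planted network and respects controls", {
  reg <- toy_registry(c(A = 6, B = 6, C = 6, D = 6, E = 6))
  nets <- enumerate_networks(reg, 2:3)
  fam_nets <- subsample_networks(nets, 8, keep = "A+B+C", seed = 1)
  expect_true("A+B+C" %in% fam_nets$network)
  # controls share at most one ROI with the planted network
  overlap <- vapply(fam_nets$members, function(m) {
    length(intersect(m, c("A", "B", "C")))
  }, 1L)
  expect_true(all(overlap[fam_nets$network != "A+B+C"] <= 1))

  coh <- simulate_cohort(4, reg, acq_config(),
                         ground_truth(list(c("A", "B", "C")), coupling = 0.8),
                         build_stimulus_set(0.2), seed = 17)
  fam <- run_family_analysis(coh, fam_nets, n_perm = 49, seed = 3)
  rep <- tidy(fam)
  expect_true(rep$significant[rep$unit == "A+B+C"])
  expect_equal(rep$p[rep$unit == "A+B+C"], 1 / 49)
  expect_s3_class(glance(fam), "tbl_df")
  expect_s3_class(autoplot(fam), "ggplot")
  expect_s3_class(autoplot(fam$null, observed = 0.5), "ggplot")

  # irrelevant-item relabeling destroys the planted signal
  irr <- run_family_analysis(coh, fam_nets, mode = "irrelevant-item",
                             n_perm = 49, seed = 3)
  expect_lt(tidy(irr)$observed[tidy(irr)$unit == "A+B+C"],
            rep$observed[rep$unit == "A+B+C"] - 0.2)
})

test_that("family analysis is reproducible and p-values ignore unit order", {
  reg <- toy_registry(c(A = 6, B = 6, C = 6))
  nets <- enumerate_networks(reg, 2)
  coh <- simulate_cohort(3, reg, acq_config(),
                         ground_truth(list(c("A", "B")), coupling = 0.5),
                         build_stimulus_set(0.2), seed = 8)
  f1 <- run_family_analysis(coh, nets, n_perm = 29, seed = 11)
  f2 <- run_family_analysis(coh, nets, n_perm = 29, seed = 11)
  expect_identical(tidy(f1), tidy(f2))
  # reversing the family order leaves each unit's p unchanged
  f3 <- run_family_analysis(coh, nets[3:1, ], n_perm = 29, seed = 11)
  r1 <- dplyr::arrange(tidy(f1), .data$unit)
  r3 <- dplyr::arrange(tidy(f3), .data$unit)
  expect_equal(r1$p, r3$p)
  expect_equal(r1$observed, r3$observed)
})

test_that("within-ROI and activation modes run end to end", {
  reg <- toy_registry(c(A = 6, B = 6))
  coh <- simulate_cohort(3, reg, acq_config(),
                         ground_truth(list(c("A", "B")), coupling = 0.7),
                         build_stimulus_set(0.2), seed = 30)
  wr <- run_family_analysis(coh, mode = "within-roi", n_perm = 19, seed = 1)
  expect_equal(nrow(tidy(wr)), 2L)
  act <- run_family_analysis(coh, mode = "activation", n_perm = 19, seed = 1)
  expect_equal(nrow(tidy(act)), 2L)
  # amplitudes are class-exchangeable by construction: activation decoding
  # carries no content even though connectivity does
  conn <- run_family_analysis(coh, enumerate_networks(reg, 2),
                              n_perm = 19, seed = 1)
  expect_gt(max(tidy(conn)$observed), max(tidy(act)$observed))
})
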