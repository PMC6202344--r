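test_that("a dyad runs 20 epochs of 5 trials and is seed-reproducible", {
  d <- run_dyad(0.55, 1.3e-5, seed = 101)
  expect_s3_class(d, "hl_cohort")
  expect_identical(dim(d$choice), c(1L, 20L))
  expect_identical(dim(d$trials$o), c(1L, 20L, 5L))

  d2 <- run_dyad(0.55, 1.3e-5, seed = 101)
  expect_identical(d$trials, d2$trials)
  expect_identical(d$epoch_err, d2$epoch_err)

  expect_error(run_dyad(0.55, 1.3e-5, n_epochs = 0L, seed = 1))
})

test_that("the vectorised engine reproduces the single-dyad path", {
  d <- run_dyad(0.7, 5e-5, seed = 55)
  co <- run_cohort(1, 0.7, 5e-5, seed = 55)
  expect_identical(d$w, co$w)
  expect_identical(d$choice, co$choice)
  expect_identical(d$feedback, co$feedback)
  expect_identical(d$v_final, co$v_final)
})

test_that("recorded trajectories replay exactly through the epoch-level ops", {
  co <- run_cohort(4, 0.55, 1.3e-5, n_epochs = 10L, seed = 77,
                   keep_trials = TRUE)
  for (i in seq_len(co$n_dyads)) {
    v <- co$v0[i, ]
    a <- c(0, 0, 0)
    for (t in seq_len(co$n_epochs)) {
      chosen <- co$choice[i, t]
      f <- filter_indicator(chosen)
      pcts <- numeric(5)
      for (tr in 1:5) {
        x <- co$trials$x[i, , t, tr]
        y <- compute_target(co$w[i, ], x)
        o <- l_estimate(v, x, f)
        expect_equal(o, co$trials$o[i, t, tr], tolerance = 1e-10)
        expect_equal(y, co$trials$y[i, t, tr], tolerance = 1e-10)
        pcts[tr] <- percent_error(y, o)
        v <- l_update_weights(v, x, f, y, o, 1.3e-5)
      }
      expect_equal(mean(pcts), co$feedback[i, t], tolerance = 1e-10)
      a <- update_attraction(a, chosen, mean(pcts))
      expect_equal(a, co$a_hist[i, , t], tolerance = 1e-10)
      expect_equal(v, co$v_hist[i, , t], tolerance = 1e-10)
    }
  }
})

test_that("run_epoch composes the agent-level operations", {
  inputs <- matrix(c(10, 20, 30,
                     40, 50, 60,
                     0, 0, 0,
                     100, 100, 100,
                     5, 5, 5), 5, 3, byrow = TRUE)
  w <- c(0.9, 0.5, 0.1)
  res <- run_epoch(attractions = c(0, 0, 0), v = c(0.5, 0.5, 0.5), w = w,
                   gamma = 0.55, lambda = 0, inputs = inputs,
                   select_u = 0)   # u = 0 selects filter 1
  expect_identical(res$chosen, 1L)
  expect_equal(res$trials$y, apply(inputs, 1, compute_target, w = w))
  expect_equal(res$trials$o,
               apply(inputs, 1, l_estimate, v = c(0.5, 0.5, 0.5),
                     f = c(0, 1, 1)))
  expect_equal(res$feedback, mean(res$trials$pct_err))
  expect_equal(res$attractions, c(max(0, 100 - res$feedback), 0, 0))
  expect_equal(res$v, c(0.5, 0.5, 0.5))  # lambda = 0
})

test_that("feedback equals the mean of the epoch's per-trial percent errors", {
  co <- run_cohort(20, 0.55, 1.3e-5, seed = 31, keep_trials = TRUE)
  pct <- 100 * abs(co$trials$y - co$trials$o) / co$trials$y
  pct[co$trials$y == 0] <- 0
  expect_equal(apply(pct, c(1, 2), mean), co$feedback, tolerance = 1e-10)
  # exactly one attraction changes per epoch
  prev <- matrix(0, 20, 3)
  for (t in seq_len(co$n_epochs)) {
    changed <- rowSums(co$a_hist[, , t] != prev)
    expect_true(all(changed <= 1))
    prev <- co$a_hist[, , t]
  }
})

test_that("no-learning parameters compose into no-ops", {
  co <- run_cohort(30, gamma = 0, lambda = 0, seed = 13, keep_trials = FALSE)
  # L weights never move
  expect_equal(co$v_hist[, , co$n_epochs], co$v0, tolerance = 1e-12)
  # attractions still accumulate reinforcement
  expect_true(any(co$attractions > 0))
})

test_that("two disjoint seeds give statistically indistinguishable cohorts", {
  a <- last_epochs_error(run_cohort(2000, 0.55, 1.3e-5, seed = 1001,
                                    keep_trials = FALSE))
  b <- last_epochs_error(run_cohort(2000, 0.55, 1.3e-5, seed = 2002,
                                    keep_trials = FALSE))
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("the baseline cohort shows a decreasing mean learning curve", {
  co <- run_cohort(2000, 0.55, 1.3e-5, seed = 303, keep_trials = FALSE)
  curve <- cohort_mean_curves(co)$error
  expect_lt(curve[20], 0.6 * curve[1])
  expect_lt(stats::coef(stats::lm(curve ~ seq_along(curve)))[2], 0)
  # local noise only: no epoch-to-epoch increase beyond a small wiggle
  expect_true(all(diff(curve) < 0.25))
})

test_that("fixed-filter ablation orders cohorts by disclosed information", {
  opt <- run_ablation_fixed_filter("optimal", lambda = 1.3e-5,
                                   n_dyads = 1000, seed = 17,
                                   keep_trials = FALSE)
  wst <- run_ablation_fixed_filter("worst", lambda = 1.3e-5,
                                   n_dyads = 1000, seed = 18,
                                   keep_trials = FALSE)
  expect_lt(mean(last_epochs_error(opt)), mean(last_epochs_error(wst)))
  expect_identical(unique(as.vector(opt$choice - opt$opt_hidden)), 0L)
  # lambda = 0: no trend in errors over epochs
  flat <- run_ablation_fixed_filter("optimal", lambda = 0, n_dyads = 1000,
                                    seed = 19, keep_trials = FALSE)
  curve <- cohort_mean_curves(flat)$error
  expect_lt(abs(stats::coef(stats::lm(curve ~ seq_along(curve)))[2]), 0.05)
})

test_that("the statistical H-agent samples round-robin then commits forever", {
  s <- 2L
  co <- run_statistical_H(s, lambda = 1.3e-5, n_dyads = 50,
                          n_epochs = 12L, seed = 71, keep_trials = FALSE)
  expect_true(all(co$choice[, seq_len(3 * s)] ==
                    matrix(rep(1:3, s), 50, 3 * s, byrow = TRUE)))
  post <- co$choice[, (3 * s + 1L):co$n_epochs, drop = FALSE]
  expect_identical(max(switch_rate(post)), 0)  # once and for all
  expect_true(all(post[, 1L] == co$committed))
  expect_true(all(!is.na(co$commit_p)))
  expect_error(run_statistical_H(5L, lambda = 0, n_dyads = 2, n_epochs = 10L,
                                 seed = 1))
})
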