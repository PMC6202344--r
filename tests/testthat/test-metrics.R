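test_that("epoch error curves follow their closed forms", {
  # frozen correct weights + optimal filter: error is exactly 0.1 x_hidden
  co <- dyadlearn:::cohort_engine(10, 20, gamma = 0, lambda = 0, seed = 21,
                                  h_mode = "fixed", fixed = "optimal",
                                  l_learn = FALSE, l_init = "correct",
                                  keep_trials = TRUE)
  hid <- co$opt_hidden
  for (i in 1:10) {
    xh <- co$trials$x[i, hid[i], , ]           # epochs x trials
    expect_equal(epoch_error_curve(co)[i, ], rowMeans(0.1 * xh),
                 tolerance = 1e-9)
  }
  # the long-run error equals the mean of the final 25 per-trial errors
  err25 <- abs(co$trials$y - co$trials$o)[, 16:20, ]
  expect_equal(last_epochs_error(co), apply(err25, 1, mean),
               tolerance = 1e-12)
})

test_that("the lowest attainable error benchmark is 2.5", {
  expect_identical(lowest_attainable_error(), 2.5)
  # brute force on the integer grid 0..100
  grid_mean <- sum(abs(0:100 - 50)) / 101
  expect_equal(lowest_attainable_error(discrete = TRUE), 0.1 * grid_mean)
  expect_equal(round(lowest_attainable_error(discrete = TRUE), 3), 2.525)
})

test_that("median split labels dyads strictly below the median as learning", {
  labs <- median_split(c(1, 2, 30, 40))
  expect_identical(as.character(labs),
                   c("learning", "learning", "deadlocked", "deadlocked"))
  expect_identical(attr(labs, "median"), 16)

  expect_warning(labs2 <- median_split(rep(3, 5)), "ties")
  expect_true(all(labs2 == "deadlocked"))

  # balanced group sizes (odd n logs the middle dyad's tie by design)
  set.seed(11)
  for (n in c(10, 11, 22, 101)) {
    e <- runif(n)
    g <- suppressWarnings(median_split(e))
    expect_equal(sum(g == "learning"), floor(n / 2))
  }
})

test_that("switch rate counts changed choices among transitions", {
  expect_equal(switch_rate(c(1, 1, 1, 1)), 0)
  expect_equal(switch_rate(c(1, 2, 1, 2)), 1)
  expect_equal(switch_rate(c(1, 1, 2, 2, 2)), 0.25)
  m <- rbind(c(1, 1, 2), c(3, 3, 3))
  expect_equal(switch_rate(m), c(0.5, 0))
})

test_that("sensitivity score contrasts feedback before switches vs repeats", {
  expect_equal(sensitivity_score(c(1, 1, 2, 2), c(40, 10, 30, 5)), -25)
  expect_true(is.na(sensitivity_score(c(1, 1, 1, 1), c(5, 5, 5, 5))))
  expect_equal(sensitivity_score(c(1, 2, 1, 1), c(7, 7, 7, 7)), 0)
})

test_that("convergence requires a constant filter over the window", {
  co <- run_cohort(60, 0.55, 1.3e-5, seed = 41, keep_trials = FALSE)
  conv <- convergence_class(co)
  last5 <- co$choice[, 16:20]
  expect_identical(conv$converged,
                   apply(last5, 1, function(r) length(unique(r)) == 1L))
  # a single deviation in the window breaks convergence
  co$choice[1, 20] <- (co$choice[1, 20] %% 3L) + 1L
  conv2 <- convergence_class(co)
  expect_false(conv2$converged[1])
  # choice shares over the window sum to one
  shares <- conv$share_opt_last + conv$share_second_last +
    conv$share_worst_last
  expect_equal(shares, rep(1, 60))
})

test_that("an insensitive H-agent switches at the random baseline rate", {
  co <- run_cohort(4000, gamma = 0, lambda = 1.3e-5, seed = 51,
                   keep_trials = FALSE)
  curve <- cohort_switch_curve(co)
  expect_lt(abs(curve[["epoch2"]] - 2 / 3), 0.03)
  # fully committed cohorts never switch
  fx <- run_ablation_fixed_filter("optimal", lambda = 0, n_dyads = 50,
                                  seed = 52, keep_trials = FALSE)
  expect_true(all(cohort_switch_curve(fx) == 0))
})

test_that("learning dyads switch less than deadlocked dyads late on", {
  co <- run_cohort(2000, 0.55, 1.3e-5, seed = 61, keep_trials = FALSE)
  set.seed(61)
  an <- analyze_cohort(co, n_boot = 200)
  expect_lt(an$switch_rate_last[["learning"]],
            an$switch_rate_last[["deadlocked"]])
  # non-converging deadlocked shares over the three filters sum to 100%
  expect_equal(an$nonconv_deadlocked_opt_share_last_pct +
                 an$nonconv_deadlocked_second_share_last_pct +
                 an$nonconv_deadlocked_worst_share_last_pct, 100,
               tolerance = 1e-9)
})
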