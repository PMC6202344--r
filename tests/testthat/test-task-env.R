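test_that("weight permutations cover the fixed multiset uniformly", {
  set.seed(1)
  w <- permute_weights()
  expect_setequal(w, c(0.9, 0.5, 0.1))

  set.seed(42)
  a <- permute_weights()
  set.seed(42)
  b <- permute_weights()
  expect_identical(a, b)

  set.seed(7)
  perms <- replicate(6000, paste(permute_weights(), collapse = ","))
  tab <- table(perms)
  expect_length(tab, 6L)
  expect_gt(stats::chisq.test(tab, p = rep(1 / 6, 6))$p.value, 1e-3)
})

test_that("inputs are independent uniform integers on 0..100", {
  set.seed(2)
  x <- t(vapply(seq_len(30000), function(i) as.numeric(draw_input()),
                numeric(3)))
  expect_true(all(x == floor(x)))
  expect_true(all(x >= 0 & x <= 100))
  expect_true(all(abs(colMeans(x) - 50) < 0.7))   # se ~ 0.17
  cors <- stats::cor(x)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.03))
})

test_that("target value is the weighted linear combination", {
  w <- c(0.9, 0.5, 0.1)
  expect_identical(compute_target(w, c(0, 0, 0)), 0)
  expect_equal(compute_target(w, c(100, 100, 100)), 150)
  expect_equal(compute_target(w, c(10, 20, 30)), 22.0)

  # linearity in the input
  set.seed(3)
  for (i in 1:20) {
    ww <- permute_weights()
    x1 <- draw_input()
    x2 <- draw_input()
    expect_equal(compute_target(ww, x1 + x2),
                 compute_target(ww, x1) + compute_target(ww, x2))
  }
})

test_that("disclosed-information rate takes the three canonical values", {
  w <- c(0.9, 0.5, 0.1)
  expect_equal(disclosed_rate(w, 3L), 14 / 15)         # optimal, prints 0.93
  expect_equal(round(disclosed_rate(w, 3L), 2), 0.93)
  expect_equal(disclosed_rate(w, 1L), 0.40)            # minimal
  expect_equal(round(mean(vapply(1:3, function(h) disclosed_rate(w, h),
                                 numeric(1))), 2), 0.67) # random choice

  set.seed(4)
  rates <- unlist(lapply(1:30, function(i) {
    ww <- permute_weights()
    vapply(1:3, function(h) disclosed_rate(ww, h), numeric(1))
  }))
  expect_setequal(round(rates, 10), round(c(0.6, 1.0, 1.4) / 1.5, 10))
})

test_that("filters are resolved against the dyad's weight permutation", {
  w <- c(0.5, 0.1, 0.9)
  expect_identical(ranked_filter(w, "optimal"), 2L)
  expect_identical(ranked_filter(w, "worst"), 3L)
  expect_identical(ranked_filter(w, "second"), 1L)
  expect_identical(filter_indicator(2L), c(1L, 0L, 1L))
  expect_error(filter_indicator(4L))
})
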