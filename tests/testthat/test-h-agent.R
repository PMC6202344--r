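test_that("softmax choice probabilities behave across the gamma range", {
  expect_equal(choice_probs(c(5, 80, 13), gamma = 0), rep(1 / 3, 3))
  expect_equal(choice_probs(c(7, 7, 7), gamma = 2), rep(1 / 3, 3))
  # deterministic preference in the large-gamma limit
  p <- choice_probs(c(1000, 0, 0), gamma = 1e6)
  expect_equal(p, c(1, 0, 0), tolerance = 1e-12)
  # overflow-safe on huge attractions
  p <- choice_probs(c(1e6, 0, 0), gamma = 10)
  expect_false(anyNA(p))
  expect_equal(sum(p), 1)
})

test_that("a common attraction offset never changes choice probabilities", {
  set.seed(6)
  for (i in 1:50) {
    a <- runif(3, 0, 500)
    g <- runif(1, 0, 3)
    off <- runif(1, -300, 300)
    expect_equal(choice_probs(a, g), choice_probs(a + off, g),
                 tolerance = 1e-12)
  }
})

test_that("choice probabilities are monotone in the own attraction", {
  set.seed(7)
  for (i in 1:30) {
    a <- runif(3, 0, 200)
    g <- runif(1, 0, 2)
    a2 <- a + c(runif(1, 0, 100), 0, 0)
    expect_gte(choice_probs(a2, g)[1], choice_probs(a, g)[1])
  }
})

test_that("filter sampling matches the softmax distribution", {
  set.seed(8)
  draws <- vapply(seq_len(30000), function(i) select_filter(c(0, 0, 0), 0),
                  integer(1))
  tab <- table(factor(draws, levels = 1:3))
  expect_gt(stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value, 1e-3)

  # near-degenerate distribution always picks the dominant filter
  set.seed(9)
  draws <- vapply(seq_len(200), function(i)
    select_filter(c(1000, 0, 0), 1e6), integer(1))
  expect_true(all(draws == 1L))

  set.seed(10)
  s1 <- vapply(1:50, function(i) select_filter(c(3, 2, 1), 0.5), integer(1))
  set.seed(10)
  s2 <- vapply(1:50, function(i) select_filter(c(3, 2, 1), 0.5), integer(1))
  expect_identical(s1, s2)
})

test_that("reinforcement updates only the chosen attraction", {
  a <- c(0, 10, 20)
  expect_equal(update_attraction(a, 1L, pctE = 30), c(70, 10, 20))
  expect_equal(update_attraction(a, 2L, pctE = 150), a)  # max{0, .} binds
  expect_equal(update_attraction(a, 3L, pctE = 0), c(0, 10, 120))
  expect_error(update_attraction(a, 1L, pctE = -5))
})
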