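#' Task environment: inputs, weights, filters and target values
#'
#' The task environment presents three-component integer inputs whose value
#' is a fixed weighted sum.  The weight vector is a random permutation of
#' `c(0.9, 0.5, 0.1)`, drawn once per dyad and held constant.  An
#' information filter discloses exactly two of the three components; filters
#' are identified by the index of the single hidden component
#' (`hidden_index` in 1..3).  The optimal filter hides the component with
#' the smallest weight (0.1).
#'
#' @name task_env
NULL

#' True environment weights, as permutations of {0.9, 0.5, 0.1}
#'
#' Draws a uniformly random permutation of the weight multiset
#' `{0.9, 0.5, 0.1}` from the current RNG stream.  Fixed thereafter for the
#' lifetime of a dyad.
#'
#' @return Numeric vector of length 3.
#' @examples
#' set.seed(1)
#' permute_weights()
#' @export
permute_weights <- function() {
  c(0.9, 0.5, 0.1)[sample.int(3L)]
}

#' Draw one input vector
#'
#' Three independent uniform integer draws on 0..100 inclusive.
#'
#' @return Integer vector of length 3.
#' @export
draw_input <- function() {
  sample.int(101L, 3L, replace = TRUE) - 1L
}

#' Target value of an input
#'
#' The input's value is the weighted linear combination of its three
#' components, `y = sum(w * x)`, in \[0, 150\].
#'
#' @param w weight vector (length 3).
#' @param x input vector (length 3).
#' @return Scalar target value.
#' @examples
#' compute_target(c(0.9, 0.5, 0.1), c(10, 20, 30)) # 22
#' @export
compute_target <- function(w, x) {
  stopifnot(length(w) == 3L, length(x) == 3L)
  sum(w * x)
}

#' Filter indicator vector from the hidden component index
#'
#' @param hidden_index index (1..3) of the component the filter hides.
#' @return 0/1 vector of length 3 with exactly one zero.
#' @export
filter_indicator <- function(hidden_index) {
  stopifnot(hidden_index %in% 1:3)
  f <- rep(1L, 3L)
  f[hidden_index] <- 0L
  f
}

#' Rate of disclosed information for a filter
#'
#' Sum of the weights of the disclosed components, normalised by the sum of
#' all three weights.  With weights {0.9, 0.5, 0.1} the three attainable
#' rates are 14/15 (optimal, printed 0.93), 1.0/1.5 (0.67) and 0.6/1.5
#' (minimal, 0.40); the expectation under uniformly random filter choice is
#' 2/3.
#'
#' @param w weight vector (length 3).
#' @param hidden_index index of the hidden component.
#' @return Scalar in \[0, 1\].
#' @export
disclosed_rate <- function(w, hidden_index) {
  stopifnot(length(w) == 3L, hidden_index %in% 1:3)
  (sum(w) - w[hidden_index]) / sum(w)
}

#' Index of the optimal (or other ranked) filter for a weight vector
#'
#' Filter optimality is resolved against the dyad's weight permutation: the
#' optimal filter hides the smallest weight, the worst filter hides the
#' largest.
#'
#' @param w weight vector (length 3).
#' @param rank one of `"optimal"`, `"second"`, `"worst"`.
#' @return The hidden-component index (1..3) of the requested filter.
#' @export
ranked_filter <- function(w, rank = c("optimal", "second", "worst")) {
  rank <- match.arg(rank)
  ord <- order(w) # ascending: smallest weight first
  switch(rank, optimal = ord[1L], second = ord[2L], worst = ord[3L])
}
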