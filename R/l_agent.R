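#' The operational agent (L-agent): a simple perceptron
#'
#' The L-agent holds a vector of learned weights `v` (initialised from
#' U\[0, 1\]) and estimates each filtered input as the weighted sum of its
#' disclosed components.  After each trial it observes the true value and
#' adjusts `v` by the delta rule with learning rate `lambda`.  The weight of
#' a hidden component is never updated (its filter indicator is zero) and
#' retains its last value until that component is disclosed again.  Weights
#' are not bounded or clipped during learning.
#'
#' @name l_agent
NULL

#' Initialise L-agent weights
#'
#' Independent random draws from U\[0, 1\] for each of the three components.
#'
#' @return Numeric vector of length 3.
#' @export
l_init_weights <- function() {
  runif(3L)
}

#' Perceptron estimate of a filtered input
#'
#' `o = sum(v * x * f)`: the hidden component contributes nothing.
#'
#' @param v learned weights (length 3).
#' @param x input vector (length 3).
#' @param f filter indicator (length 3, one zero).
#' @return Scalar estimate.
#' @examples
#' l_estimate(c(0.9, 0.5, 0.1), c(10, 20, 30), c(1, 1, 0)) # 19
#' @export
l_estimate <- function(v, x, f) {
  sum(v * x * f)
}

#' Delta-rule weight update
#'
#' `v_j <- v_j + lambda * (y - o) * f_j * x_j`.  Weights tied to larger
#' disclosed components receive proportionally larger adjustments; the
#' hidden component's weight is unchanged.  The rule performs stochastic
#' gradient descent on the squared estimation error.
#'
#' @param v current weights (length 3).
#' @param x input vector.
#' @param f filter indicator.
#' @param y true target value.
#' @param o the estimate produced from the same `(x, f)`.
#' @param lambda learning rate (>= 0).
#' @return Updated weight vector.
#' @export
l_update_weights <- function(v, x, f, y, o, lambda) {
  stopifnot(lambda >= 0)
  v + lambda * (y - o) * f * x
}

#' Absolute estimation error
#'
#' `|y - o|`, the fundamental dyad-level performance measure.
#'
#' @param y true value.
#' @param o estimate.
#' @return Non-negative scalar (vectorised).
#' @export
absolute_error <- function(y, o) {
  abs(y - o)
}

#' Percent estimation error
#'
#' `100 * |y - o| / y`.  The epoch average of this quantity is the only
#' feedback the H-agent receives.  Values above 100 are possible and are not
#' capped.  The degenerate case `y = 0` (all three input components zero,
#' probability about 1e-6 per trial) returns 0 when the estimate is also 0
#' and 100 otherwise; callers flag such trials.
#'
#' @param y true value (vectorised).
#' @param o estimate (vectorised).
#' @return Non-negative percent error.
#' @export
percent_error <- function(y, o) {
  out <- ifelse(y > 0, 100 * abs(y - o) / y, ifelse(o == 0, 0, 100))
  as.numeric(out)
}
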