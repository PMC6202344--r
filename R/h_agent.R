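#' The strategy agent (H-agent): attraction-based reinforcement learning
#'
#' The H-agent associates each of the three information filters with an
#' attraction.  Choice probabilities follow a logistic (softmax) rule with
#' sensitivity `gamma`; after each epoch only the chosen filter's attraction
#' grows by the reinforcement `pi = max(0, 100 - pctE)`, where `pctE` is the
#' epoch's average percent estimation error.  All attractions start at the
#' same value (0 here); a common offset never changes choice probabilities,
#' so the initial level is irrelevant.  There is no forgetting, no decay and
#' no update of unchosen attractions.
#'
#' @name h_agent
NULL

#' Softmax choice probabilities over the three filters
#'
#' `p_i = exp(gamma * a_i / 100) / sum_j exp(gamma * a_j / 100)`, computed
#' with the usual overflow-safe shift by the maximum attraction.
#' `gamma = 0` gives uniform choice; as `gamma` grows the rule approaches a
#' deterministic preference for the highest attraction.
#'
#' Attractions accumulate the epoch reinforcement on the 0-100
#' percentage-point scale (see [update_attraction()]); the sensitivity
#' `gamma` is calibrated per unit of reward *fraction* — the scale of the
#' epoch's bonus-winning probability `(100 - pctE)/100` — hence the
#' conversion by the 100-point scale inside the softmax.  This is the
#' reading under which the canonical fitted sensitivity (0.55) produces
#' gradual lock-in and heterogeneous long-run outcomes; applied directly to
#' percentage points, any sensitivity above about 0.1 would saturate the
#' softmax after a single epoch and all dyads would lock onto their first
#' reinforced filter.
#'
#' @param a attraction vector (length 3).
#' @param gamma sensitivity parameter (>= 0).
#' @return Probability vector of length 3.
#' @export
choice_probs <- function(a, gamma) {
  stopifnot(gamma >= 0, length(a) == 3L)
  z <- gamma * (a - max(a)) / 100
  e <- exp(z)
  e / sum(e)
}

#' Sample a filter from the softmax distribution
#'
#' Inverse-CDF sampling with a single uniform draw, so that the number of
#' RNG draws per selection is constant (one) regardless of the parameters.
#'
#' @param a attraction vector.
#' @param gamma sensitivity.
#' @return The hidden-component index (1..3) of the sampled filter.
#' @export
select_filter <- function(a, gamma) {
  p <- choice_probs(a, gamma)
  u <- runif(1L)
  1L + sum(u > cumsum(p)[1:2])
}

#' Reinforcement update of the chosen filter's attraction
#'
#' `a_k <- a_k + max(0, 100 - pctE)`.  Unchosen attractions are never
#' modified; attractions are non-decreasing over epochs.
#'
#' @param a attraction vector.
#' @param chosen hidden-component index of the filter chosen this epoch.
#' @param pctE the epoch's average percent estimation error (>= 0).
#' @return Updated attraction vector.
#' @export
update_attraction <- function(a, chosen, pctE) {
  stopifnot(chosen %in% 1:3)
  if (is.na(pctE) || pctE < 0) {
    stop("pctE must be a non-negative percent error")
  }
  a[chosen] <- a[chosen] + max(0, 100 - pctE)
  a
}
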