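#' Performance measures and distributional analyses
#'
#' Every measure is computable from the per-epoch records of an
#' [run_cohort()] result: per-epoch mean absolute error, disclosed-
#' information rate, switch indicators, sensitivity scores, the median split
#' into learning and deadlocked dyads, convergence classification over the
#' final epochs, and Hartigan's dip test of unimodality on the distribution
#' of long-run error.
#'
#' @name metrics
NULL

#' Per-epoch mean absolute estimation error
#'
#' @param cohort an `hl_cohort` object.
#' @return For a single dyad, a numeric vector of length `n_epochs`;
#'   otherwise an `n_dyads` x `n_epochs` matrix.  Element t is the mean of
#'   the five per-trial absolute errors of epoch t.
#' @export
epoch_error_curve <- function(cohort) {
  stopifnot(inherits(cohort, "hl_cohort"))
  if (cohort$n_dyads == 1L) drop(cohort$epoch_err) else cohort$epoch_err
}

#' Cohort-mean trajectory curves
#'
#' Cross-dyad means, per epoch, of the estimation error and of the
#' disclosed-information rate — the two aggregate measures used for
#' parameter fitting.
#'
#' @param cohort an `hl_cohort`.
#' @return List with numeric vectors `error` and `disclosure`.
#' @export
cohort_mean_curves <- function(cohort) {
  stopifnot(inherits(cohort, "hl_cohort"))
  list(error = colMeans(cohort$epoch_err),
       disclosure = colMeans(cohort$disclosed))
}

#' Per-dyad mean error over the final epochs
#'
#' The long-run performance measure: the mean absolute error over the last
#' `last_k` epochs (equivalently over the final `5 * last_k` trials).
#'
#' @param cohort an `hl_cohort`.
#' @param last_k number of final epochs (default 5).
#' @return Numeric vector of length `n_dyads`.
#' @export
last_epochs_error <- function(cohort, last_k = 5L) {
  stopifnot(inherits(cohort, "hl_cohort"), last_k >= 1L,
            last_k <= cohort$n_epochs)
  idx <- seq.int(cohort$n_epochs - last_k + 1L, cohort$n_epochs)
  rowMeans(cohort$epoch_err[, idx, drop = FALSE])
}

#' Lowest attainable average estimation error
#'
#' With the optimal filter in force and correct learned weights, the truth
#' and the estimate diverge by `0.1 * |X - c|` where `X` is the hidden
#' component and `c` its implicit guess; the best guess is 50, giving
#' `0.1 * E|X - 50| = 2.5` for X uniform on \[0, 100\].  On the integer grid
#' 0..100 the exact mean is `0.1 * 2550/101 = 2.5248`; the continuous value
#' 2.5 is the conventional benchmark.
#'
#' @param discrete if `TRUE`, return the exact value for the integer input
#'   grid instead of the continuous benchmark.
#' @return Scalar.
#' @export
lowest_attainable_error <- function(discrete = FALSE) {
  if (discrete) 0.1 * mean(abs(0:100 - 50)) else 2.5
}

#' Median split into learning and deadlocked dyads
#'
#' Dyads strictly below the cohort median of long-run error are labelled
#' `"learning"`, the rest `"deadlocked"`.  With an even count and no ties
#' the split is exactly half/half (the median is the midpoint of the two
#' central order statistics).  Dyads lying exactly at the median go to the
#' deadlocked group — a deterministic rule, flagged with a warning because
#' it can unbalance the groups.
#'
#' @param errors numeric vector of per-dyad long-run errors (>= 2 values).
#' @return Factor with levels `learning`, `deadlocked`; the median is
#'   attached as attribute `"median"`.
#' @export
median_split <- function(errors) {
  stopifnot(length(errors) >= 2L, !anyNA(errors))
  m <- median(errors)
  if (any(errors == m)) {
    warning("ties at the median assigned to the deadlocked group")
  }
  out <- factor(ifelse(errors < m, "learning", "deadlocked"),
                levels = c("learning", "deadlocked"))
  attr(out, "median") <- m
  out
}

#' Switch rate of a choice sequence
#'
#' Fraction of epochs from the second onwards in which the chosen filter
#' differs from the previous epoch's choice.
#'
#' @param choices integer vector of per-epoch choices, or a dyads x epochs
#'   matrix.
#' @return Scalar in \[0, 1\], or one value per row for a matrix.
#' @export
switch_rate <- function(choices) {
  if (is.matrix(choices)) {
    stopifnot(ncol(choices) >= 2L)
    sw <- choices[, -1L, drop = FALSE] != choices[, -ncol(choices), drop = FALSE]
    rowMeans(sw)
  } else {
    stopifnot(length(choices) >= 2L)
    mean(choices[-1L] != choices[-length(choices)])
  }
}

#' Cross-dyad mean switch indicator per epoch
#'
#' @param cohort an `hl_cohort`.
#' @return Numeric vector over epochs 2..n_epochs: the share of dyads that
#'   switched filter at each epoch.
#' @export
cohort_switch_curve <- function(cohort) {
  stopifnot(inherits(cohort, "hl_cohort"), cohort$n_epochs >= 2L)
  ch <- cohort$choice
  sw <- ch[, -1L, drop = FALSE] != ch[, -ncol(ch), drop = FALSE]
  stats::setNames(colMeans(sw), paste0("epoch", 2:cohort$n_epochs))
}

#' Sensitivity of the H-agent to error feedback
#'
#' Mean feedback error preceding filter switches minus mean feedback error
#' preceding repetitions.  A positive score means the H-agent tends to
#' abandon a filter after poor feedback.  Undefined (`NA`) when the agent
#' never switched or never repeated.
#'
#' @param choices per-epoch choices (vector) or a dyads x epochs matrix.
#' @param feedback matching per-epoch feedback percent errors.
#' @return Scalar (or per-dyad vector), `NA` where undefined.
#' @export
sensitivity_score <- function(choices, feedback) {
  one <- function(ch, fb) {
    tt <- seq_along(ch)[-1L]
    is_switch <- ch[tt] != ch[tt - 1L]
    prior <- fb[tt - 1L]
    if (!any(is_switch) || all(is_switch)) return(NA_real_)
    mean(prior[is_switch]) - mean(prior[!is_switch])
  }
  if (is.matrix(choices)) {
    stopifnot(all(dim(choices) == dim(feedback)), ncol(choices) >= 2L)
    vapply(seq_len(nrow(choices)),
           function(i) one(choices[i, ], feedback[i, ]), numeric(1))
  } else {
    stopifnot(length(choices) == length(feedback), length(choices) >= 2L)
    one(choices, feedback)
  }
}

#' Convergence classification over the final epochs
#'
#' A dyad has converged when the same filter is chosen in every one of the
#' last `last_k` epochs; the converged-to filter is then ranked against the
#' dyad's weight permutation (optimal / second / worst).  Non-converged
#' dyads get the share of epochs in which they chose each filter, both over
#' the last `last_k` epochs and over the whole run.
#'
#' @param cohort an `hl_cohort`.
#' @param last_k window length (default 5).
#' @return Data frame with one row per dyad: `converged` (logical),
#'   `converged_hidden` (hidden index or NA), `converged_rank`
#'   (`"optimal"`, `"second"`, `"worst"` or NA), `share_opt_last`,
#'   `share_second_last`, `share_worst_last` (choice shares in the window)
#'   and `share_opt_all` (share over all epochs).
#' @export
convergence_class <- function(cohort, last_k = 5L) {
  stopifnot(inherits(cohort, "hl_cohort"), last_k >= 1L,
            last_k <= cohort$n_epochs)
  n <- cohort$n_dyads
  E <- cohort$n_epochs
  idx <- seq.int(E - last_k + 1L, E)
  ch <- cohort$choice[, idx, drop = FALSE]
  constant <- rowSums(ch == ch[, 1L]) == last_k
  conv_hidden <- ifelse(constant, ch[, 1L], NA_integer_)

  w <- cohort$w
  hid2rank <- function(hidden) {
    out <- rep(NA_character_, n)
    ok <- !is.na(hidden)
    wh <- w[cbind(which(ok), hidden[ok])]
    out[ok] <- c("0.1" = "optimal", "0.5" = "second",
                 "0.9" = "worst")[format(wh)]
    out
  }

  opt <- cohort$opt_hidden
  second <- max.col(w == 0.5, ties.method = "first")
  worst <- max.col(w == 0.9, ties.method = "first")
  share_of <- function(target, cols) {
    rowMeans(cohort$choice[, cols, drop = FALSE] == target)
  }
  data.frame(
    converged = constant,
    converged_hidden = conv_hidden,
    converged_rank = hid2rank(conv_hidden),
    share_opt_last = share_of(opt, idx),
    share_second_last = share_of(second, idx),
    share_worst_last = share_of(worst, idx),
    share_opt_all = share_of(opt, seq_len(E))
  )
}

#' Hartigan's dip statistic
#'
#' The maximum distance between the empirical CDF of a sample and the
#' closest unimodal CDF, computed by the greatest-convex-minorant /
#' least-concave-majorant modal-interval algorithm.  Lies in
#' \[1/(2n), 0.25\]; large values indicate multimodality.
#'
#' @param x numeric sample (n >= 2; need not be sorted).
#' @return The dip statistic.
#' @examples
#' dip_statistic(c(0, 1))       # 0.25, the maximal dip
#' dip_statistic(seq_len(100))  # 1/200, the minimal dip at n = 100
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2L, !anyNA(x))
  .dip_sorted_cpp(sort(x))
}

#' Monte Carlo p-value for the dip statistic
#'
#' Share of `n_boot` uniform(0, 1) samples of size `n` whose dip is at
#' least `D`.  The uniform distribution is the conventional calibrating
#' null for the dip test.  Draws come from the current RNG stream; seed
#' with [set.seed()] for reproducibility.
#'
#' @param D observed dip statistic.
#' @param n sample size of the observed sample.
#' @param n_boot number of null samples (>= 100; default 2000).
#' @return p-value in \[0, 1\].
#' @export
dip_pvalue <- function(D, n, n_boot = 2000L) {
  stopifnot(n_boot >= 100L, n >= 2L, D >= 0)
  mean(.dip_null_boot_cpp(as.integer(n), as.integer(n_boot)) >= D)
}

#' Dip test of unimodality
#'
#' Convenience wrapper: dip statistic plus Monte Carlo p-value.
#'
#' @param x numeric sample.
#' @param n_boot Monte Carlo replicates for the p-value.
#' @return List with `statistic`, `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(x, n_boot = 2000L) {
  D <- dip_statistic(x)
  list(statistic = D, p_value = dip_pvalue(D, length(x), n_boot),
       n = length(x), n_boot = n_boot)
}

#' Full cohort analysis
#'
#' Median split on long-run error, group-wise convergence shares, choice
#' shares of non-converging deadlocked dyads, switch rates by group, the
#' dip test on the long-run error distribution, and the cohort mean curves.
#'
#' @param cohort an `hl_cohort`.
#' @param last_k window for long-run error and convergence (default 5).
#' @param n_boot Monte Carlo replicates for the dip p-value (default 2000).
#' @return List of class `hl_analysis`; see Details.
#' @details
#' Components: `last5_error` (per-dyad), `group` (median-split factor),
#' `dip` (list), `curves`, `learning_converged_opt_pct` (share of learning
#' dyads converged to the optimal filter, percent),
#' `deadlocked_converged_subopt_pct` (share of deadlocked dyads settled on
#' one suboptimal filter, percent), `nonconv_deadlocked_opt_share_last_pct`
#' and `..._all_pct` (average share of epochs choosing the optimal filter
#' among non-converging deadlocked dyads, over the window and over all
#' epochs), `nonconv_deadlocked_second_share_last_pct`,
#' `nonconv_deadlocked_worst_share_last_pct`, and `switch_rate_last` means
#' by group.
#' @export
analyze_cohort <- function(cohort, last_k = 5L, n_boot = 2000L) {
  err <- last_epochs_error(cohort, last_k)
  grp <- median_split(err)
  conv <- convergence_class(cohort, last_k)
  learning <- grp == "learning"
  deadlocked <- !learning

  conv_opt <- conv$converged & conv$converged_rank %in% "optimal"
  conv_subopt <- conv$converged & !(conv$converged_rank %in% "optimal")
  nonconv_dead <- deadlocked & !conv$converged

  sw <- switch_rate(cohort$choice[, seq.int(cohort$n_epochs - last_k + 1L,
                                            cohort$n_epochs), drop = FALSE])

  dipres <- dip_test(err, n_boot = n_boot)

  structure(list(
    n_dyads = cohort$n_dyads, last_k = last_k,
    median = attr(grp, "median"),
    last5_error = err, group = grp, convergence = conv,
    dip = dipres, curves = cohort_mean_curves(cohort),
    learning_converged_opt_pct = 100 * mean(conv_opt[learning]),
    deadlocked_converged_subopt_pct = 100 * mean(conv_subopt[deadlocked]),
    nonconv_deadlocked_opt_share_last_pct =
      100 * mean(conv$share_opt_last[nonconv_dead]),
    nonconv_deadlocked_second_share_last_pct =
      100 * mean(conv$share_second_last[nonconv_dead]),
    nonconv_deadlocked_worst_share_last_pct =
      100 * mean(conv$share_worst_last[nonconv_dead]),
    nonconv_deadlocked_opt_share_all_pct =
      100 * mean(conv$share_opt_all[nonconv_dead]),
    switch_rate_last = c(
      learning = mean(sw[learning]),
      deadlocked = mean(sw[deadlocked])),
    median_last5_error = median(err)
  ), class = "hl_analysis")
}

#' @export
print.hl_analysis <- function(x, ...) {
  cat(sprintf("<hl_analysis> %d dyads, window = last %d epochs\n",
              x$n_dyads, x$last_k))
  cat(sprintf("  median long-run error: %.2f\n", x$median))
  cat(sprintf("  dip D = %.4f, Monte Carlo p = %.4g (n_boot = %d)\n",
              x$dip$statistic, x$dip$p_value, x$dip$n_boot))
  cat(sprintf("  learning dyads converged to optimal filter: %.1f%%\n",
              x$learning_converged_opt_pct))
  cat(sprintf("  deadlocked dyads settled on a suboptimal filter: %.1f%%\n",
              x$deadlocked_converged_subopt_pct))
  cat(sprintf(
    "  non-converging deadlocked choice shares (last %d): %.0f/%.0f/%.0f%%\n",
    x$last_k, x$nonconv_deadlocked_opt_share_last_pct,
    x$nonconv_deadlocked_second_share_last_pct,
    x$nonconv_deadlocked_worst_share_last_pct))
  cat(sprintf("  switch rate (last %d): learning %.2f, deadlocked %.2f\n",
              x$last_k, x$switch_rate_last["learning"],
              x$switch_rate_last["deadlocked"]))
  invisible(x)
}
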