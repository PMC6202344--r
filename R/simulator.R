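#' Dyadic interaction protocol and cohort simulation
#'
#' An epoch consists of one filter selection by the H-agent followed by five
#' estimation trials by the L-agent; after the fifth trial the H-agent
#' receives the epoch's average percent error as feedback and reinforces the
#' chosen filter's attraction.  A run comprises 20 epochs by default (20
#' filter choices, 100 estimations).  Cohorts are simulated with a single
#' vectorised engine; all randomness comes from one seeded stream drawn in a
#' fixed order (per-dyad weight permutations, initial L-weights, then per
#' epoch one selection uniform per dyad and per trial one input triplet per
#' dyad), so a cohort is a pure function of (parameters, n_dyads, n_epochs,
#' seed) and `run_cohort(n_dyads = 1)` reproduces `run_dyad()` exactly.
#'
#' @name simulator
NULL

# softmax over gamma * a / 100 per row; attractions are on the 0-100
# percentage-point scale, sensitivity per unit of reward fraction
# (cf. choice_probs)
row_softmax3 <- function(z) {
  m <- pmax(z[, 1L], z[, 2L], z[, 3L])
  e <- exp((z - m) / 100)
  e / rowSums(e)
}

resolve_fixed_hidden <- function(w, fixed) {
  if (is.numeric(fixed)) {
    stopifnot(fixed %in% 1:3)
    rep.int(as.integer(fixed), nrow(w))
  } else {
    rank <- match.arg(fixed, c("optimal", "second", "worst"))
    target <- switch(rank, optimal = 0.1, second = 0.5, worst = 0.9)
    max.col(w == target, ties.method = "first")
  }
}

# Core vectorised engine behind all cohort-level entry points.
cohort_engine <- function(n_dyads, n_epochs, gamma, lambda, seed = NULL,
                          h_mode = c("softmax", "fixed", "statistical"),
                          fixed = "optimal",
                          l_learn = TRUE,
                          l_init = c("uniform", "correct", "perturbed"),
                          noise_halfwidth = 0.1,
                          samples_per_filter = NULL, alpha = 0.05,
                          keep_trials = n_dyads <= 100L) {
  h_mode <- match.arg(h_mode)
  l_init <- match.arg(l_init)
  stopifnot(n_dyads >= 1L, n_epochs >= 1L, gamma >= 0, lambda >= 0)
  if (h_mode == "statistical") {
    stopifnot(!is.null(samples_per_filter), samples_per_filter >= 1L,
              3L * samples_per_filter <= n_epochs)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_dyads)
  E <- as.integer(n_epochs)

  # -- draw order step 1: per-dyad weight permutations
  w <- t(vapply(seq_len(n), function(i) permute_weights(), numeric(3L)))
  opt_hidden <- max.col(w == 0.1, ties.method = "first")

  # -- draw order step 2: initial L-agent weights
  v <- switch(l_init,
    uniform   = matrix(runif(3L * n), n, 3L),
    correct   = w,
    perturbed = w + matrix(runif(3L * n, -noise_halfwidth, noise_halfwidth),
                           n, 3L)
  )
  v0 <- v

  fixed_hidden <- if (h_mode == "fixed") resolve_fixed_hidden(w, fixed)
  committed <- rep(NA_integer_, n)
  commit_p <- rep(NA_real_, n)

  a <- matrix(0, n, 3L)
  choice <- matrix(NA_integer_, n, E)
  feedback <- matrix(NA_real_, n, E)
  epoch_err <- matrix(NA_real_, n, E)
  a_hist <- array(NA_real_, c(n, 3L, E))
  v_hist <- array(NA_real_, c(n, 3L, E))
  zero_y_trials <- 0L

  trials <- NULL
  if (keep_trials) {
    trials <- list(
      x = array(NA_real_, c(n, 3L, E, 5L)),
      o = array(NA_real_, c(n, E, 5L)),
      y = array(NA_real_, c(n, E, 5L))
    )
  }

  rows <- seq_len(n)
  for (t in seq_len(E)) {
    # -- H-agent moves first and selects a filter for the epoch
    chosen <- switch(h_mode,
      softmax = {
        u <- runif(n)
        p <- row_softmax3(gamma * a)
        1L + (u > p[, 1L]) + (u > p[, 1L] + p[, 2L])
      },
      fixed = fixed_hidden,
      statistical = {
        if (t <= 3L * samples_per_filter) {
          rep.int(((t - 1L) %% 3L) + 1L, n)
        } else {
          committed
        }
      }
    )
    fmat <- matrix(1, n, 3L)
    fmat[cbind(rows, chosen)] <- 0

    abs_sum <- numeric(n)
    pct_sum <- numeric(n)
    for (tr in 1:5) {
      x <- matrix(sample.int(101L, 3L * n, replace = TRUE) - 1L, n, 3L)
      y <- rowSums(w * x)
      o <- rowSums(v * x * fmat)
      d <- y - o
      ae <- abs(d)
      pe <- numeric(n)
      pos <- y > 0
      pe[pos] <- 100 * ae[pos] / y[pos]
      if (!all(pos)) {
        bad <- !pos
        pe[bad] <- ifelse(o[bad] == 0, 0, 100)
        zero_y_trials <- zero_y_trials + sum(bad)
      }
      if (l_learn) v <- v + lambda * d * x * fmat
      abs_sum <- abs_sum + ae
      pct_sum <- pct_sum + pe
      if (keep_trials) {
        trials$x[, , t, tr] <- x
        trials$o[, t, tr] <- o
        trials$y[, t, tr] <- y
      }
    }

    choice[, t] <- chosen
    feedback[, t] <- pct_sum / 5
    epoch_err[, t] <- abs_sum / 5

    if (h_mode == "softmax") {
      idx <- cbind(rows, chosen)
      a[idx] <- a[idx] + pmax(0, 100 - feedback[, t])
    } else if (h_mode == "statistical" && t == 3L * samples_per_filter) {
      s <- samples_per_filter
      fb <- feedback[, seq_len(3L * s), drop = FALSE]
      filt <- ((seq_len(3L * s) - 1L) %% 3L) + 1L
      gm <- vapply(1:3, function(k) {
        rowMeans(fb[, filt == k, drop = FALSE])
      }, numeric(n))
      # commit once and for all to the filter with lowest mean error;
      # ties broken uniformly at random
      committed <- max.col(-gm, ties.method = "random")
      if (s >= 2L) {
        # one-way F test on per-epoch feedback by filter, logged only
        grand <- rowMeans(fb)
        ssb <- s * rowSums((gm - grand)^2)
        ssw <- numeric(n)
        for (k in 1:3) {
          ssw <- ssw + rowSums((fb[, filt == k, drop = FALSE] - gm[, k])^2)
        }
        fstat <- (ssb / 2) / (ssw / (3L * s - 3L))
        commit_p <- pf(fstat, 2, 3L * s - 3L, lower.tail = FALSE)
      }
    }
    a_hist[, , t] <- a
    v_hist[, , t] <- v
  }

  w_hidden <- matrix(w[cbind(rep(rows, E), as.vector(choice))], n, E)
  disclosed <- (1.5 - w_hidden) / 1.5

  structure(list(
    n_dyads = n, n_epochs = E, gamma = gamma, lambda = lambda, seed = seed,
    variant = switch(h_mode,
      softmax = if (l_learn) "baseline" else "frozen_l",
      fixed = "fixed_filter",
      statistical = "statistical_h"),
    h_mode = h_mode, l_learn = l_learn, l_init = l_init,
    noise_halfwidth = if (l_init == "perturbed") noise_halfwidth else NA_real_,
    samples_per_filter = samples_per_filter, alpha = alpha,
    w = w, opt_hidden = opt_hidden,
    choice = choice, feedback = feedback, epoch_err = epoch_err,
    disclosed = disclosed,
    v0 = v0, v_final = v, attractions = a,
    a_hist = a_hist, v_hist = v_hist,
    committed = committed, commit_p = commit_p,
    zero_y_trials = zero_y_trials,
    trials = trials
  ), class = "hl_cohort")
}

#' Run one epoch for a single dyad
#'
#' The H-agent selects a filter from its attractions; the L-agent then faces
#' `n_trials` estimation tasks, updating its weights after each; finally the
#' epoch's mean percent error is fed back and reinforces the chosen filter's
#' attraction.  Built directly from the agent-level operations; the
#' vectorised cohort engine is tested against a replay through this
#' function.
#'
#' @param attractions H-agent attraction vector (length 3).
#' @param v L-agent weight vector (length 3).
#' @param w true environment weights.
#' @param gamma softmax sensitivity.
#' @param lambda delta-rule learning rate.
#' @param n_trials trials per epoch (5 in the canonical protocol).
#' @param inputs optional `n_trials` x 3 matrix of pre-drawn inputs (for
#'   deterministic replay); drawn internally when `NULL`.
#' @param select_u optional uniform draw for the filter selection (replay).
#' @return List with elements `chosen` (hidden index), `trials` (data frame
#'   of x, o, y, absolute and percent error), `feedback` (mean percent
#'   error), `attractions`, `v`.
#' @export
run_epoch <- function(attractions, v, w, gamma, lambda, n_trials = 5L,
                      inputs = NULL, select_u = NULL) {
  if (is.null(select_u)) {
    chosen <- select_filter(attractions, gamma)
  } else {
    p <- choice_probs(attractions, gamma)
    chosen <- 1L + sum(select_u > cumsum(p)[1:2])
  }
  f <- filter_indicator(chosen)
  rec <- matrix(NA_real_, n_trials, 7L)
  for (tr in seq_len(n_trials)) {
    x <- if (is.null(inputs)) draw_input() else inputs[tr, ]
    y <- compute_target(w, x)
    o <- l_estimate(v, x, f)
    pe <- percent_error(y, o)
    v <- l_update_weights(v, x, f, y, o, lambda)
    rec[tr, ] <- c(x, o, y, absolute_error(y, o), pe)
  }
  colnames(rec) <- c("x1", "x2", "x3", "o", "y", "abs_err", "pct_err")
  feedback <- mean(rec[, "pct_err"])
  attractions <- update_attraction(attractions, chosen, feedback)
  list(chosen = chosen, trials = as.data.frame(rec), feedback = feedback,
       attractions = attractions, v = v)
}

#' Simulate a single dyad
#'
#' Fresh weight permutation, fresh U\[0, 1\] initial L-weights, attractions
#' at zero, then `n_epochs` epochs of the interaction protocol.
#'
#' @param gamma softmax sensitivity of the H-agent.
#' @param lambda learning rate of the L-agent.
#' @param n_epochs number of epochs (>= 1; 20 in the canonical protocol).
#' @param seed integer seed; the trajectory is bit-identical for equal seeds.
#' @param keep_trials keep per-trial records (default `TRUE`).
#' @return An object of class `hl_cohort` with `n_dyads = 1`.
#' @export
run_dyad <- function(gamma, lambda, n_epochs = 20L, seed = NULL,
                     keep_trials = TRUE) {
  cohort_engine(1L, n_epochs, gamma, lambda, seed = seed,
                h_mode = "softmax", keep_trials = keep_trials)
}

#' Simulate a cohort of identically parameterised dyads
#'
#' Dyads are mutually independent: each gets its own weight permutation,
#' initial L-weights and input stream, but all share the same (gamma,
#' lambda), mirroring identically initialised agents whose divergent
#' trajectories are entirely endogenous to the learning process.
#'
#' @param n_dyads number of dyads (>= 1).
#' @param gamma softmax sensitivity.
#' @param lambda delta-rule learning rate.
#' @param n_epochs epochs per dyad.
#' @param seed integer seed for the whole cohort.
#' @param keep_trials keep per-trial records (defaults to `TRUE` only for
#'   small cohorts; epoch-level records are always kept).
#' @return An `hl_cohort` object.
#' @export
run_cohort <- function(n_dyads, gamma, lambda, n_epochs = 20L, seed = NULL,
                       keep_trials = n_dyads <= 100L) {
  cohort_engine(n_dyads, n_epochs, gamma, lambda, seed = seed,
                h_mode = "softmax", keep_trials = keep_trials)
}

#' Ablation: H-agent learning inhibited, filter held fixed
#'
#' The H-agent neither learns nor randomises: the same filter is applied in
#' every epoch (resolved per dyad when given as a rank such as "optimal").
#' The L-agent learns normally.
#'
#' @param fixed `"optimal"`, `"second"`, `"worst"`, or a hidden-component
#'   index 1..3 applied to all dyads.
#' @param lambda L-agent learning rate.
#' @param n_dyads,n_epochs,seed,keep_trials as in [run_cohort()].
#' @return An `hl_cohort` object.
#' @export
run_ablation_fixed_filter <- function(fixed = "optimal", lambda, n_dyads,
                                      n_epochs = 20L, seed = NULL,
                                      keep_trials = n_dyads <= 100L) {
  cohort_engine(n_dyads, n_epochs, gamma = 0, lambda = lambda, seed = seed,
                h_mode = "fixed", fixed = fixed, keep_trials = keep_trials)
}

#' Ablation: L-agent learning inhibited (frozen weights)
#'
#' The L-agent's weights are fixed for the whole run at either the correct
#' environment weights or the correct weights plus independent
#' U\[-noise_halfwidth, noise_halfwidth\] noise per component (drawn once
#' per dyad).  The H-agent learns normally with sensitivity `gamma`.  Even
#' with correct weights the feedback remains noisy — the hidden component
#' contributes an irreducible random error — so the H-agent's reinforcement
#' learning need not converge to the optimal filter.
#'
#' @param init `"correct"` or `"perturbed"`.
#' @param noise_halfwidth half-width of the uniform perturbation.
#' @param gamma H-agent sensitivity.
#' @param n_dyads,n_epochs,seed,keep_trials as in [run_cohort()].
#' @return An `hl_cohort` object.
#' @export
run_ablation_frozen_L <- function(init = c("correct", "perturbed"),
                                  noise_halfwidth = 0.1, gamma, n_dyads,
                                  n_epochs = 20L, seed = NULL,
                                  keep_trials = n_dyads <= 100L) {
  init <- match.arg(init)
  cohort_engine(n_dyads, n_epochs, gamma = gamma, lambda = 0, seed = seed,
                h_mode = "softmax", l_learn = FALSE, l_init = init,
                noise_halfwidth = noise_halfwidth, keep_trials = keep_trials)
}

#' Boundary-condition variant: a statistically sophisticated H-agent
#'
#' The H-agent forgoes attraction learning: it samples each filter for
#' `samples_per_filter` epochs in round-robin order, then commits once and
#' for all to the filter with the lowest mean feedback error (ties broken
#' uniformly at random).  A one-way F test on the per-epoch feedback grouped
#' by filter is computed at level `alpha` and logged per dyad
#' (`commit_p`); it does not affect the commitment.  The L-agent learns
#' throughout.
#'
#' @param samples_per_filter epochs sampled per filter before committing
#'   (requires `3 * samples_per_filter <= n_epochs`).
#' @param alpha nominal level for the logged significance test.
#' @param lambda L-agent learning rate.
#' @param n_dyads,n_epochs,seed,keep_trials as in [run_cohort()].
#' @return An `hl_cohort` object with per-dyad `committed` filter and
#'   logged `commit_p`.
#' @export
run_statistical_H <- function(samples_per_filter, alpha = 0.05, lambda,
                              n_dyads, n_epochs = 20L, seed = NULL,
                              keep_trials = n_dyads <= 100L) {
  cohort_engine(n_dyads, n_epochs, gamma = 0, lambda = lambda, seed = seed,
                h_mode = "statistical", samples_per_filter = samples_per_filter,
                alpha = alpha, keep_trials = keep_trials)
}

#' @export
print.hl_cohort <- function(x, ...) {
  cat(sprintf(
    "<hl_cohort> %s: %d dyads x %d epochs (gamma=%g, lambda=%g, seed=%s)\n",
    x$variant, x$n_dyads, x$n_epochs, x$gamma, x$lambda,
    if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  mean error epoch 1: %.2f; epoch %d: %.2f\n",
              mean(x$epoch_err[, 1L]), x$n_epochs,
              mean(x$epoch_err[, x$n_epochs])))
  if (x$zero_y_trials > 0L) {
    cat(sprintf("  note: %d trial(s) with zero target value (flagged)\n",
                x$zero_y_trials))
  }
  invisible(x)
}
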