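#' Reproduce the canonical simulated results
#'
#' Runs the baseline cohort at the canonical best-fit parameters
#' (gamma = 0.55, lambda = 1.3e-5), the two ablations (H-agent inhibited at
#' the optimal filter; L-agent frozen at correct and at perturbed weights),
#' analyses each cohort, and returns a side-by-side report of the computed
#' quantities next to the reference values this simulation suite is
#' designed to reproduce, together with the analytic constants (lowest
#' attainable error 2.5; disclosed-information rates 0.93 / 0.40 / 0.67).
#'
#' @param scale `"full"` for 20,000 dyads per cohort, `"desk"` for a
#'   faster 2,000-dyad version with the same qualitative outcomes.
#' @param seed master seed; the four cohorts use seed, seed+1, seed+2,
#'   seed+3.
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` and the mean curves as `curves.csv`.
#' @param n_boot Monte Carlo replicates for dip p-values.
#' @return List of class `hl_report` with components `constants`,
#'   `baseline`, `fixed_optimal`, `frozen_correct`, `frozen_perturbed` and
#'   `reference`.
#' @export
reproduce_simulations <- function(scale = c("desk", "full"), seed = 1L,
                                  out_dir = NULL, n_boot = 2000L) {
  scale <- match.arg(scale)
  n <- if (scale == "full") 20000L else 2000L
  gamma <- 0.55
  lambda <- 1.3e-5

  message(sprintf("baseline cohort (n = %d) ...", n))
  base <- run_cohort(n, gamma, lambda, seed = seed, keep_trials = FALSE)
  set.seed(seed + 1000L)
  base_an <- analyze_cohort(base, n_boot = n_boot)

  message("ablation: H-agent fixed at the optimal filter ...")
  fixed <- run_ablation_fixed_filter("optimal", lambda = lambda, n_dyads = n,
                                     seed = seed + 1L, keep_trials = FALSE)
  fixed_err <- last_epochs_error(fixed)
  set.seed(seed + 1001L)
  fixed_dip <- dip_test(fixed_err, n_boot = n_boot)

  message("ablation: L-agent frozen at correct weights ...")
  froz_c <- run_ablation_frozen_L("correct", gamma = gamma, n_dyads = n,
                                  seed = seed + 2L, keep_trials = FALSE)
  set.seed(seed + 1002L)
  froz_c_dip <- dip_test(last_epochs_error(froz_c), n_boot = n_boot)
  froz_c_conv <- convergence_class(froz_c)

  message("ablation: L-agent frozen at perturbed weights ...")
  froz_p <- run_ablation_frozen_L("perturbed", gamma = gamma, n_dyads = n,
                                  seed = seed + 3L, keep_trials = FALSE)
  froz_p_conv <- convergence_class(froz_p)

  nonconv_opt <- function(conv) {
    100 * mean(!(conv$converged & conv$converged_rank %in% "optimal"))
  }

  report <- structure(list(
    scale = scale, n_dyads = n, seed = seed,
    gamma = gamma, lambda = lambda,
    constants = list(
      lowest_attainable_error = lowest_attainable_error(),
      disclosed_rate_optimal = disclosed_rate(c(0.9, 0.5, 0.1), 3L),
      disclosed_rate_minimal = disclosed_rate(c(0.9, 0.5, 0.1), 1L),
      disclosed_rate_random = mean(vapply(1:3, function(h)
        disclosed_rate(c(0.9, 0.5, 0.1), h), numeric(1)))),
    baseline = list(
      dip_D = base_an$dip$statistic, dip_p = base_an$dip$p_value,
      learning_converged_opt_pct = base_an$learning_converged_opt_pct,
      deadlocked_converged_subopt_pct =
        base_an$deadlocked_converged_subopt_pct,
      nonconv_deadlocked_shares_pct = c(
        optimal = base_an$nonconv_deadlocked_opt_share_last_pct,
        second = base_an$nonconv_deadlocked_second_share_last_pct,
        worst = base_an$nonconv_deadlocked_worst_share_last_pct),
      curves = base_an$curves),
    fixed_optimal = list(
      median_last5_error = median(fixed_err),
      dip_D = fixed_dip$statistic, dip_p = fixed_dip$p_value),
    frozen_correct = list(
      dip_D = froz_c_dip$statistic, dip_p = froz_c_dip$p_value,
      nonconverged_to_opt_pct = nonconv_opt(froz_c_conv)),
    frozen_perturbed = list(
      nonconverged_to_opt_pct = nonconv_opt(froz_p_conv)),
    reference = list(
      baseline_dip_D = 0.031,
      learning_converged_opt_pct = 86,
      deadlocked_converged_subopt_pct = 58,
      nonconv_deadlocked_shares_pct = c(optimal = 24, second = 38,
                                        worst = 38),
      fixed_optimal_median_error = 4.0,
      fixed_optimal_dip_D = 0.0009,
      frozen_correct_dip_D = 0.043,
      lowest_attainable_error = 2.5,
      disclosed_rates = c(optimal = 0.93, minimal = 0.40, random = 0.67))
  ), class = "hl_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    utils::write.csv(
      data.frame(epoch = seq_along(report$baseline$curves$error),
                 mean_error = report$baseline$curves$error,
                 mean_disclosed = report$baseline$curves$disclosure),
      file.path(out_dir, "curves.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.hl_report <- function(x, ...) {
  fmt <- function(label, got, ref) {
    cat(sprintf("  %-42s %10.4g   (reference %.4g)\n", label, got, ref))
  }
  cat(sprintf("<hl_report> scale = %s (n = %d per cohort, seed = %d)\n",
              x$scale, x$n_dyads, x$seed))
  cat("analytic constants:\n")
  fmt("lowest attainable error", x$constants$lowest_attainable_error,
      x$reference$lowest_attainable_error)
  fmt("disclosed rate, optimal filter",
      x$constants$disclosed_rate_optimal, 0.93)
  fmt("disclosed rate, minimal", x$constants$disclosed_rate_minimal, 0.40)
  fmt("disclosed rate, random", x$constants$disclosed_rate_random, 0.67)
  cat("baseline cohort:\n")
  fmt("dip D of last-5 error", x$baseline$dip_D, x$reference$baseline_dip_D)
  fmt("learning dyads at optimal filter (%)",
      x$baseline$learning_converged_opt_pct,
      x$reference$learning_converged_opt_pct)
  fmt("deadlocked dyads on one suboptimal (%)",
      x$baseline$deadlocked_converged_subopt_pct,
      x$reference$deadlocked_converged_subopt_pct)
  fmt("non-converging deadlocked: optimal (%)",
      x$baseline$nonconv_deadlocked_shares_pct["optimal"], 24)
  cat("H-agent inhibited at optimal filter:\n")
  fmt("median last-5 error", x$fixed_optimal$median_last5_error,
      x$reference$fixed_optimal_median_error)
  fmt("dip D", x$fixed_optimal$dip_D, x$reference$fixed_optimal_dip_D)
  cat("L-agent frozen:\n")
  fmt("dip D (correct weights)", x$frozen_correct$dip_D,
      x$reference$frozen_correct_dip_D)
  cat(sprintf(
    "  non-convergence to optimal: correct %.1f%% < perturbed %.1f%%\n",
    x$frozen_correct$nonconverged_to_opt_pct,
    x$frozen_perturbed$nonconverged_to_opt_pct))
  invisible(x)
}
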