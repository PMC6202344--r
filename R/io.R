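#' Cohort input/output
#'
#' A cohort is written as plain delimited text plus a JSON metadata
#' document: `meta.json` (parameters, seed, counts), `dyads.csv` (weights
#' and per-dyad summaries), `epochs.csv` (one row per dyad-epoch: chosen
#' filter, feedback, error, disclosed rate, attractions and learned
#' weights) and, when trial records were kept, `trials.csv` (one row per
#' trial).  Numbers are written with 17 significant digits so the
#' round-trip reproduces doubles exactly.
#'
#' @name cohort_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

write_table17 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in required) {
    vals <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop("malformed file ", path, ": unparseable value at row ", bad[1L],
           ", column '", cn, "'")
    }
    df[[cn]] <- vals
  }
  df
}

#' Write a cohort to a directory
#'
#' @param cohort an `hl_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- cohort$n_dyads
  E <- cohort$n_epochs

  meta <- cohort[c("n_dyads", "n_epochs", "gamma", "lambda", "seed",
                   "variant", "h_mode", "l_learn", "l_init",
                   "noise_halfwidth", "samples_per_filter", "alpha",
                   "zero_y_trials")]
  meta$has_trials <- !is.null(cohort$trials)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  dyads <- data.frame(dyad = seq_len(n),
                      w1 = cohort$w[, 1L], w2 = cohort$w[, 2L],
                      w3 = cohort$w[, 3L],
                      opt_hidden = cohort$opt_hidden,
                      committed = cohort$committed,
                      commit_p = cohort$commit_p)
  write_table17(dyads, file.path(dir, "dyads.csv"))

  ep <- data.frame(
    dyad = rep(seq_len(n), E),
    epoch = rep(seq_len(E), each = n),
    hidden_index = as.vector(cohort$choice),
    feedback_pctE = as.vector(cohort$feedback),
    epoch_abs_err = as.vector(cohort$epoch_err),
    disclosed_rate = as.vector(cohort$disclosed),
    a1 = as.vector(cohort$a_hist[, 1L, ]),
    a2 = as.vector(cohort$a_hist[, 2L, ]),
    a3 = as.vector(cohort$a_hist[, 3L, ]),
    v1 = as.vector(cohort$v_hist[, 1L, ]),
    v2 = as.vector(cohort$v_hist[, 2L, ]),
    v3 = as.vector(cohort$v_hist[, 3L, ])
  )
  write_table17(ep, file.path(dir, "epochs.csv"))

  if (!is.null(cohort$trials)) {
    tr <- expand.grid(dyad = seq_len(n), epoch = seq_len(E), trial = 1:5,
                      KEEP.OUT.ATTRS = FALSE)
    tr$x1 <- as.vector(cohort$trials$x[, 1L, , ])
    tr$x2 <- as.vector(cohort$trials$x[, 2L, , ])
    tr$x3 <- as.vector(cohort$trials$x[, 3L, , ])
    tr$o <- as.vector(cohort$trials$o)
    tr$y <- as.vector(cohort$trials$y)
    tr$abs_err <- abs(tr$y - tr$o)
    tr$pct_err <- percent_error(tr$y, tr$o)
    write_table17(tr, file.path(dir, "trials.csv"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `meta.json`, `dyads.csv`, `epochs.csv`
#'   and optionally `trials.csv`.
#' @return An `hl_cohort` object equal to the one written (trial records
#'   restored when present).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n <- as.integer(meta$n_dyads)
  E <- as.integer(meta$n_epochs)

  dyads <- read_table_checked(
    file.path(dir, "dyads.csv"),
    c("dyad", "w1", "w2", "w3", "opt_hidden"))
  if (nrow(dyads) != n) {
    stop("malformed file dyads.csv: expected ", n, " rows, found ",
         nrow(dyads))
  }
  ep <- read_table_checked(
    file.path(dir, "epochs.csv"),
    c("dyad", "epoch", "hidden_index", "feedback_pctE", "epoch_abs_err",
      "disclosed_rate", "a1", "a2", "a3", "v1", "v2", "v3"))
  if (nrow(ep) != n * E) {
    stop("malformed file epochs.csv: expected ", n * E, " rows, found ",
         nrow(ep))
  }
  ord <- order(ep$epoch, ep$dyad)
  ep <- ep[ord, ]

  as_mat <- function(v) matrix(v, n, E)
  as_arr <- function(c1, c2, c3) {
    a <- array(NA_real_, c(n, 3L, E))
    a[, 1L, ] <- c1; a[, 2L, ] <- c2; a[, 3L, ] <- c3
    a
  }
  cohort <- structure(list(
    n_dyads = n, n_epochs = E, gamma = meta$gamma, lambda = meta$lambda,
    seed = meta$seed, variant = meta$variant, h_mode = meta$h_mode,
    l_learn = meta$l_learn, l_init = meta$l_init,
    noise_halfwidth = if (is.null(meta$noise_halfwidth)) NA_real_ else
      meta$noise_halfwidth,
    samples_per_filter = meta$samples_per_filter, alpha = meta$alpha,
    w = cbind(dyads$w1, dyads$w2, dyads$w3),
    opt_hidden = as.integer(dyads$opt_hidden),
    choice = matrix(as.integer(ep$hidden_index), n, E),
    feedback = as_mat(ep$feedback_pctE),
    epoch_err = as_mat(ep$epoch_abs_err),
    disclosed = as_mat(ep$disclosed_rate),
    v0 = NULL,
    v_final = cbind(matrix(ep$v1, n, E)[, E], matrix(ep$v2, n, E)[, E],
                    matrix(ep$v3, n, E)[, E]),
    attractions = cbind(matrix(ep$a1, n, E)[, E], matrix(ep$a2, n, E)[, E],
                        matrix(ep$a3, n, E)[, E]),
    a_hist = as_arr(ep$a1, ep$a2, ep$a3),
    v_hist = as_arr(ep$v1, ep$v2, ep$v3),
    committed = if ("committed" %in% names(dyads))
      as.integer(dyads$committed) else rep(NA_integer_, n),
    commit_p = if ("commit_p" %in% names(dyads)) dyads$commit_p else
      rep(NA_real_, n),
    zero_y_trials = as.integer(meta$zero_y_trials),
    trials = NULL
  ), class = "hl_cohort")

  if (isTRUE(meta$has_trials)) {
    tr <- read_table_checked(
      file.path(dir, "trials.csv"),
      c("dyad", "epoch", "trial", "x1", "x2", "x3", "o", "y"))
    if (nrow(tr) != n * E * 5L) {
      stop("malformed file trials.csv: expected ", n * E * 5L,
           " rows, found ", nrow(tr))
    }
    tr <- tr[order(tr$trial, tr$epoch, tr$dyad), ]
    x <- array(NA_real_, c(n, 3L, E, 5L))
    x[, 1L, , ] <- tr$x1; x[, 2L, , ] <- tr$x2; x[, 3L, , ] <- tr$x3
    cohort$trials <- list(
      x = x,
      o = array(tr$o, c(n, E, 5L)),
      y = array(tr$y, c(n, E, 5L))
    )
  }
  cohort
}
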