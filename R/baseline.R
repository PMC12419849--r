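#' Random-CpG baseline error distribution
#'
#' The yardstick against which clocks are judged: repeatedly sample
#' `n_cpgs` CpGs at random without replacement, fit a 10-fold
#' cross-validated elastic net of chronological age on them in the
#' training split, predict the held-out test split, and record the
#' median absolute error (overall and per tissue). Iterations use
#' sub-seeds derived deterministically from `seed`, so the first `k`
#' iterations of a long run equal a `k`-iteration run.
#'
#' @param x A [methyl_matrix()] on the M scale, covering train and test
#'   samples.
#' @param sheet Sample sheet covering the matrix samples.
#' @param split A [stratified_split()] of the samples (fixed across
#'   iterations).
#' @param n_iterations Number of random models (default 2500; scale down
#'   for desk-size experiments).
#' @param n_cpgs CpGs per model (default 350, roughly the size of a
#'   published clock).
#' @param en_alpha Elastic-net mixing parameter (default 0.5).
#' @param cv_folds Folds for the per-iteration penalty search.
#' @param seed Integer master seed.
#' @return An object of class `baseline_distribution`: `per_iteration_mae`
#'   (test-set median absolute error per iteration),
#'   `per_iteration_tissue_mae` (iteration x tissue matrix),
#'   `n_iterations`, `n_cpgs_per_iteration` and `seed`.
#' @export
run_random_baseline <- function(x, sheet, split, n_iterations = 2500,
                                n_cpgs = 350, en_alpha = 0.5, cv_folds = 10,
                                seed = 1) {
  stopifnot(inherits(x, "methyl_matrix"), is_count(n_iterations), is_count(n_cpgs))
  if (x$scale != "m") stop("baseline models are fitted on M-values", call. = FALSE)
  if (n_cpgs > ncol(x$values)) {
    stop(sprintf("n_cpgs (%d) exceeds the CpG universe (%d)", n_cpgs, ncol(x$values)),
         call. = FALSE)
  }
  sheet <- align_sheet(x, sheet)
  tr <- match(split$train_ids, sample_ids(x))
  te <- match(split$test_ids, sample_ids(x))
  if (anyNA(tr) || anyNA(te)) stop("split ids absent from matrix", call. = FALSE)
  y_tr <- sheet$age[tr]
  y_te <- sheet$age[te]
  tissue_te <- as.character(sheet$tissue)[te]
  tissues <- sort(unique(tissue_te))

  set.seed(sub_seed(seed, 51L))
  iter_seeds <- sample.int(2147483647L, n_iterations)

  mae <- numeric(n_iterations)
  tissue_mae <- matrix(NA_real_, n_iterations, length(tissues),
                       dimnames = list(NULL, tissues))
  for (i in seq_len(n_iterations)) {
    set.seed(iter_seeds[i])
    cols <- sample.int(ncol(x$values), n_cpgs)
    Xtr <- x$values[tr, cols, drop = FALSE]
    Xte <- x$values[te, cols, drop = FALSE]
    foldid <- sample(rep_len(seq_len(cv_folds), length(tr)))
    cv <- glmnet::cv.glmnet(Xtr, y_tr, alpha = en_alpha, foldid = foldid,
                            type.measure = "mae")
    pred <- as.numeric(stats::predict(cv, Xte, s = "lambda.min"))
    err <- abs(pred - y_te)
    mae[i] <- stats::median(err)
    tissue_mae[i, ] <- vapply(tissues, function(t) stats::median(err[tissue_te == t]), 0)
  }
  structure(list(per_iteration_mae = mae,
                 per_iteration_tissue_mae = tissue_mae,
                 n_iterations = n_iterations,
                 n_cpgs_per_iteration = n_cpgs,
                 seed = seed), class = "baseline_distribution")
}

#' @export
print.baseline_distribution <- function(x, ...) {
  cat(sprintf("<baseline_distribution> %d iterations x %d CpGs, median MAE %.2f y\n",
              x$n_iterations, x$n_cpgs_per_iteration,
              stats::median(x$per_iteration_mae)))
  invisible(x)
}

#' Compare clock error distributions
#'
#' Pairwise Student's t-tests of absolute-error vectors against a
#' reference (typically the random-CpG baseline): for each comparison the
#' mean difference, its 95% confidence interval, the p-value and the
#' Benjamini-Hochberg FDR across the requested family. Zero-variance
#' inputs are flagged as degenerate instead of tested.
#'
#' @param errors A numeric vector of absolute errors (years) or a named
#'   list of such vectors (one per clock).
#' @param reference Reference errors: a numeric vector or a
#'   `baseline_distribution` (its per-iteration MAEs are used).
#' @param var_equal Use the classical equal-variance Student's t-test
#'   (default `TRUE`); `FALSE` gives Welch.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A data frame with one row per comparison: `comparison`,
#'   `mean_diff` (errors minus reference), `ci_low`, `ci_high`, `p`,
#'   `fdr`, `degenerate`.
#' @export
compare_errors <- function(errors, reference, var_equal = TRUE,
                           conf_level = 0.95) {
  if (inherits(reference, "baseline_distribution")) {
    reference <- reference$per_iteration_mae
  }
  if (!is.list(errors)) errors <- list(clock = errors)
  if (is.null(names(errors)) || any(!nzchar(names(errors)))) {
    names(errors) <- paste0("clock", seq_along(errors))
  }
  rows <- lapply(names(errors), function(nm) {
    a <- errors[[nm]]
    if (!length(a) || !length(reference)) stop("empty error vector", call. = FALSE)
    if (stats::sd(a) == 0 && stats::sd(reference) == 0) {
      return(data.frame(comparison = nm, mean_diff = mean(a) - mean(reference),
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(a, reference, var.equal = var_equal,
                        conf.level = conf_level)
    data.frame(comparison = nm, mean_diff = unname(diff(rev(tt$estimate))),
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !out$degenerate
  out$fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[, c("comparison", "mean_diff", "ci_low", "ci_high", "p", "fdr", "degenerate")]
}
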