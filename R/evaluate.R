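# Single source of truth for per-sample age acceleration:
# predicted age minus chronological age, joined on sample_id.
acceleration_table <- function(predictions, sheet) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(predictions$sample_id, sheet$sample_id)
  if (anyNA(idx)) {
    stop("predictions contain samples absent from the sheet: ",
         paste(utils::head(predictions$sample_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  data.frame(sample_id = predictions$sample_id,
             predicted_age = predictions$predicted_age,
             age = sheet$age[idx],
             tissue = as.character(sheet$tissue)[idx],
             replicate_group = sheet$replicate_group[idx],
             population_doublings = sheet$population_doublings[idx],
             condition = sheet$condition[idx],
             acceleration = predictions$predicted_age - sheet$age[idx],
             stringsAsFactors = FALSE)
}

#' Accuracy report for a set of age predictions
#'
#' Computes the package's standard accuracy summary: per-sample age
#' acceleration (predicted minus chronological), its median absolute
#' value overall and per tissue, the R-squared of the regression of
#' predicted on chronological age, and per-sample errors as a
#' percentage of chronological age (samples aged 0 are excluded from the
#' percentage with a warning).
#'
#' @param predictions Output of [predict_age()] (`sample_id`,
#'   `predicted_age`).
#' @param sheet Sample sheet with chronological ages.
#' @return An object of class `evaluation_report`:
#'   `overall_median_abs_error`, `per_tissue_median_abs_error`,
#'   `r_squared`, `error_as_pct_of_age`, `n_by_tissue`, `accelerations`.
#' @export
evaluation_report <- function(predictions, sheet) {
  acc <- acceleration_table(predictions, sheet)
  per_tissue <- tapply(abs(acc$acceleration), acc$tissue, stats::median)
  per_tissue <- stats::setNames(as.numeric(per_tissue), names(per_tissue))
  pct <- rep(NA_real_, nrow(acc))
  nonzero <- acc$age > 0
  if (any(!nonzero)) {
    warning(sprintf("%d sample(s) aged 0 excluded from percentage errors",
                    sum(!nonzero)), call. = FALSE)
  }
  pct[nonzero] <- 100 * abs(acc$acceleration[nonzero]) / acc$age[nonzero]
  r2 <- if (stats::sd(acc$age) == 0) NA_real_ else
    summary(stats::lm(predicted_age ~ age, data = acc))$r.squared
  structure(list(
    overall_median_abs_error = stats::median(abs(acc$acceleration)),
    per_tissue_median_abs_error = per_tissue[sort(names(per_tissue))],
    r_squared = r2,
    error_as_pct_of_age = stats::setNames(pct, acc$sample_id),
    n_by_tissue = table(acc$tissue),
    accelerations = stats::setNames(acc$acceleration, acc$sample_id)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> median |error| %.2f y, R^2 %.3f\n",
              x$overall_median_abs_error, x$r_squared))
  pt <- x$per_tissue_median_abs_error
  for (t in names(pt)) cat(sprintf("  %-12s %.2f y (n = %d)\n", t, pt[[t]],
                                   x$n_by_tissue[[t]]))
  invisible(x)
}

#' Technical-replicate concordance of age predictions
#'
#' For each replicate pair (samples sharing a `replicate_group`), the
#' signed difference in predicted age (second member minus first, in
#' sheet order -- e.g. platform B minus platform A) and the median
#' difference across pairs. Replicate groups without exactly two members
#' are an error.
#'
#' @param predictions Output of [predict_age()].
#' @param sheet Sample sheet defining `replicate_group` pairs.
#' @return A list with `pairs` (data frame: `replicate_group`,
#'   `difference`), `median_difference` and `median_abs_difference`.
#' @export
replicate_concordance <- function(predictions, sheet) {
  acc <- acceleration_table(predictions, sheet)
  acc <- acc[!is.na(acc$replicate_group), , drop = FALSE]
  if (!nrow(acc)) stop("no replicate pairs defined in the sheet", call. = FALSE)
  counts <- table(acc$replicate_group)
  if (any(counts != 2L)) {
    stop("replicate group(s) without exactly 2 members: ",
         paste(utils::head(names(counts)[counts != 2L], 5), collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(acc$replicate_group)
  diffs <- vapply(groups, function(g) {
    p <- acc$predicted_age[acc$replicate_group == g]
    p[2] - p[1]
  }, 0)
  list(pairs = data.frame(replicate_group = groups, difference = diffs,
                          stringsAsFactors = FALSE),
       median_difference = stats::median(diffs),
       median_abs_difference = stats::median(abs(diffs)))
}

#' Regression of predicted age on population doublings
#'
#' The in-vitro ageing-rate readout: ordinary least squares of predicted
#' age (not acceleration -- intercepts stay on the age scale) on
#' cumulative population doublings, giving the clock's "ticking rate" in
#' years per doubling. Pass a named list of prediction tables to compare
#' several clocks on the same series; p-values are then BH-adjusted
#' across the family.
#'
#' @param predictions Output of [predict_age()], or a named list of such
#'   tables.
#' @param sheet Sample sheet with `population_doublings`.
#' @return A data frame with one row per clock: `clock`, `slope`
#'   (years/doubling), `intercept`, `r_squared`, `p_value`, `fdr`,
#'   `slope_se`, `n`.
#' @export
doubling_regression <- function(predictions, sheet) {
  single <- !is.null(predictions$sample_id)
  preds <- if (single) list(clock = predictions) else predictions
  if (is.null(names(preds)) || any(!nzchar(names(preds)))) {
    names(preds) <- paste0("clock", seq_along(preds))
  }
  rows <- lapply(names(preds), function(nm) {
    acc <- acceleration_table(preds[[nm]], sheet)
    acc <- acc[!is.na(acc$population_doublings), , drop = FALSE]
    if (nrow(acc) < 2L) stop("need >= 2 samples with population doublings", call. = FALSE)
    if (stats::sd(acc$population_doublings) == 0) {
      stop("population doublings are constant; no regression possible", call. = FALSE)
    }
    fit <- stats::lm(predicted_age ~ population_doublings, data = acc)
    sm <- summary(fit)
    data.frame(clock = nm,
               slope = sm$coefficients[2, 1],
               intercept = sm$coefficients[1, 1],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               slope_se = sm$coefficients[2, 2],
               n = nrow(acc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("clock", "slope", "intercept", "r_squared", "p_value", "fdr",
          "slope_se", "n")]
}

#' Group age-acceleration contrasts
#'
#' Tests whether experimental groups differ in mean age acceleration:
#' for each requested contrast, a Student's t-test (equal variances; set
#' `var_equal = FALSE` for Welch) of per-sample accelerations between
#' the two groups, with Benjamini-Hochberg adjustment across the
#' requested family. The family is an explicit argument because the FDR
#' depends on it. Contrasts involving a group with fewer than 2 samples
#' are skipped with a warning.
#'
#' @param predictions Output of [predict_age()].
#' @param sheet Sample sheet whose `condition` column (or
#'   `group_col`) labels the groups.
#' @param contrasts List of length-2 character vectors `c(group_a,
#'   group_b)`; default: all pairs of observed groups.
#' @param group_col Sheet column holding the group labels (default
#'   `"condition"`).
#' @param var_equal Student (default) vs Welch.
#' @return A data frame: `group_a`, `group_b`, `mean_diff` (a minus b,
#'   years), `p`, `fdr`, `n_a`, `n_b`.
#' @export
group_acceleration_test <- function(predictions, sheet, contrasts = NULL,
                                    group_col = "condition", var_equal = TRUE) {
  acc <- acceleration_table(predictions, sheet)
  sheet <- validate_sample_sheet(sheet)
  grp <- as.character(sheet[[group_col]])[match(acc$sample_id, sheet$sample_id)]
  acc <- acc[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]
  if (is.null(contrasts)) {
    g <- sort(unique(grp))
    if (length(g) < 2L) stop("need at least 2 groups to contrast", call. = FALSE)
    contrasts <- utils::combn(g, 2, simplify = FALSE)
  }
  rows <- lapply(contrasts, function(ct) {
    a <- acc$acceleration[grp == ct[1]]
    b <- acc$acceleration[grp == ct[2]]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("contrast %s vs %s skipped (singleton group)", ct[1], ct[2]),
              call. = FALSE)
      return(NULL)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      p <- 1 # identical degenerate groups: no evidence of a difference
    } else {
      p <- stats::t.test(a, b, var.equal = var_equal)$p.value
    }
    data.frame(group_a = ct[1], group_b = ct[2], mean_diff = mean(a) - mean(b),
               p = p, n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no testable contrasts", call. = FALSE)
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("group_a", "group_b", "mean_diff", "p", "fdr", "n_a", "n_b")]
}
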