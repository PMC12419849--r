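#' Filter probes by quality and annotation rules
#'
#' Applies the standard array-cleaning rules to a methylation matrix:
#' removes CpGs that (a) fail detection (detection p-value above
#' `p_threshold` in more than `max_fail_fraction` of samples, when a
#' detection matrix is supplied), (b) sit within 2 bp of a SNP, (c) map
#' to chromosome X or Y, or (d) cross-hybridise to multiple genomic
#' locations. Rules are applied in that order and each CpG is counted
#' under the first rule that removes it. The operation is idempotent.
#'
#' @param x A [methyl_matrix()].
#' @param annotation Probe annotation data frame
#'   (see [read_probe_annotation()]).
#' @param detection_p Optional numeric matrix of detection p-values,
#'   samples x CpGs, aligned to `x` by dimnames.
#' @param p_threshold Detection p-value above which a probe fails in a
#'   sample (default 0.01).
#' @param max_fail_fraction Fraction of samples allowed to fail detection
#'   before the CpG is removed. The default 0 removes a CpG failing in
#'   any sample (the strictest reading); raise to tolerate sporadic
#'   failures.
#' @param missing_annotation `"keep"` (default) keeps un-annotated CpGs
#'   with a warning; `"error"` aborts.
#' @return A list with `matrix` (the filtered `methyl_matrix`) and
#'   `report` (a data frame of removal counts per rule).
#' @export
filter_probes <- function(x, annotation, detection_p = NULL, p_threshold = 0.01,
                          max_fail_fraction = 0,
                          missing_annotation = c("keep", "error")) {
  stopifnot(inherits(x, "methyl_matrix"))
  missing_annotation <- match.arg(missing_annotation)
  cpgs <- cpg_ids(x)
  idx <- match(cpgs, annotation$cpg_id)
  if (anyNA(idx)) {
    unannotated <- cpgs[is.na(idx)]
    if (missing_annotation == "error") {
      stop("no annotation for CpG(s): ",
           paste(utils::head(unannotated, 5), collapse = ", "), call. = FALSE)
    }
    warning(sprintf("%d CpG(s) lack annotation and are kept", length(unannotated)),
            call. = FALSE)
  }
  ann <- annotation[idx, , drop = FALSE]

  fails_detection <- rep(FALSE, length(cpgs))
  if (!is.null(detection_p)) {
    if (!all(cpgs %in% colnames(detection_p)) ||
        !all(sample_ids(x) %in% rownames(detection_p))) {
      stop("detection_p matrix is not aligned to the methylation matrix", call. = FALSE)
    }
    dp <- detection_p[sample_ids(x), cpgs, drop = FALSE]
    fails_detection <- colMeans(dp > p_threshold, na.rm = TRUE) > max_fail_fraction
  }
  chrom <- toupper(sub("^CHR", "", toupper(ifelse(is.na(ann$chromosome), "", ann$chromosome))))
  on_sex <- chrom %in% c("X", "Y")
  snp <- !is.na(ann$snp_within_2bp) & ann$snp_within_2bp
  xhyb <- !is.na(ann$cross_hybridising) & ann$cross_hybridising

  rule <- rep(NA_character_, length(cpgs))
  rule[xhyb] <- "cross_hybridising"
  rule[on_sex] <- "sex_chromosome"
  rule[snp] <- "snp_within_2bp"
  rule[fails_detection] <- "detection_p"

  keep <- is.na(rule)
  report <- data.frame(
    rule = c("detection_p", "snp_within_2bp", "sex_chromosome", "cross_hybridising"),
    n_removed = c(sum(rule == "detection_p", na.rm = TRUE),
                  sum(rule == "snp_within_2bp", na.rm = TRUE),
                  sum(rule == "sex_chromosome", na.rm = TRUE),
                  sum(rule == "cross_hybridising", na.rm = TRUE))
  )
  list(matrix = structure(list(values = x$values[, keep, drop = FALSE], scale = x$scale),
                          class = "methyl_matrix"),
       report = report)
}

#' Convert between beta and M scales
#'
#' `beta_to_m()` computes `M = log2(beta / (1 - beta))`; `m_to_beta()`
#' inverts it. Missing values are preserved. The conversion is exact up
#' to the clipping applied at read time, so the round-trip is the
#' identity on `[1e-6, 1 - 1e-6]`.
#'
#' @param x A [methyl_matrix()] on the matching scale.
#' @return A `methyl_matrix` on the other scale.
#' @export
beta_to_m <- function(x) {
  stopifnot(inherits(x, "methyl_matrix"))
  if (x$scale != "beta") stop("matrix is not on the beta scale", call. = FALSE)
  m <- log2(x$values / (1 - x$values))
  structure(list(values = m, scale = "m"), class = "methyl_matrix")
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(x) {
  stopifnot(inherits(x, "methyl_matrix"))
  if (x$scale != "m") stop("matrix is not on the M scale", call. = FALSE)
  b <- 2^x$values / (1 + 2^x$values)
  structure(list(values = b, scale = "beta"), class = "methyl_matrix")
}

#' K-nearest-neighbour imputation of missing methylation values
#'
#' Each missing cell is replaced by the mean of that CpG's value in the
#' `k` nearest samples, where distance between two samples is the
#' Euclidean distance over their mutually observed CpGs rescaled by the
#' number of CpGs used (so samples with different missingness patterns
#' are comparable). Neighbours lacking the CpG themselves are skipped in
#' favour of the next nearest; observed values are never altered.
#'
#' @param x A [methyl_matrix()].
#' @param k Number of neighbours (default 10, capped at n - 1).
#' @param max_missing Per-CpG missingness ceiling (fraction, default 0.5);
#'   a CpG above it aborts with an error.
#' @return The imputed `methyl_matrix`.
#' @export
knn_impute <- function(x, k = 10, max_missing = 0.5) {
  stopifnot(inherits(x, "methyl_matrix"))
  v <- x$values
  if (!anyNA(v)) return(x)
  n <- nrow(v)
  if (any(rowSums(!is.na(v)) == 0L)) {
    stop("sample(s) with all values missing cannot be imputed", call. = FALSE)
  }
  frac <- colMeans(is.na(v))
  if (any(frac > max_missing)) {
    stop(sprintf("%d CpG(s) exceed the %.0f%% missingness ceiling",
                 sum(frac > max_missing), 100 * max_missing), call. = FALSE)
  }
  k <- min(k, n - 1L)
  # dist() on rows uses pairwise complete coordinates rescaled by the
  # number used -- exactly the contract above.
  d <- as.matrix(stats::dist(v))
  diag(d) <- Inf
  miss <- which(is.na(v), arr.ind = TRUE)
  for (row in unique(miss[, 1])) {
    nb_order <- order(d[row, ])
    for (j in miss[miss[, 1] == row, 2]) {
      avail <- nb_order[!is.na(x$values[nb_order, j])] # originally observed only
      if (!length(avail)) { # no neighbour observed: fall back to CpG mean
        v[row, j] <- mean(x$values[, j], na.rm = TRUE)
        next
      }
      v[row, j] <- mean(x$values[utils::head(avail, k), j])
    }
  }
  structure(list(values = v, scale = x$scale), class = "methyl_matrix")
}

#' Log-linear age transformation
#'
#' The transform used as the clock's regression target: logarithmic in
#' childhood and linear in adulthood, continuous and strictly increasing,
#' with its junction at `adult_age` (20 years):
#' `F(age) = log(age + 1) - log(adult_age + 1)` for `age < adult_age`,
#' and `F(age) = (age - adult_age) / (adult_age + 1)` otherwise
#' (natural log). `inverse_transform_age()` maps predictions back to
#' years.
#'
#' @param age Non-negative ages in years (vectorised).
#' @param f Transformed values (any finite real).
#' @param adult_age Junction age in years (default 20).
#' @return Numeric vector.
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  ifelse(age < adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @export
inverse_transform_age <- function(f, adult_age = 20) {
  ifelse(f < 0,
         exp(f + log(adult_age + 1)) - 1,
         f * (adult_age + 1) + adult_age)
}

#' Stratified train/test split
#'
#' Randomly partitions samples into training and test sets within each
#' stratum, so every tissue (and dataset) contributes the same fraction
#' to training. The training share of a stratum of size `s` is
#' `round(fraction * s)`.
#'
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param fraction Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed; the assignment is deterministic given
#'   (sheet, fraction, seed).
#' @param by `"tissue_dataset"` (default) stratifies on the tissue x
#'   dataset interaction; `"tissue"` on tissue alone.
#' @return A list with `train_ids`, `test_ids`, `strata` (named by
#'   sample) and `fraction`.
#' @export
stratified_split <- function(sheet, fraction = 0.7, seed = 1,
                             by = c("tissue_dataset", "tissue")) {
  by <- match.arg(by)
  sheet <- validate_sample_sheet(sheet)
  if (!is_prob(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  strata <- if (by == "tissue") as.character(sheet$tissue) else
    paste(sheet$tissue, sheet$dataset, sep = "|")
  names(strata) <- sheet$sample_id
  sizes <- table(strata)
  if (any(sizes < 2L)) {
    stop("singleton stratum (cannot be split): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  train <- character(0)
  for (s in sort(unique(strata))) {
    ids <- sheet$sample_id[strata == s]
    n_train <- round(fraction * length(ids))
    n_train <- min(max(n_train, 1L), length(ids) - 1L) # both sides non-empty
    train <- c(train, sample(ids, n_train))
  }
  list(train_ids = sort(train),
       test_ids = sort(setdiff(sheet$sample_id, train)),
       strata = strata,
       fraction = fraction)
}

#' Per-tissue correlation pre-filter of candidate CpGs
#'
#' Computes, within each tissue, the Pearson correlation between every
#' CpG's M-value and chronological age, and retains a CpG when the
#' per-tissue correlations satisfy the rule: `"max"` (default) keeps a
#' CpG whose absolute correlation reaches `threshold` in at least one
#' tissue, `"mean"` averages |r| over tissues, `"pooled"` correlates over
#' all samples at once. Zero-variance CpGs get r = 0. Tissues with fewer
#' than `min_tissue_n` samples are excluded from the criterion with a
#' warning.
#'
#' @param x A [methyl_matrix()] on the M scale.
#' @param sheet Sample sheet covering the matrix samples.
#' @param threshold Absolute-correlation cutoff (default 0.3).
#' @param rule Combination rule over tissues; see above.
#' @param min_tissue_n Minimum samples for a tissue to count (default 3).
#' @return A list with `cpg_ids` (retained, in matrix order), `r_table`
#'   (CpG x tissue correlations; for `"pooled"`, a single column) and
#'   `threshold`.
#' @export
correlation_prefilter <- function(x, sheet, threshold = 0.3,
                                  rule = c("max", "mean", "pooled"),
                                  min_tissue_n = 3) {
  stopifnot(inherits(x, "methyl_matrix"))
  if (x$scale != "m") stop("pre-filter operates on M-values; convert first", call. = FALSE)
  rule <- match.arg(rule)
  sheet <- align_sheet(x, sheet)
  tissues <- sort(unique(as.character(sheet$tissue)))

  cor_block <- function(rows) {
    r <- suppressWarnings(
      stats::cor(x$values[rows, , drop = FALSE], sheet$age[rows],
                 use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0 # zero variance or too few pairs
    r
  }

  if (rule == "pooled") {
    r_table <- cor_block(seq_len(nrow(sheet)))
    colnames(r_table) <- "pooled"
    score <- abs(r_table[, 1])
  } else {
    usable <- tissues[vapply(tissues, function(t) sum(sheet$tissue == t), 0L) >= min_tissue_n]
    dropped <- setdiff(tissues, usable)
    if (length(dropped)) {
      warning("tissue(s) with < ", min_tissue_n, " samples excluded from pre-filter: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    if (!length(usable)) stop("no tissue has enough samples for the pre-filter", call. = FALSE)
    r_table <- vapply(usable, function(t) cor_block(which(sheet$tissue == t))[, 1],
                      numeric(ncol(x$values)))
    score <- if (rule == "max") apply(abs(r_table), 1, max) else rowMeans(abs(r_table))
  }
  keep <- score >= threshold
  list(cpg_ids = cpg_ids(x)[keep], r_table = r_table, threshold = threshold)
}
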