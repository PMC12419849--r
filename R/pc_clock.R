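#' Principal components of a selected CpG matrix
#'
#' Centers each CpG by its training mean (no variance scaling --
#' M-values share a scale) and computes the singular value decomposition
#' of the centered matrix. All components up to numerical rank are
#' retained; shrinkage in the downstream elastic net subsumes component
#' truncation. Each loading column's sign is fixed so its
#' largest-magnitude entry is positive, making the decomposition
#' deterministic.
#'
#' @param M Numeric matrix (samples x selected CpGs) on the M scale, or
#'   a [methyl_matrix()]; missing values are an error (impute first with
#'   [knn_impute()]).
#' @return A list with `center` (per-CpG training means), `loadings`
#'   (CpG x component, orthonormal), `scores` (sample x component) and
#'   `d` (singular values).
#' @export
fit_pcs <- function(M) {
  if (inherits(M, "methyl_matrix")) {
    if (M$scale != "m") stop("principal components are computed on M-values", call. = FALSE)
    M <- M$values
  }
  if (anyNA(M)) stop("matrix has missing values; run knn_impute() first", call. = FALSE)
  if (nrow(M) < 2L) stop("at least 2 samples are required", call. = FALSE)
  center <- colMeans(M)
  Xc <- sweep(M, 2, center)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8)
  rank <- max(rank, 1L)
  loadings <- sv$v[, seq_len(rank), drop = FALSE]
  # sign convention: largest-|entry| of each column is positive
  flip <- vapply(seq_len(rank), function(j) {
    i <- which.max(abs(loadings[, j]))
    loadings[i, j] < 0
  }, logical(1))
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  rownames(loadings) <- colnames(M)
  scores <- Xc %*% loadings
  list(center = center, loadings = loadings, scores = scores,
       d = sv$d[seq_len(rank)])
}

#' Train a principal-component elastic-net clock
#'
#' The final clock construction: the training matrix is restricted to
#' `selected_cpgs` (typically the GA winner), its M-values are
#' decomposed into principal components ([fit_pcs()]), and an elastic
#' net (mixing `en_alpha`, penalty chosen by seeded `cv_folds`-fold
#' cross-validation minimising MAE) regresses the *transformed* age
#' ([transform_age()]) on the PC scores. The returned [clock_model()]
#' carries everything needed to place new samples into the same PC space
#' and invert the transform.
#'
#' @param M_train A [methyl_matrix()] on the M scale (or bare matrix) of
#'   training samples.
#' @param sheet_train Sample sheet covering the training samples.
#' @param selected_cpgs Non-empty character vector of CpGs to build on.
#' @param en_alpha Elastic-net mixing parameter (default 0.5; 0 = ridge,
#'   1 = lasso).
#' @param cv_folds Cross-validation folds for the penalty (reduced with
#'   a warning when there are fewer samples).
#' @param seed Integer seed for the fold assignment.
#' @return A [clock_model()].
#' @export
train_clock <- function(M_train, sheet_train, selected_cpgs,
                        en_alpha = 0.5, cv_folds = 10, seed = 1) {
  if (!length(selected_cpgs)) stop("`selected_cpgs` must be non-empty", call. = FALSE)
  M <- if (inherits(M_train, "methyl_matrix")) {
    if (M_train$scale != "m") stop("clock is trained on M-values; convert first", call. = FALSE)
    M_train$values
  } else M_train
  sheet <- validate_sample_sheet(sheet_train)
  sheet <- sheet[match(rownames(M), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sheet does not cover all training samples", call. = FALSE)
  missing <- setdiff(selected_cpgs, colnames(M))
  if (length(missing)) {
    stop("selected CpGs absent from training matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  M <- M[, selected_cpgs, drop = FALSE]
  if (anyNA(M)) stop("training matrix has missing values; impute first", call. = FALSE)

  pcs <- fit_pcs(M)
  y <- transform_age(sheet$age)
  n <- nrow(M)
  if (n < cv_folds) {
    cv_folds <- max(3L, n %/% 2L)
    warning(sprintf("cv_folds reduced to %d (only %d samples)", cv_folds, n),
            call. = FALSE)
  }
  set.seed(sub_seed(seed, 41L))
  foldid <- sample(rep_len(seq_len(cv_folds), n))
  if (ncol(pcs$scores) >= 2L) {
    # explicit penalty grid: glmnet's default path stops early once the
    # deviance saturates, which strands near-interpolating fits
    lmax <- max(abs(crossprod(pcs$scores, y - mean(y)))) / (n * max(en_alpha, 0.001))
    lambda <- exp(seq(log(lmax), log(lmax * 1e-8), length.out = 100))
    cv <- glmnet::cv.glmnet(pcs$scores, y, alpha = en_alpha, foldid = foldid,
                            type.measure = "mae", standardize = FALSE,
                            lambda = lambda, thresh = 1e-10)
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))
    intercept <- co[1]
    coefficients <- co[-1]
    lambda <- cv$lambda.min
  } else { # a single component: ordinary least squares
    fit <- stats::lm(y ~ pcs$scores[, 1])
    intercept <- stats::coef(fit)[[1]]
    coefficients <- stats::coef(fit)[[2]]
    lambda <- 0
  }
  clock_model(
    cpg_ids = selected_cpgs,
    center = pcs$center,
    loadings = pcs$loadings,
    intercept = intercept,
    coefficients = coefficients,
    training_metadata = list(
      tissues = sort(unique(as.character(sheet$tissue))),
      n_train = n,
      n_by_tissue = as.list(table(as.character(sheet$tissue))),
      en_alpha = en_alpha, lambda = lambda, cv_folds = cv_folds, seed = seed
    )
  )
}

#' Predict epigenetic age for new samples
#'
#' Places new M-values into the clock's training PC space (subtract the
#' training means, multiply by the stored loadings), applies the elastic
#' net coefficients, and inverts the age transform to years. CpGs absent
#' from `M_new` are filled with their training mean -- exactly "no
#' information" after centering -- with a warning; if more than
#' `max_missing` of the clock's CpGs are absent the prediction aborts
#' instead of degrading silently.
#'
#' @param model A [clock_model()].
#' @param M_new A [methyl_matrix()] on the M scale (or bare matrix).
#' @param sheet Optional sample sheet; when it provides ages, the age
#'   acceleration (predicted - chronological) is filled in.
#' @param max_missing Ceiling on the fraction of model CpGs that may be
#'   absent from `M_new` (default 0.05).
#' @param transformed Return predictions on the transformed-age scale
#'   instead of years (default `FALSE`).
#' @return A data frame with `sample_id`, `predicted_age` and
#'   `age_acceleration` (`NA` without chronological ages).
#' @export
predict_age <- function(model, M_new, sheet = NULL, max_missing = 0.05,
                        transformed = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  M <- if (inherits(M_new, "methyl_matrix")) {
    if (M_new$scale != "m") stop("predictions require M-values; convert first", call. = FALSE)
    M_new$values
  } else M_new
  absent <- setdiff(model$cpg_ids, colnames(M))
  frac <- length(absent) / length(model$cpg_ids)
  if (frac > max_missing) {
    stop(sprintf("%d of %d clock CpGs (%.1f%%) absent from input (ceiling %.0f%%)",
                 length(absent), length(model$cpg_ids), 100 * frac,
                 100 * max_missing), call. = FALSE)
  }
  X <- matrix(rep(model$center, each = nrow(M)), nrow = nrow(M),
              dimnames = list(rownames(M), model$cpg_ids))
  present <- intersect(model$cpg_ids, colnames(M))
  X[, present] <- M[, present, drop = FALSE]
  if (length(absent)) {
    warning(sprintf("%d clock CpG(s) absent; filled with training means", length(absent)),
            call. = FALSE)
  }
  if (anyNA(X)) { # per-cell missingness also falls back to the training mean
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- model$center[idx[, 2]]
  }
  scores <- sweep(X, 2, model$center) %*% model$loadings
  f <- as.numeric(model$intercept + scores %*% model$coefficients)
  pred <- if (transformed) f else
    inverse_transform_age(f, model$age_transform$adult_age)
  out <- data.frame(sample_id = rownames(M), predicted_age = pred,
                    age_acceleration = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    age <- sheet$age[match(out$sample_id, sheet$sample_id)]
    out$age_acceleration <- out$predicted_age - age
  }
  out
}

#' Train the full-matrix PCA comparator clock
#'
#' Identical construction to [train_clock()] but on the whole candidate
#' matrix, skipping GA selection. Exists to measure what feature
#' selection buys: principal components of everything versus principal
#' components of the selected CpGs.
#'
#' @inheritParams train_clock
#' @param candidate_cpgs CpGs to use (default: every column of
#'   `M_train`).
#' @return A [clock_model()].
#' @export
baseline_pca_clock <- function(M_train, sheet_train, candidate_cpgs = NULL,
                               en_alpha = 0.5, cv_folds = 10, seed = 1) {
  M <- if (inherits(M_train, "methyl_matrix")) M_train else NULL
  cols <- candidate_cpgs %||% (if (is.null(M)) colnames(M_train) else cpg_ids(M))
  train_clock(M_train, sheet_train, cols, en_alpha = en_alpha,
              cv_folds = cv_folds, seed = seed)
}
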