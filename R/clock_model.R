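MODEL_SCHEMA <- "gaclock-clock/1"

#' Construct a clock model object
#'
#' A fitted clock is fully described by: the ordered list of selected
#' CpGs, their training-mean M-values (`center`), the orthonormal PC
#' `loadings` (CpG x component), and the elastic-net `intercept` and
#' per-component `coefficients` on the transformed-age scale, together
#' with the age-transform junction (`adult_age`, 20 years). Prediction is
#' a pure function of these fields, so a model can be serialized,
#' shipped and reloaded without loss (see [write_model()]).
#'
#' @param cpg_ids Ordered character vector of selected CpGs.
#' @param center Numeric vector of training mean M-values, one per CpG.
#' @param loadings Numeric matrix, CpGs x components, orthonormal columns.
#' @param intercept,coefficients Elastic-net parameters on PC scores.
#' @param adult_age Junction of the log-linear age transform (years).
#' @param training_metadata Free-form list (tissues, sample counts, seeds).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(cpg_ids, center, loadings, intercept, coefficients,
                        adult_age = 20, training_metadata = list()) {
  cpg_ids <- as.character(cpg_ids)
  check_unique_ids(cpg_ids, "CpG")
  loadings <- as.matrix(loadings)
  if (length(center) != length(cpg_ids) || nrow(loadings) != length(cpg_ids)) {
    stop("center and loadings rows must match cpg_ids", call. = FALSE)
  }
  if (ncol(loadings) != length(coefficients)) {
    stop("one coefficient per loading column required", call. = FALSE)
  }
  gram <- crossprod(loadings)
  if (max(abs(gram - diag(ncol(loadings)))) > 1e-8) {
    stop("loading columns must be orthonormal (tolerance 1e-8)", call. = FALSE)
  }
  structure(list(
    cpg_ids = cpg_ids,
    center = as.numeric(center),
    loadings = unname(loadings),
    n_components = ncol(loadings),
    intercept = as.numeric(intercept),
    coefficients = as.numeric(coefficients),
    age_transform = list(adult_age = adult_age),
    training_metadata = training_metadata
  ), class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d CpGs, %d principal components\n",
              length(x$cpg_ids), x$n_components))
  invisible(x)
}

#' Serialize / deserialize a clock model
#'
#' The model is written as a single self-describing JSON container with a
#' schema version and full-precision numeric blocks; `read_model()`
#' refuses files whose schema it does not know rather than misreading
#' them. `read_model(write_model(m))` is the identity for all fields.
#'
#' @param model A [clock_model()].
#' @param path File path (conventionally `.json`).
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns the reconstructed `clock_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  payload <- list(
    schema = MODEL_SCHEMA,
    cpg_ids = model$cpg_ids,
    center = model$center,
    loadings = model$loadings,      # serialized row-wise as nested arrays
    n_components = model$n_components,
    intercept = model$intercept,
    coefficients = model$coefficients,
    age_transform = model$age_transform,
    training_metadata = model$training_metadata
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("not a readable model container: ", conditionMessage(e),
                             call. = FALSE)
                      })
  if (!identical(payload$schema, MODEL_SCHEMA)) {
    stop(sprintf("model schema mismatch: found %s, expected %s",
                 deparse(payload$schema), MODEL_SCHEMA), call. = FALSE)
  }
  loadings <- matrix(as.numeric(payload$loadings), nrow = length(payload$cpg_ids))
  clock_model(
    cpg_ids = payload$cpg_ids,
    center = payload$center,
    loadings = loadings,
    intercept = payload$intercept,
    coefficients = payload$coefficients,
    adult_age = payload$age_transform$adult_age,
    training_metadata = payload$training_metadata
  )
}
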