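#' Construct a methylation matrix
#'
#' The universal payload of the package: a numeric matrix of methylation
#' values with samples in rows and CpGs in columns, tagged with its
#' measurement scale. Beta values are methylation fractions in (0, 1);
#' M-values are `log2(beta / (1 - beta))` and may be any finite real.
#' Missing values (`NA`) are allowed on either scale.
#'
#' @param values Numeric matrix, samples x CpGs, with unique non-empty
#'   rownames (sample ids) and colnames (CpG ids).
#' @param scale `"beta"` or `"m"`.
#' @return An object of class `methyl_matrix`: a list with elements
#'   `values` and `scale`.
#' @seealso [read_matrix()], [beta_to_m()], [m_to_beta()]
#' @export
methyl_matrix <- function(values, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x CpGs)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (sample ids) and colnames (CpG ids)",
         call. = FALSE)
  }
  check_unique_ids(rownames(values), "sample")
  check_unique_ids(colnames(values), "CpG")
  v <- values[is.finite(values)]
  if (scale == "beta" && length(v) && (min(v) <= 0 || max(v) >= 1)) {
    stop("beta values must lie strictly inside (0, 1); ",
         "use read_matrix() for clipping or convert scales explicitly",
         call. = FALSE)
  }
  if (scale == "m" && any(is.infinite(values))) {
    stop("M-values must be finite or missing", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "methyl_matrix")
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s ids must be non-empty strings", what), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$values)

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d samples x %d CpGs, %s scale, %d missing\n",
              nrow(x$values), ncol(x$values), x$scale, sum(is.na(x$values))))
  invisible(x)
}

#' Sample and CpG identifiers of a methylation matrix
#' @param x A `methyl_matrix`.
#' @return Character vector of ids in storage order.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
cpg_ids <- function(x) colnames(x$values)

# Restrict to a CpG subset (order given by `cpgs`), keeping the class.
subset_cpgs <- function(x, cpgs) {
  missing <- setdiff(cpgs, colnames(x$values))
  if (length(missing)) {
    stop("CpGs absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = x$values[, cpgs, drop = FALSE], scale = x$scale),
            class = "methyl_matrix")
}

#' Read a methylation matrix from delimited text
#'
#' On disk, matrices follow the array-world convention of CpGs in rows and
#' samples in columns: the first column holds CpG ids and the header row
#' holds sample ids. In memory the matrix is transposed to the modelling
#' convention (samples x CpGs). Empty cells are read as missing. Under
#' `scale = "beta"`, values outside (0, 1) are clipped to
#' `[1e-6, 1 - 1e-6]` (below array resolution, keeps M-values finite) and
#' the number of clipped cells is reported in a warning.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected).
#' @param scale Declared scale of the stored values, `"beta"` or `"m"`.
#' @return A [methyl_matrix()].
#' @export
read_matrix <- function(path, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"))
  if (ncol(dt) < 2L) stop("matrix file needs a CpG id column plus >= 1 sample", call. = FALSE)
  cpgs <- as.character(dt[[1]])
  samples <- colnames(dt)[-1]
  check_unique_ids(cpgs, "CpG")
  check_unique_ids(samples, "sample")
  for (j in seq(2L, ncol(dt))) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric cell at CpG '%s', sample '%s': \"%s\"",
                     cpgs[bad[1]], samples[j - 1L], col[bad[1]]), call. = FALSE)
      }
      data.table::set(dt, j = j, value = num)
    }
  }
  m <- t(as.matrix(dt[, -1]))
  dimnames(m) <- list(samples, cpgs)
  if (scale == "beta") {
    low <- which(!is.na(m) & m <= 0)
    high <- which(!is.na(m) & m >= 1)
    if (length(low)) m[low] <- 1e-6
    if (length(high)) m[high] <- 1 - 1e-6
    n_clip <- length(low) + length(high)
    if (n_clip) warning(sprintf("clipped %d beta value(s) to [1e-06, 1 - 1e-06]", n_clip),
                        call. = FALSE)
  }
  methyl_matrix(m, scale)
}

#' Write a methylation matrix to delimited text
#'
#' Inverse of [read_matrix()]: stores CpGs in rows and samples in columns
#' at full double precision, so a write/read round-trip reproduces the
#' values.
#'
#' @param x A `methyl_matrix`.
#' @param path Output file path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "methyl_matrix"))
  dt <- data.table::as.data.table(t(x$values), keep.rownames = "cpg_id")
  data.table::fwrite(dt, path, sep = if (grepl("\\.tsv$", path)) "\t" else ",")
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' A sample sheet carries one row of metadata per sample: `sample_id`,
#' chronological `age` in years, `tissue` label and `dataset` id, plus the
#' optional columns `replicate_group` (links technical replicates),
#' `population_doublings` (cumulative doublings for cultured cells) and
#' `condition` (experimental group for acceleration contrasts).
#'
#' @param path CSV file with a header row using the column names above.
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, na.strings = c("", "NA")))
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate in place of reading from file.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "age", "tissue", "dataset")
  miss <- setdiff(req, colnames(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  check_unique_ids(sheet$sample_id, "sample")
  if (!is.numeric(sheet$age) || anyNA(sheet$age) || any(sheet$age < 0)) {
    stop("`age` must be non-negative years for every sample", call. = FALSE)
  }
  for (opt in c("replicate_group", "population_doublings", "condition")) {
    if (!opt %in% colnames(sheet)) sheet[[opt]] <- NA
  }
  if (any(!is.na(sheet$population_doublings) & sheet$population_doublings < 0)) {
    stop("`population_doublings` must be non-negative", call. = FALSE)
  }
  sheet
}

# Align a sheet to a matrix: every sample needs exactly one sheet row.
align_sheet <- function(x, sheet) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(sample_ids(x), sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from sheet: ",
         paste(utils::head(sample_ids(x)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  sheet[idx, , drop = FALSE]
}

#' Read a probe annotation table
#'
#' Columns: `cpg_id`, `chromosome` (e.g. `"1"`, `"X"`, `"chrY"`),
#' `snp_within_2bp` and `cross_hybridising` (logical or 0/1).
#'
#' @param path CSV file.
#' @return A validated `data.frame`.
#' @export
read_probe_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  req <- c("cpg_id", "chromosome", "snp_within_2bp", "cross_hybridising")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$cpg_id <- as.character(df$cpg_id)
  check_unique_ids(df$cpg_id, "CpG")
  df$snp_within_2bp <- as.logical(df$snp_within_2bp)
  df$cross_hybridising <- as.logical(df$cross_hybridising)
  df
}
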