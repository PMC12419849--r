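#' Define the ground truth of a synthetic multi-tissue methylation study
#'
#' Draws the planted structure of a simulated dataset and fixes it in an
#' explicit, inspectable object: which CpGs carry a linear age trend on
#' the M-value scale (shared across tissues or specific to one), their
#' slopes, which CpGs carry tissue-identity offsets, and the per-tissue
#' sample sizes and age ranges. The defaults are a desk-scale mirror of a
#' multi-tissue compendium: deliberately unbalanced tissues, strong
#' tissue-identity signal, and a minority of age-informative CpGs.
#'
#' @param n_cpgs Size of the CpG universe (default 2000).
#' @param tissues Tissue labels (default four musculoskeletal-style
#'   tissues).
#' @param tissue_sizes Samples per tissue (default `c(120, 80, 50, 30)`).
#' @param age_ranges List (or 2-column matrix) of per-tissue `[min, max]`
#'   ages in years; defaults are overlapping but unequal ranges.
#' @param n_age_shared Age CpGs with the same slope in every tissue
#'   (default 50).
#' @param n_age_specific Age CpGs *per tissue* whose slope acts in that
#'   tissue only (default 30).
#' @param n_identity CpGs with per-tissue baseline offsets but no age
#'   trend (default 200).
#' @param slope_range Absolute slope range in M-units/year (default
#'   `c(0.02, 0.06)`; signs random).
#' @param identity_sd SD of tissue-identity offsets in M-units
#'   (default 2).
#' @param noise_sd SD of additive M-value noise (default 0.3).
#' @param missing_rate Probability a cell is missing (default 0).
#' @param seed Integer seed fixing both the planted structure and, via
#'   [simulate_dataset()], the generated data.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_cpgs = 2000,
                             tissues = c("cartilage", "bone", "msc", "tendon"),
                             tissue_sizes = c(120, 80, 50, 30),
                             age_ranges = list(c(20, 90), c(30, 85), c(20, 70), c(40, 75)),
                             n_age_shared = 50,
                             n_age_specific = 30,
                             n_identity = 200,
                             slope_range = c(0.02, 0.06),
                             identity_sd = 2,
                             noise_sd = 0.3,
                             missing_rate = 0,
                             seed = 1) {
  stopifnot(length(tissues) >= 2, length(tissue_sizes) == length(tissues),
            length(age_ranges) == length(tissues),
            is_prob(missing_rate), noise_sd >= 0)
  n_planted <- n_age_shared + n_age_specific * length(tissues) + n_identity
  if (n_planted > n_cpgs) {
    stop("planted CpG sets exceed the CpG universe", call. = FALSE)
  }
  age_ranges <- lapply(age_ranges, function(r) {
    stopifnot(length(r) == 2, r[1] >= 0, r[2] > r[1]); as.numeric(r)
  })
  names(age_ranges) <- names(tissue_sizes) <- tissues

  set.seed(sub_seed(seed, 1L))
  cpgs <- sprintf("cg%06d", seq_len(n_cpgs))
  planted <- sample(cpgs, n_planted)
  take <- function(n) { # pop n ids off the planted pool (handles n = 0)
    out <- planted[seq_len(n)]
    planted <<- planted[seq_len(length(planted)) > n]
    out
  }
  shared <- take(n_age_shared)
  specific <- list()
  for (t in tissues) specific[[t]] <- take(n_age_specific)
  identity_cpgs <- planted

  age_cpgs <- c(shared, unlist(specific, use.names = FALSE))
  slopes <- stats::runif(length(age_cpgs), slope_range[1], slope_range[2]) *
    sample(c(-1, 1), length(age_cpgs), replace = TRUE)
  names(slopes) <- age_cpgs
  scope <- c(rep("shared", n_age_shared),
             rep(tissues, each = n_age_specific))
  names(scope) <- age_cpgs

  baseline <- stats::runif(n_cpgs, -4, 4)
  names(baseline) <- cpgs
  offsets <- matrix(stats::rnorm(length(identity_cpgs) * length(tissues), 0, identity_sd),
                    nrow = length(identity_cpgs), ncol = length(tissues),
                    dimnames = list(identity_cpgs, tissues))

  structure(list(
    cpg_ids = cpgs, tissues = tissues, tissue_sizes = tissue_sizes,
    age_ranges = age_ranges,
    age_cpg_ids = age_cpgs, slopes = slopes, scope = scope,
    identity_cpg_ids = identity_cpgs, identity_offsets = offsets,
    baseline = baseline, noise_sd = noise_sd, missing_rate = missing_rate,
    seed = seed
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(paste0("<simulation_truth> %d CpGs (%d age, %d identity), ",
                     "%d tissues, noise_sd %.2g, seed %d\n"),
              length(x$cpg_ids), length(x$age_cpg_ids), length(x$identity_cpg_ids),
              length(x$tissues), x$noise_sd, x$seed))
  invisible(x)
}

# Expected (noise-free) M-value matrix for given ages/tissues.
expected_m <- function(truth, ages, tissues) {
  n <- length(ages)
  m <- matrix(rep(truth$baseline, each = n), nrow = n,
              dimnames = list(NULL, truth$cpg_ids))
  for (t in unique(tissues)) {
    rows <- which(tissues == t)
    m[rows, truth$identity_cpg_ids] <-
      m[rows, truth$identity_cpg_ids] +
      rep(truth$identity_offsets[, t], each = length(rows))
    in_scope <- truth$age_cpg_ids[truth$scope == "shared" | truth$scope == t]
    m[rows, in_scope] <- m[rows, in_scope] +
      outer(ages[rows], truth$slopes[in_scope])
  }
  m
}

#' Simulate a multi-tissue methylation dataset with known ground truth
#'
#' Generates M-values under the additive model
#' `M_ij = mu_j + delta_j,tissue(i) + b_j * age_i * [j in scope] + eps_ij`
#' with `eps ~ N(0, noise_sd^2)`, ages drawn uniformly within each
#' tissue's range, and cells deleted independently at `missing_rate`.
#' The output is fully determined by `truth$seed`.
#'
#' @param truth A [simulation_truth()].
#' @param scale Output scale, `"m"` (default) or `"beta"` (inverse
#'   logit).
#' @param dataset_id Dataset label written to the sample sheet.
#' @return A list with `matrix` (a [methyl_matrix()]), `sheet` (sample
#'   sheet data frame) and `truth` (the input, unchanged).
#' @export
simulate_dataset <- function(truth, scale = c("m", "beta"), dataset_id = "sim01") {
  stopifnot(inherits(truth, "simulation_truth"))
  scale <- match.arg(scale)
  set.seed(sub_seed(truth$seed, 2L))
  tissues <- rep(truth$tissues, truth$tissue_sizes)
  n <- length(tissues)
  ages <- numeric(n)
  for (t in truth$tissues) {
    rows <- which(tissues == t)
    r <- truth$age_ranges[[t]]
    ages[rows] <- stats::runif(length(rows), r[1], r[2])
  }
  m <- expected_m(truth, ages, tissues)
  if (truth$noise_sd > 0) {
    m <- m + stats::rnorm(length(m), 0, truth$noise_sd)
  }
  if (truth$missing_rate > 0) {
    m[stats::runif(length(m)) < truth$missing_rate] <- NA_real_
  }
  ids <- sprintf("s%04d", seq_len(n))
  rownames(m) <- ids
  if (scale == "beta") m <- 2^m / (1 + 2^m)
  sheet <- data.frame(sample_id = ids, age = ages, tissue = tissues,
                      dataset = dataset_id, replicate_group = NA_character_,
                      population_doublings = NA_real_, condition = NA_character_,
                      stringsAsFactors = FALSE)
  list(matrix = methyl_matrix(m, scale), sheet = sheet, truth = truth)
}

#' Add technical replicates to a simulated dataset
#'
#' Emulates re-running each sample on a second array: every sample is
#' duplicated and both copies receive independent `N(0, tech_sd^2)`
#' M-value noise, so the within-pair difference at any CpG is
#' `N(0, 2 * tech_sd^2)`. Pairs are linked through `replicate_group`
#' (the original sample id) and distinguished by the `dataset` suffixes
#' `_repA` / `_repB`.
#'
#' @param x A [methyl_matrix()] on the M scale.
#' @param sheet Its sample sheet.
#' @param tech_sd Technical noise SD in M-units (>= 0).
#' @param seed Integer seed.
#' @return A list with `matrix` and `sheet` covering `2 * n` samples.
#' @export
simulate_replicates <- function(x, sheet, tech_sd, seed = 1) {
  stopifnot(inherits(x, "methyl_matrix"), tech_sd >= 0)
  if (x$scale != "m") stop("replicate noise is added on the M scale", call. = FALSE)
  sheet <- align_sheet(x, sheet)
  set.seed(sub_seed(seed, 3L))
  n <- nrow(x$values)
  a <- x$values + stats::rnorm(length(x$values), 0, tech_sd)
  b <- x$values + stats::rnorm(length(x$values), 0, tech_sd)
  rownames(a) <- paste0(sample_ids(x), "_A")
  rownames(b) <- paste0(sample_ids(x), "_B")
  sheet_a <- sheet_b <- sheet
  sheet_a$sample_id <- rownames(a)
  sheet_b$sample_id <- rownames(b)
  sheet_a$dataset <- paste0(sheet$dataset, "_repA")
  sheet_b$dataset <- paste0(sheet$dataset, "_repB")
  sheet_a$replicate_group <- sheet_b$replicate_group <- sheet$sample_id
  out <- rbind(a, b)
  list(matrix = methyl_matrix(out, "m"),
       sheet = rbind(sheet_a, sheet_b))
}

#' Simulate a serial-passage (population-doubling) series
#'
#' Emulates longitudinal in-vitro ageing: each donor is sampled at every
#' point of a doubling grid, and methylation is generated from the
#' donor's *effective* age, `chronological + years_per_doubling *
#' doublings`, under the same planted model as [simulate_dataset()]. The
#' sample sheet records chronological age and `population_doublings`, so
#' a clock trained on the truth's CpGs should read the effective age and
#' its regression on doublings should recover `years_per_doubling`.
#'
#' @param n_donors Number of donors (default 6).
#' @param doublings_grid Non-negative increasing doubling counts at which
#'   each donor is assayed (default 8 points spanning 0-77).
#' @param years_per_doubling Planted in-vitro ageing rate (years per
#'   doubling).
#' @param truth A [simulation_truth()] defining the CpG universe; the
#'   first tissue's identity profile is used (a culture is one cell
#'   type).
#' @param donor_age_range Chronological ages are drawn uniformly from
#'   this range (default 20-40 years, a narrow adult band typical of
#'   fibroblast lifespan studies).
#' @param seed Integer seed.
#' @return A list with `matrix` (M scale) and `sheet`.
#' @export
simulate_passage_series <- function(n_donors = 6,
                                    doublings_grid = seq(0, 77, by = 11),
                                    years_per_doubling = 0.45,
                                    truth = simulation_truth(),
                                    donor_age_range = c(20, 40),
                                    seed = 1) {
  stopifnot(is_count(n_donors), all(doublings_grid >= 0),
            !is.unsorted(doublings_grid, strictly = TRUE))
  set.seed(sub_seed(seed, 4L))
  tissue <- truth$tissues[1]
  donor_age <- stats::runif(n_donors, donor_age_range[1], donor_age_range[2])
  grid <- expand.grid(donor = seq_len(n_donors), pd = doublings_grid)
  eff_age <- donor_age[grid$donor] + years_per_doubling * grid$pd
  m <- expected_m(truth, eff_age, rep(tissue, nrow(grid)))
  if (truth$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, truth$noise_sd)
  ids <- sprintf("d%02d_pd%05.1f", grid$donor, grid$pd)
  rownames(m) <- ids
  sheet <- data.frame(sample_id = ids, age = donor_age[grid$donor],
                      tissue = tissue, dataset = "passage",
                      replicate_group = NA_character_,
                      population_doublings = grid$pd,
                      condition = sprintf("donor%02d", grid$donor),
                      stringsAsFactors = FALSE)
  list(matrix = methyl_matrix(m, "m"), sheet = sheet)
}
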