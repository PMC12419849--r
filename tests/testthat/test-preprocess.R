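make_filter_fixture <- function() {
  # 10 CpGs: 2 SNP-flagged, 1 on chrY, 1 failing detection in one sample
  cpgs <- sprintf("cg%02d", 1:10)
  set.seed(4)
  m <- matrix(runif(40, 0.2, 0.8), 4, 10,
              dimnames = list(paste0("s", 1:4), cpgs))
  ann <- data.frame(
    cpg_id = cpgs,
    chromosome = c("1", "2", "Y", "3", "4", "5", "6", "7", "8", "9"),
    snp_within_2bp = c(TRUE, TRUE, rep(FALSE, 8)),
    cross_hybridising = FALSE)
  dp <- matrix(0, 4, 10, dimnames = dimnames(m))
  dp["s2", "cg05"] <- 0.2
  list(x = methyl_matrix(m, "beta"), ann = ann, dp = dp)
}

test_that("probe filtering applies each removal rule and reports counts", {
  f <- make_filter_fixture()
  out <- filter_probes(f$x, f$ann, detection_p = f$dp)
  expect_equal(ncol(out$matrix$values), 6) # 10 - 2 SNP - 1 chrY - 1 detection
  expect_false(any(c("cg01", "cg02", "cg03", "cg05") %in% cpg_ids(out$matrix)))
  rep <- setNames(out$report$n_removed, out$report$rule)
  expect_equal(rep[["snp_within_2bp"]], 2)
  expect_equal(rep[["sex_chromosome"]], 1)
  expect_equal(rep[["detection_p"]], 1)
  expect_equal(rep[["cross_hybridising"]], 0)

  # idempotent: filtering the survivors removes nothing
  again <- filter_probes(out$matrix, f$ann, detection_p = f$dp)
  expect_identical(again$matrix$values, out$matrix$values)
  expect_equal(sum(again$report$n_removed), 0)
})

test_that("clean matrices pass through probe filtering unchanged", {
  f <- make_filter_fixture()
  ann <- f$ann
  ann$snp_within_2bp <- FALSE
  ann$chromosome <- "1"
  out <- filter_probes(f$x, ann, detection_p = matrix(0, 4, 10, dimnames = dimnames(f$x$values)))
  expect_identical(out$matrix$values, f$x$values)
  # chrX alias handling
  ann$chromosome[4] <- "chrX"
  expect_false("cg04" %in% cpg_ids(filter_probes(f$x, ann)$matrix))
  # unannotated CpGs kept with a warning by default
  expect_warning(filter_probes(f$x, ann[-1, ]), "lack annotation")
  expect_error(filter_probes(f$x, ann[-1, ], missing_annotation = "error"),
               "no annotation")
})

test_that("beta/M conversion matches the logit2 definition and inverts", {
  m <- matrix(c(0.5, 0.8, 0.2, NA), 2, 2,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2")))
  x <- methyl_matrix(m, "beta")
  mm <- beta_to_m(x)
  expect_equal(mm$values["s1", "cg1"], 0)           # logit2(0.5)
  expect_equal(mm$values["s2", "cg1"], 2)           # log2(0.8/0.2)
  expect_true(is.na(mm$values["s2", "cg2"]))
  expect_error(beta_to_m(mm), "not on the beta scale")

  grid <- matrix(seq(1e-6, 1 - 1e-6, length.out = 101), 1, 101,
                 dimnames = list("s", sprintf("cg%03d", 1:101)))
  g <- methyl_matrix(grid, "beta")
  expect_equal(m_to_beta(beta_to_m(g))$values, grid, tolerance = 1e-12)
})

test_that("knn imputation recovers duplicates exactly and leaves complete data alone", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
  masked <- m; masked[1, 2] <- NA
  out <- knn_impute(methyl_matrix(masked, "m"), k = 1)
  expect_equal(out$values[1, 2], 2) # the identical twin's value
  expect_equal(out$values[-3], masked[-3])

  complete <- methyl_matrix(m, "m")
  expect_identical(knn_impute(complete)$values, m)

  all_na <- masked; all_na[1, ] <- NA
  expect_error(knn_impute(methyl_matrix(all_na, "m")), "all values missing")
})

test_that("knn imputation error stays near the noise floor on masked data", {
  sim <- tiny_world(seed = 31, noise_sd = 0.1)
  v <- sim$matrix$values
  set.seed(8)
  holes <- cbind(sample(nrow(v), 150, replace = TRUE),
                 sample(ncol(v), 150, replace = TRUE))
  holes <- holes[!duplicated(holes), ]
  masked <- v
  masked[holes] <- NA
  out <- knn_impute(methyl_matrix(masked, "m"), k = 10)
  rmse <- sqrt(mean((out$values[holes] - v[holes])^2))
  expect_lt(rmse, 2 * 0.1) # recover within twice the noise SD
})

test_that("age transform hits its anchors and inverts to machine precision", {
  expect_equal(transform_age(20), 0)
  expect_equal(transform_age(41), 1)
  expect_equal(transform_age(0), -log(21))
  ages <- seq(0, 120, by = 0.25)
  expect_equal(inverse_transform_age(transform_age(ages)), ages, tolerance = 1e-12)
  expect_error(transform_age(-1), "non-negative")
})

test_that("age transform is strictly increasing and continuous at the junction", {
  ages <- seq(0, 120, by = 0.05)
  f <- transform_age(ages)
  expect_true(all(diff(f) > 0))
  eps <- 1e-9
  expect_lt(abs(transform_age(20 + eps) - transform_age(20 - eps)), 1e-8)
})

test_that("stratified split honours per-stratum fractions and the seed", {
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:30), age = 50,
                      tissue = rep(c("a", "b", "c"), each = 10), dataset = "d")
  sp <- stratified_split(sheet, fraction = 0.7, seed = 5)
  for (t in c("a", "b", "c")) {
    ids <- sheet$sample_id[sheet$tissue == t]
    expect_equal(sum(ids %in% sp$train_ids), 7)
    expect_equal(sum(ids %in% sp$test_ids), 3)
  }
  expect_identical(sp, stratified_split(sheet, fraction = 0.7, seed = 5))
  expect_false(identical(sp$train_ids,
                         stratified_split(sheet, fraction = 0.7, seed = 6)$train_ids))

  singleton <- rbind(sheet, data.frame(sample_id = "x", age = 1, tissue = "z",
                                       dataset = "d"))
  expect_error(stratified_split(singleton), "singleton stratum.*z")
})

test_that("across many seeds every sample trains at about the nominal fraction", {
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:10), age = 50,
                      tissue = "a", dataset = "d")
  counts <- setNames(numeric(10), sheet$sample_id)
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    sp <- stratified_split(sheet, fraction = 0.7, seed = s)
    counts[sp$train_ids] <- counts[sp$train_ids] + 1
  }
  freq <- counts / n_rep
  expect_true(all(freq >= 0.6 & freq <= 0.8))
})

test_that("correlation pre-filter keeps any-tissue correlates and drops constants", {
  set.seed(12)
  n <- 40
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:n), age = runif(n, 20, 80),
                      tissue = rep(c("a", "b"), each = n / 2), dataset = "d")
  m <- matrix(rnorm(n * 3, 0, 1), n, 3,
              dimnames = list(sheet$sample_id, c("cg_hit", "cg_const", "cg_noise")))
  rows_a <- sheet$tissue == "a"
  m[rows_a, "cg_hit"] <- sheet$age[rows_a] * 0.05          # perfect in tissue a
  m[, "cg_const"] <- 1.7
  x <- methyl_matrix(m, "m")
  res <- correlation_prefilter(x, sheet, threshold = 0.3)
  expect_true("cg_hit" %in% res$cpg_ids)
  expect_false("cg_const" %in% res$cpg_ids)
  expect_equal(res$r_table["cg_const", ], c(a = 0, b = 0))
  expect_equal(abs(res$r_table["cg_hit", "a"]), 1, tolerance = 1e-9)
})

test_that("on noiseless data the pre-filter recovers exactly the planted set", {
  sim <- tiny_world(seed = 17, noise_sd = 0)
  res <- correlation_prefilter(sim$matrix, sim$sheet, threshold = 0.3)
  expect_setequal(res$cpg_ids, sim$truth$age_cpg_ids)
})

test_that("pre-filter retention shrinks as the threshold rises", {
  sim <- tiny_world(seed = 19)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.8), function(th) {
    length(correlation_prefilter(sim$matrix, sim$sheet, threshold = th)$cpg_ids)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  # alternative rules stay within the max-rule pool
  pooled <- correlation_prefilter(sim$matrix, sim$sheet, rule = "pooled")
  expect_identical(colnames(pooled$r_table), "pooled")
})
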