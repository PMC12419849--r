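eval_fixture <- function() {
  sheet <- data.frame(
    sample_id = sprintf("s%d", 1:6), age = c(30, 40, 50, 60, 70, 80),
    tissue = rep(c("bone", "cartilage"), each = 3), dataset = "d")
  pred <- data.frame(sample_id = sheet$sample_id,
                     predicted_age = sheet$age + c(1, -2, 3, -1, 2, -4))
  list(sheet = sheet, pred = pred)
}

test_that("evaluation reports medians, R-squared and percentage errors", {
  f <- eval_fixture()
  perfect <- data.frame(sample_id = f$sheet$sample_id,
                        predicted_age = f$sheet$age)
  rep0 <- suppressWarnings(evaluation_report(perfect, f$sheet))
  expect_equal(rep0$overall_median_abs_error, 0)
  expect_equal(unname(rep0$per_tissue_median_abs_error), c(0, 0))
  expect_equal(rep0$r_squared, 1)

  shifted <- data.frame(sample_id = f$sheet$sample_id,
                        predicted_age = f$sheet$age + 2)
  rep2 <- suppressWarnings(evaluation_report(shifted, f$sheet))
  expect_equal(rep2$overall_median_abs_error, 2)
  expect_equal(rep2$r_squared, 1)
  expect_equal(unname(rep2$error_as_pct_of_age["s1"]), 100 * 2 / 30)

  rep3 <- evaluation_report(f$pred, f$sheet)
  expect_equal(unname(rep3$per_tissue_median_abs_error["bone"]), 2)
  expect_equal(unname(rep3$per_tissue_median_abs_error["cartilage"]), 2)
  expect_equal(rep3$overall_median_abs_error, 2)
  expect_equal(unname(rep3$accelerations), c(1, -2, 3, -1, 2, -4))
})

test_that("replicate concordance pairs by group and orders differences", {
  sheet <- data.frame(
    sample_id = c("a_A", "a_B", "b_A", "b_B"), age = 50,
    tissue = "bone", dataset = c("d_A", "d_B", "d_A", "d_B"),
    replicate_group = c("a", "a", "b", "b"))
  pred <- data.frame(sample_id = sheet$sample_id,
                     predicted_age = c(50, 53, 60, 59))
  out <- replicate_concordance(pred, sheet)
  expect_equal(nrow(out$pairs), 2)
  expect_equal(out$pairs$difference, c(3, -1)) # B minus A
  expect_equal(out$median_difference, 1)

  identical_pred <- data.frame(sample_id = sheet$sample_id, predicted_age = 42)
  expect_equal(replicate_concordance(identical_pred, sheet)$median_difference, 0)

  unpaired <- sheet[1:3, ]
  expect_error(replicate_concordance(pred[1:3, ], unpaired), "exactly 2")
})

test_that("replicate spread tracks the injected technical noise", {
  sim <- tiny_world(seed = 47)
  model <- train_clock(sim$matrix, sim$sheet, sim$truth$age_cpg_ids, seed = 1)
  spread <- vapply(c(0.05, 0.5), function(ts) {
    reps <- simulate_replicates(sim$matrix, sim$sheet, tech_sd = ts, seed = 5)
    pred <- predict_age(model, reps$matrix)
    replicate_concordance(pred, reps$sheet)$median_abs_difference
  }, 0)
  expect_lt(spread[1], spread[2])
})

test_that("doubling regression reproduces a planted line exactly", {
  pd <- seq(0, 70, by = 10)
  sheet <- data.frame(sample_id = sprintf("p%d", seq_along(pd)), age = 30,
                      tissue = "fibroblast", dataset = "d",
                      population_doublings = pd)
  pred <- data.frame(sample_id = sheet$sample_id,
                     predicted_age = 11.64 + 0.45 * pd)
  fit <- suppressWarnings(doubling_regression(pred, sheet))
  expect_equal(fit$slope, 0.45, tolerance = 1e-12)
  expect_equal(fit$intercept, 11.64, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # slope is shift-invariant; intercept absorbs the shift
  shift <- pred; shift$predicted_age <- shift$predicted_age + 7
  fit2 <- suppressWarnings(doubling_regression(shift, sheet))
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept + 7, tolerance = 1e-12)

  # two-point closed form
  two <- sheet[1:2, ]
  two_pred <- pred[1:2, ]
  fit3 <- suppressWarnings(doubling_regression(two_pred, two))
  expect_equal(fit3$slope,
               diff(two_pred$predicted_age) / diff(two$population_doublings))

  const <- sheet; const$population_doublings <- 5
  expect_error(doubling_regression(pred, const), "constant")

  multi <- suppressWarnings(doubling_regression(list(a = pred, b = shift), sheet))
  expect_equal(nrow(multi), 2)
  expect_equal(multi$fdr, p.adjust(multi$p_value, "BH"))
})

test_that("group acceleration contrasts test means with family FDR", {
  set.seed(23)
  n <- 25
  sheet <- data.frame(
    sample_id = sprintf("s%02d", 1:(2 * n)), age = 50, tissue = "cartilage",
    dataset = "d", condition = rep(c("control", "lesioned"), each = n))
  pred <- data.frame(sample_id = sheet$sample_id,
                     predicted_age = 50 + c(rnorm(n, 0, 1), rnorm(n, 4, 1)))
  out <- group_acceleration_test(pred, sheet)
  expect_equal(out$mean_diff, -4, tolerance = 0.8)
  expect_lt(out$fdr, 0.01)

  same <- pred
  same$predicted_age <- rep(52, 2 * n)
  out0 <- group_acceleration_test(same, sheet)
  expect_equal(out0$mean_diff, 0)
  expect_equal(out0$p, 1)

  sheet$condition[1] <- "odd"
  # two contrasts touch the singleton group, hence two warnings
  expect_warning(
    expect_warning(out2 <- group_acceleration_test(pred, sheet), "singleton"),
    "singleton")
  expect_equal(nrow(out2), 1)
})

test_that("passage-series pipeline recovers the planted doubling rate", {
  truth <- tiny_truth(seed = 49, noise_sd = 0.3)
  train <- simulate_dataset(truth)
  model <- train_clock(train$matrix, train$sheet, truth$age_cpg_ids, seed = 2)
  ps <- simulate_passage_series(n_donors = 6, years_per_doubling = 0.45,
                                truth = truth, seed = 3)
  pred <- predict_age(model, ps$matrix, sheet = ps$sheet)
  fit <- doubling_regression(pred, ps$sheet)
  expect_lt(abs(fit$slope - 0.45), 3 * fit$slope_se)
  expect_gt(fit$r_squared, 0.5)
})
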