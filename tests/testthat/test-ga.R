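# Small world shared by the GA tests: 2 tissues, modest CpG universe.
ga_world <- function(seed = 42, noise_sd = 0.3) {
  sim <- tiny_world(seed = seed, noise_sd = noise_sd)
  cfg <- ga_config(population_size = 16, n_islands = 2, n_generations = 6,
                   cv_folds = 5, seed = seed)
  list(sim = sim, cfg = cfg)
}

test_that("ridge fitness matches a direct penalised-least-squares oracle", {
  # tiny problem: compare the closed-form ridge path against optim()
  set.seed(2)
  n <- 30; p <- 3
  X <- matrix(rnorm(n * p), n, dimnames = list(paste0("s", 1:n), paste0("cg", 1:p)))
  y <- 50 + X %*% c(3, -2, 1) + rnorm(n, 0, 0.5)
  lambda <- 7.3
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Xs <- scale(X, mu, sdv)
  obj <- function(b) sum((y - mean(y) - Xs %*% b)^2) + lambda * sum(b^2)
  oracle <- optim(rep(0, p), obj, method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 1000))$par
  G <- crossprod(Xs)
  e <- eigen(G, symmetric = TRUE)
  a <- crossprod(e$vectors, crossprod(Xs, y - mean(y)))[, 1]
  ours <- e$vectors %*% (a / (e$values + lambda))
  expect_equal(as.numeric(ours), oracle, tolerance = 1e-6)
})

test_that("ridge fitness decomposes exactly into mean tissue MAE plus penalty", {
  w <- ga_world()
  sheet <- w$sim$sheet
  chrom <- rep(FALSE, 300)
  chrom[match(w$sim$truth$age_cpg_ids, cpg_ids(w$sim$matrix))] <- TRUE
  fit <- ridge_fitness(chrom, w$sim$matrix, sheet, w$cfg)
  expect_identical(fit$fitness, fit$mean_mae + fit$penalty)
  expect_identical(fit$penalty, w$cfg$cpg_penalty * fit$n_selected)
  expect_identical(fit$mean_mae, mean(fit$per_tissue_mae))
  expect_equal(fit$n_selected, sum(chrom))
  expect_true(all(fit$per_tissue_mae >= 0))
})

test_that("the planted chromosome on noiseless data scores near the pure penalty", {
  w <- ga_world(noise_sd = 0)
  chrom <- cpg_ids(w$sim$matrix) %in% w$sim$truth$age_cpg_ids
  fit <- ridge_fitness(chrom, w$sim$matrix, w$sim$sheet, w$cfg)
  expect_lt(max(fit$per_tissue_mae), 0.1)
  expect_equal(fit$fitness, w$cfg$cpg_penalty * sum(chrom), tolerance = 0.1)
})

test_that("an all-zero chromosome scores as the intercept-only model", {
  w <- ga_world()
  fit <- ridge_fitness(rep(FALSE, 300), w$sim$matrix, w$sim$sheet, w$cfg)
  expect_equal(fit$n_selected, 0L)
  expect_equal(fit$penalty, 0)
  # intercept-only cross-validated MAE is near the tissue-mean absolute deviation
  expect_gt(fit$mean_mae, 5)
})

test_that("appending a pure-noise CpG raises the penalised fitness almost always", {
  w <- ga_world(noise_sd = 0.2)
  ids <- cpg_ids(w$sim$matrix)
  base <- ids %in% w$sim$truth$age_cpg_ids
  noise_pool <- which(!(ids %in% c(w$sim$truth$age_cpg_ids,
                                   w$sim$truth$identity_cpg_ids)))
  fit0 <- ridge_fitness(base, w$sim$matrix, w$sim$sheet, w$cfg)
  set.seed(77)
  worse <- 0L
  n_trials <- 50
  for (i in seq_len(n_trials)) {
    chrom <- base
    chrom[sample(noise_pool, 1)] <- TRUE
    fit1 <- ridge_fitness(chrom, w$sim$matrix, w$sim$sheet, w$cfg)
    if (fit1$fitness - fit0$fitness >= 0.005) worse <- worse + 1L
  }
  expect_gte(worse / n_trials, 0.95)
})

test_that("equal tissue weighting: duplicating a tissue barely moves the fitness", {
  w <- ga_world(noise_sd = 0)
  sim <- w$sim
  chrom <- cpg_ids(sim$matrix) %in% sim$truth$age_cpg_ids
  fit0 <- ridge_fitness(chrom, sim$matrix, sim$sheet, w$cfg)
  dup_rows <- sim$sheet$tissue == "bone"
  v2 <- rbind(sim$matrix$values, sim$matrix$values[dup_rows, ])
  sheet2 <- rbind(sim$sheet, transform(sim$sheet[dup_rows, ],
                                       sample_id = paste0(sample_id, "_dup")))
  rownames(v2) <- sheet2$sample_id
  fit1 <- ridge_fitness(chrom, methyl_matrix(v2, "m"), sheet2, w$cfg)
  expect_lt(abs(fit1$mean_mae - fit0$mean_mae), 0.1)
})

test_that("population initialisation matches its density and never yields empty chromosomes", {
  cfg <- ga_config(population_size = 200, init_density = 0.1, seed = 3)
  pop <- init_population(cfg, 500)
  expect_length(pop, 200)
  expect_true(all(vapply(pop, any, TRUE)))
  mean_bits <- mean(vapply(pop, sum, 0))
  sigma <- sqrt(500 * 0.1 * 0.9)
  expect_lt(abs(mean_bits - 50), 3 * sigma / sqrt(200)) # binomial 3-sigma band
  expect_identical(pop, init_population(cfg, 500))

  ones <- init_population(ga_config(population_size = 4, n_islands = 2, init_density = 1), 20)
  expect_true(all(vapply(ones, all, TRUE)))
})

test_that("single-point crossover recombines prefixes and suffixes", {
  p1 <- as.logical(c(0, 0, 0, 0, 1, 1))
  p2 <- as.logical(c(1, 1, 0, 0, 0, 0))
  kids <- gaclock:::single_point_crossover(p1, p2, 2)
  expect_identical(kids[[1]], as.logical(c(0, 0, 0, 0, 0, 0))) # repaired downstream
  expect_identical(kids[[2]], as.logical(c(1, 1, 0, 0, 1, 1)))
  # the all-zero child is repaired at mutation time
  set.seed(1)
  repaired <- gaclock:::mutate_child(kids[[1]], ga_config(mutation_rate = 0))
  expect_equal(sum(repaired), 1)
})

test_that("evolution without crossover or mutation preserves the elite", {
  w <- ga_world()
  cfg <- ga_config(population_size = 16, n_islands = 2, n_generations = 1,
                   crossover_rate = 0, mutation_rate = 0, cv_folds = 5,
                   seed = 4)
  pop <- init_population(cfg, 40, seed = 9)[1:8]
  fit <- function(bits) {
    # deterministic toy fitness: squared distance from 3 set bits
    structure(list(per_tissue_mae = c(a = (sum(bits) - 3)^2),
                   mean_mae = (sum(bits) - 3)^2, n_selected = sum(bits),
                   penalty = 0, fitness = (sum(bits) - 3)^2, lambda = 1),
              class = "fitness_result")
  }
  island <- list(population = pop, fitness = lapply(pop, fit), generation = 0L)
  nxt <- evolve_generation(island, fit, cfg)
  expect_length(nxt$population, 8)
  ord0 <- gaclock:::island_order(island)
  ord1 <- gaclock:::island_order(nxt)
  expect_identical(nxt$population[[ord1[1]]], island$population[[ord0[1]]])
  # every offspring is a copy of an elite parent under no-op operators
  elite <- island$population[ord0[1:2]]
  expect_true(all(vapply(nxt$population, function(ch) {
    any(vapply(elite, identical, TRUE, x = ch))
  }, TRUE)))
})

test_that("elitism makes the best fitness non-increasing across generations", {
  for (s in c(1, 2, 3)) {
    w <- ga_world(seed = s)
    res <- run_ga(w$sim$matrix, w$sim$sheet, config = w$cfg)
    best_trace <- tapply(res$history$best_fitness, res$history$generation, min)
    expect_true(all(diff(best_trace) <= 1e-12))
  }
})

test_that("migration preserves island sizes and never worsens the global best", {
  w <- ga_world(seed = 6)
  cfg <- w$cfg
  ctx_fit <- function(bits) ridge_fitness(bits, w$sim$matrix, w$sim$sheet, cfg)
  set.seed(10)
  pop <- init_population(cfg, 300, seed = NULL)
  islands <- list(
    list(population = pop[1:8], fitness = lapply(pop[1:8], ctx_fit), generation = 0L),
    list(population = pop[9:16], fitness = lapply(pop[9:16], ctx_fit), generation = 0L))
  gbest <- function(isls) min(vapply(isls, function(i) {
    min(vapply(i$fitness, `[[`, 0, "fitness"))
  }, 0))
  before <- gbest(islands)
  after <- migrate(islands, cfg)
  expect_equal(vapply(after, function(i) length(i$population), 0L), c(8L, 8L))
  expect_lte(gbest(after), before)

  # identical islands are unchanged as multisets
  same <- list(islands[[1]], islands[[1]])
  moved <- migrate(same, cfg)
  key <- function(pop) sort(vapply(pop, function(b) paste(which(b), collapse = ","), ""))
  expect_identical(key(moved[[1]]$population), key(same[[1]]$population))
})

test_that("the GA run is reproducible and keeps honest books", {
  w <- ga_world(seed = 8)
  res1 <- run_ga(w$sim$matrix, w$sim$sheet, config = w$cfg)
  res2 <- run_ga(w$sim$matrix, w$sim$sheet, config = w$cfg)
  expect_identical(res1$best_chromosome, res2$best_chromosome)
  expect_identical(res1$history, res2$history)

  h <- res1$history
  expect_equal(nrow(h), w$cfg$n_generations * w$cfg$n_islands)
  expect_equal(sort(unique(h$generation)), seq_len(w$cfg$n_generations))
  expect_identical(res1$selected_cpgs,
                   res1$candidate_cpgs[res1$best_chromosome])
  # the returned best is at least as good as anything in the final history
  expect_lte(res1$best_fitness$fitness, min(h$best_fitness))
})

test_that("the refitted ridge age model predicts held-out samples sensibly", {
  sim <- tiny_world(seed = 51, noise_sd = 0.2)
  w <- split_world(sim, seed = 2)
  m <- fit_ridge_age_model(w$train, w$sheet_train, sim$truth$age_cpg_ids,
                           ga_config(cv_folds = 5, seed = 3))
  pred <- predict(m, w$test)
  mae <- mean(abs(pred - w$sheet_test$age))
  expect_lt(mae, 2)
})
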