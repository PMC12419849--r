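#' Configuration of the genetic algorithm islands model
#'
#' Collects every tunable of the CpG-selection GA with validated
#' defaults. The evolutionary parameters default to the standard islands
#' setup for this problem: a population of 200 chromosomes split equally
#' over 4 islands, 5% elitism, 70% single-point crossover, 10% per-child
#' mutation, migration of each island's best chromosome every 10
#' generations, and 400 generations. The fitness charges `cpg_penalty`
#' (0.01 years) per included CpG on top of the unweighted mean of
#' per-tissue 10-fold cross-validated MAEs from a ridge regression of
#' age on the selected CpGs.
#'
#' @param population_size Total chromosomes across all islands (must be
#'   divisible by `n_islands`).
#' @param n_islands Number of independently evolving islands.
#' @param elite_fraction Fraction of each island retained unchanged;
#'   the elite count is `max(2, ceiling(elite_fraction * island_size))`
#'   so that parent pairs always exist.
#' @param crossover_rate Probability a sampled parent pair recombines by
#'   single-point crossover (otherwise the parents are copied).
#' @param mutation_rate Per-child probability of mutation under
#'   `mutation_kind = "per_child"` (one uniformly chosen bit flips); under
#'   `"per_bit"` each bit flips independently with probability
#'   `mutation_rate / n_features`.
#' @param migration_interval Generations between migration events.
#' @param n_generations Number of generations to evolve.
#' @param cpg_penalty Fitness penalty in years per included CpG.
#' @param cv_folds Cross-validation folds for the ridge fitness (reduced
#'   with a warning when a tissue has fewer samples).
#' @param init_density Probability a bit starts set at initialisation.
#' @param lambda_grid Ridge penalty grid; default 50 log-spaced values in
#'   `[1e-3, 1e3]` applied to standardized features.
#' @param parent_selection `"elite"` (parents drawn uniformly from the
#'   elite) or `"tournament"` (size-2 tournaments over the island).
#' @param mutation_kind `"per_child"` or `"per_bit"`; see
#'   `mutation_rate`.
#' @param objective `"mae"` (default) or `"mse"` per-tissue error.
#' @param max_gram_features Candidate-universe size up to which per-fold
#'   Gram matrices are precomputed (memory/speed trade-off).
#' @param seed Integer seed; a run is fully reproducible from
#'   (data, config, seed).
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 200,
                      n_islands = 4,
                      elite_fraction = 0.05,
                      crossover_rate = 0.70,
                      mutation_rate = 0.10,
                      migration_interval = 10,
                      n_generations = 400,
                      cpg_penalty = 0.01,
                      cv_folds = 10,
                      init_density = 0.10,
                      lambda_grid = exp(seq(log(1e-3), log(1e3), length.out = 50)),
                      parent_selection = c("elite", "tournament"),
                      mutation_kind = c("per_child", "per_bit"),
                      objective = c("mae", "mse"),
                      max_gram_features = 1500,
                      seed = 1) {
  parent_selection <- match.arg(parent_selection)
  mutation_kind <- match.arg(mutation_kind)
  objective <- match.arg(objective)
  stopifnot(is_count(population_size), is_count(n_islands),
            is_count(migration_interval), is_count(n_generations),
            is_count(cv_folds), cv_folds >= 2,
            is_prob(elite_fraction), is_prob(crossover_rate),
            is_prob(mutation_rate), is_prob(init_density),
            cpg_penalty >= 0, all(lambda_grid > 0), !is.unsorted(lambda_grid))
  if (population_size %% n_islands != 0) {
    stop("`population_size` must be divisible by `n_islands`", call. = FALSE)
  }
  if (population_size / n_islands < 2) {
    stop("islands need at least 2 chromosomes each", call. = FALSE)
  }
  structure(list(
    population_size = population_size, n_islands = n_islands,
    elite_fraction = elite_fraction, crossover_rate = crossover_rate,
    mutation_rate = mutation_rate, migration_interval = migration_interval,
    n_generations = n_generations, cpg_penalty = cpg_penalty,
    cv_folds = cv_folds, init_density = init_density,
    lambda_grid = as.numeric(lambda_grid),
    parent_selection = parent_selection, mutation_kind = mutation_kind,
    objective = objective, max_gram_features = max_gram_features,
    seed = as.integer(seed)
  ), class = "ga_config")
}

# ---- fitness machinery -----------------------------------------------------

# Precompute everything the ridge fitness needs so that evaluating one
# chromosome is a small dense subproblem: seeded tissue-stratified CV
# folds, per-fold column standardization of the candidate matrix, the
# standardized Gram matrix and X'y vector per fold (when the universe is
# small enough), and the standardized held-out rows.
new_fitness_context <- function(M, sheet, config) {
  stopifnot(is.matrix(M), !anyNA(M))
  y <- sheet$age
  tissue <- as.character(sheet$tissue)
  n <- nrow(M)
  k <- config$cv_folds
  min_tissue <- min(table(tissue))
  if (min_tissue < k) {
    k <- max(2L, as.integer(min_tissue))
    warning(sprintf("cv_folds reduced to %d (smallest tissue has %d samples)",
                    k, min_tissue), call. = FALSE)
  }
  set.seed(sub_seed(config$seed, 11L))
  folds <- integer(n)
  for (t in unique(tissue)) { # stratified fold assignment
    rows <- which(tissue == t)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  use_gram <- ncol(M) <= config$max_gram_features
  fold_data <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    mu <- colMeans(M[tr, , drop = FALSE])
    sdv <- apply(M[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv < 1e-12] <- Inf # constant column: standardizes to all-zero
    Xtr <- sweep(sweep(M[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(M[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    ybar <- mean(y[tr])
    fold_data[[f]] <- list(
      te = te, ybar = ybar, Xte = Xte,
      G = if (use_gram) crossprod(Xtr) else NULL,
      Xtr = if (use_gram) NULL else Xtr,
      c = crossprod(Xtr, y[tr] - ybar)[, 1]
    )
  }
  list(y = y, tissue = tissue, n = n, k = k, folds = folds,
       fold_data = fold_data, use_gram = use_gram,
       lambda = config$lambda_grid, objective = config$objective,
       penalty = config$cpg_penalty)
}

# Out-of-fold ridge predictions for one bit vector across the whole
# lambda grid, via eigen-decomposition of the standardized Gram.
oof_predictions <- function(ctx, sel) {
  p <- length(sel)
  lam <- ctx$lambda
  oof <- matrix(NA_real_, ctx$n, length(lam))
  for (fd in ctx$fold_data) {
    if (p == 0L) {
      oof[fd$te, ] <- fd$ybar
      next
    }
    G <- if (ctx$use_gram) fd$G[sel, sel] else crossprod(fd$Xtr[, sel, drop = FALSE])
    cs <- fd$c[sel]
    if (p == 1L) {
      beta <- cs / (as.numeric(G) + lam)              # 1 x nlambda
      P <- outer(fd$Xte[, sel], beta)
    } else {
      e <- eigen(G, symmetric = TRUE)
      a <- crossprod(e$vectors, cs)[, 1]
      B <- e$vectors %*% (a / outer(pmax(e$values, 0), lam, "+"))
      P <- fd$Xte[, sel, drop = FALSE] %*% B
    }
    oof[fd$te, ] <- P + fd$ybar
  }
  oof
}

fitness_from_oof <- function(ctx, oof, n_selected) {
  err <- if (ctx$objective == "mae") abs(oof - ctx$y) else (oof - ctx$y)^2
  overall <- colMeans(err)
  li <- which.min(overall)
  per_tissue <- tapply(err[, li], ctx$tissue, mean)
  per_tissue <- stats::setNames(as.numeric(per_tissue), names(per_tissue))
  per_tissue <- per_tissue[sort(names(per_tissue))]
  mean_mae <- mean(per_tissue)
  penalty <- ctx$penalty * n_selected
  structure(list(
    per_tissue_mae = per_tissue,
    mean_mae = mean_mae,
    n_selected = n_selected,
    penalty = penalty,
    fitness = mean_mae + penalty,
    lambda = ctx$lambda[li]
  ), class = "fitness_result")
}

#' Penalised per-tissue ridge fitness of a chromosome
#'
#' The GA's objective. For the CpGs included by `chromosome`, a ridge
#' regression of chronological age on their M-values is cross-validated:
#' the ridge penalty is chosen on a fixed log-spaced grid to minimise the
#' overall out-of-fold MAE, the out-of-fold predictions at that penalty
#' give one MAE per tissue, and the fitness is the *unweighted* mean of
#' the per-tissue MAEs (so small tissues count as much as large ones)
#' plus `cpg_penalty` years per included CpG. Folds are seeded from the
#' config and identical for every chromosome, making fitness values
#' directly comparable. An all-zero chromosome is scored as the
#' intercept-only model (no penalty), keeping the fitness total.
#'
#' @param chromosome Logical (or 0/1) vector over the candidate CpGs,
#'   aligned to the columns of `M_train`.
#' @param M_train A [methyl_matrix()] on the M scale, or a bare numeric
#'   matrix (samples x candidate CpGs), without missing values.
#' @param sheet_train Sample sheet for the training samples.
#' @param config A [ga_config()].
#' @param context Precomputed fitness context (used internally by
#'   [run_ga()] to share work across evaluations); built on the fly when
#'   `NULL`.
#' @return A `fitness_result`: `per_tissue_mae`, `mean_mae`,
#'   `n_selected`, `penalty`, `fitness` (= `mean_mae + penalty`,
#'   exactly) and the chosen `lambda`.
#' @export
ridge_fitness <- function(chromosome, M_train, sheet_train, config = ga_config(),
                          context = NULL) {
  if (is.null(context)) {
    M <- if (inherits(M_train, "methyl_matrix")) M_train$values else M_train
    sheet <- if (is.data.frame(sheet_train)) sheet_train else stop("sheet required")
    sheet <- sheet[match(rownames(M), sheet$sample_id), , drop = FALSE]
    context <- new_fitness_context(M, sheet, config)
  }
  bits <- as.logical(chromosome)
  if (length(bits) != length(context$fold_data[[1]]$c)) {
    stop("chromosome length must match the candidate CpG universe", call. = FALSE)
  }
  sel <- which(bits)
  fitness_from_oof(context, oof_predictions(context, sel), length(sel))
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> fitness %.3f y = mean MAE %.3f + penalty %.3f (%d CpGs), lambda %.3g\n",
              x$fitness, x$mean_mae, x$penalty, x$n_selected, x$lambda))
  invisible(x)
}

# ---- population mechanics --------------------------------------------------

#' Initialise a GA population
#'
#' Draws `population_size` chromosomes whose bits are independently set
#' with probability `init_density`; any all-zero chromosome is repaired
#' by setting one uniformly chosen bit.
#'
#' @param config A [ga_config()].
#' @param n_features Candidate-universe size.
#' @param seed Optional seed (defaults to `config$seed`); pass `NULL` to
#'   use the current RNG state.
#' @return List of logical vectors.
#' @export
init_population <- function(config, n_features, seed = config$seed) {
  stopifnot(is_count(n_features))
  if (!is.null(seed)) set.seed(sub_seed(seed, 21L))
  lapply(seq_len(config$population_size), function(i) {
    bits <- stats::runif(n_features) < config$init_density
    if (!any(bits)) bits[sample.int(n_features, 1L)] <- TRUE
    bits
  })
}

single_point_crossover <- function(p1, p2, cut) {
  L <- length(p1)
  list(c(p1[seq_len(cut)], p2[seq(cut + 1L, L)]),
       c(p2[seq_len(cut)], p1[seq(cut + 1L, L)]))
}

mutate_child <- function(bits, config) {
  if (config$mutation_kind == "per_child") {
    if (stats::runif(1) < config$mutation_rate) {
      i <- sample.int(length(bits), 1L)
      bits[i] <- !bits[i]
    }
  } else {
    flip <- stats::runif(length(bits)) < config$mutation_rate / length(bits)
    bits[flip] <- !bits[flip]
  }
  if (!any(bits)) bits[sample.int(length(bits), 1L)] <- TRUE
  bits
}

island_order <- function(island) {
  fitness_order(vapply(island$fitness, `[[`, 0, "fitness"),
                vapply(island$fitness, `[[`, 0L, "n_selected"))
}

#' Evolve one island by one generation
#'
#' Elitism, recombination and mutation: the lowest-fitness
#' `max(2, ceiling(elite_fraction * size))` chromosomes are retained
#' unchanged (ties broken by fewer set bits, then by position); the rest
#' of the island is refilled with offspring of parent pairs (drawn
#' uniformly from the elite, or by size-2 tournament when configured)
#' that recombine by single-point crossover with probability
#' `crossover_rate` and mutate per `mutation_kind`. Offspring are
#' evaluated with `fitness_fn`; the island size never changes.
#'
#' @param island List with `population` (logical vectors), `fitness`
#'   (aligned `fitness_result`s) and `generation`.
#' @param fitness_fn Function from a bit vector to a `fitness_result`.
#' @param config A [ga_config()].
#' @return The next island state (all members evaluated).
#' @export
evolve_generation <- function(island, fitness_fn, config) {
  size <- length(island$population)
  if (size < 2L) stop("island size must be at least 2", call. = FALSE)
  ord <- island_order(island)
  n_elite <- min(size, max(2L, ceiling(config$elite_fraction * size)))
  elite_idx <- ord[seq_len(n_elite)]
  n_off <- size - n_elite

  parent_pool <- if (config$parent_selection == "elite") elite_idx else seq_len(size)
  fvals <- vapply(island$fitness, `[[`, 0, "fitness")
  pick_parent <- function() {
    if (config$parent_selection == "elite") {
      parent_pool[sample.int(length(parent_pool), 1L)]
    } else { # size-2 tournament
      cand <- sample.int(size, 2L)
      cand[which.min(fvals[cand])]
    }
  }

  offspring <- vector("list", n_off)
  filled <- 0L
  while (filled < n_off) {
    i1 <- pick_parent()
    i2 <- pick_parent()
    p1 <- island$population[[i1]]
    p2 <- island$population[[i2]]
    children <- if (stats::runif(1) < config$crossover_rate) {
      cut <- sample.int(length(p1) - 1L, 1L)
      single_point_crossover(p1, p2, cut)
    } else {
      list(p1, p2)
    }
    for (ch in children) {
      if (filled >= n_off) break
      filled <- filled + 1L
      offspring[[filled]] <- mutate_child(ch, config)
    }
  }
  new_pop <- c(island$population[elite_idx], offspring)
  new_fit <- c(island$fitness[elite_idx], lapply(offspring, fitness_fn))
  list(population = new_pop, fitness = new_fit,
       generation = island$generation + 1L)
}

#' Migrate best chromosomes around the island ring
#'
#' Every island sends a copy of its best chromosome to the next island
#' in the ring, where it replaces that island's worst member; if the
#' destination already holds an identical chromosome the migrant is
#' dropped instead of displacing diversity (so migration between
#' identical islands is a no-op). Population sizes are unchanged and the
#' global best fitness can only improve.
#'
#' @param islands List of island states (all evaluated).
#' @param config A [ga_config()].
#' @return The updated list of islands.
#' @export
migrate <- function(islands, config) {
  n <- length(islands)
  if (n < 2L) stop("migration needs at least 2 islands", call. = FALSE)
  bests <- lapply(islands, function(isl) {
    i <- island_order(isl)[1L]
    list(chromosome = isl$population[[i]], fitness = isl$fitness[[i]])
  })
  for (i in seq_len(n)) {
    dest <- if (i == n) 1L else i + 1L
    incoming <- bests[[i]]$chromosome
    already <- any(vapply(islands[[dest]]$population, identical, TRUE, y = incoming))
    if (already) next # a copy is resident; do not displace diversity for it
    ord <- island_order(islands[[dest]])
    worst <- ord[length(ord)]
    islands[[dest]]$population[[worst]] <- incoming
    islands[[dest]]$fitness[[worst]] <- bests[[i]]$fitness
  }
  islands
}

#' Run the penalised genetic algorithm islands model
#'
#' Evolves binary CpG-inclusion chromosomes to minimise the penalised
#' per-tissue ridge fitness ([ridge_fitness()]). The population is split
#' equally across `n_islands` islands that evolve independently
#' ([evolve_generation()]) and exchange their best chromosomes every
#' `migration_interval` generations ([migrate()]). Fitness values of
#' recurring chromosomes are cached, and the best chromosome ever
#' observed is returned together with a per-generation history. Islands
#' are evolved sequentially, so a run is reproducible from
#' (data, config, seed) alone.
#'
#' @param M_train A [methyl_matrix()] on the M scale (or bare matrix),
#'   training samples only, no missing values.
#' @param sheet_train Sample sheet covering the training samples.
#' @param candidate_cpgs CpGs forming the chromosome (default: all
#'   columns of `M_train`); typically the output of
#'   [correlation_prefilter()].
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `selected_cpgs`, `best_chromosome`
#'   (logical, named by candidate CpG), `best_fitness` (a
#'   `fitness_result`), `history` (data frame: generation, island,
#'   best_fitness, mean_fitness, best_n_selected), `candidate_cpgs` and
#'   `config`.
#' @export
run_ga <- function(M_train, sheet_train, candidate_cpgs = NULL,
                   config = ga_config()) {
  M <- if (inherits(M_train, "methyl_matrix")) {
    if (M_train$scale != "m") stop("GA operates on M-values; convert first", call. = FALSE)
    M_train$values
  } else M_train
  sheet <- validate_sample_sheet(sheet_train)
  sheet <- sheet[match(rownames(M), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sheet does not cover all training samples", call. = FALSE)
  candidate_cpgs <- candidate_cpgs %||% colnames(M)
  if (!all(candidate_cpgs %in% colnames(M))) {
    stop("candidate CpGs absent from the training matrix", call. = FALSE)
  }
  M <- M[, candidate_cpgs, drop = FALSE]
  if (anyNA(M)) stop("training matrix has missing values; impute first", call. = FALSE)
  n_feat <- ncol(M)

  ctx <- new_fitness_context(M, sheet, config)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L
  fit_fn <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- fitness_from_oof(ctx, oof_predictions(ctx, which(bits)), sum(bits))
    if (!is.finite(res$fitness)) stop("non-finite fitness encountered", call. = FALSE)
    n_evals <<- n_evals + 1L
    assign(key, res, envir = cache)
    res
  }

  set.seed(sub_seed(config$seed, 31L))
  pop <- init_population(config, n_feat, seed = NULL)
  island_size <- config$population_size / config$n_islands
  islands <- lapply(seq_len(config$n_islands), function(i) {
    idx <- seq.int((i - 1L) * island_size + 1L, i * island_size)
    list(population = pop[idx], fitness = lapply(pop[idx], fit_fn), generation = 0L)
  })

  best <- NULL
  note_best <- function(isl) {
    i <- island_order(isl)[1L]
    f <- isl$fitness[[i]]
    better <- is.null(best) || f$fitness < best$fitness$fitness ||
      (f$fitness == best$fitness$fitness && f$n_selected < best$fitness$n_selected)
    if (better) best <<- list(chromosome = isl$population[[i]], fitness = f)
  }
  for (isl in islands) note_best(isl)

  history <- vector("list", config$n_generations * config$n_islands)
  row <- 0L
  for (gen in seq_len(config$n_generations)) {
    for (i in seq_along(islands)) {
      islands[[i]] <- evolve_generation(islands[[i]], fit_fn, config)
    }
    if (config$n_islands >= 2L && gen %% config$migration_interval == 0L) {
      islands <- migrate(islands, config)
    }
    for (i in seq_along(islands)) {
      note_best(islands[[i]])
      fvals <- vapply(islands[[i]]$fitness, `[[`, 0, "fitness")
      bi <- island_order(islands[[i]])[1L]
      row <- row + 1L
      history[[row]] <- data.frame(
        generation = gen, island = i,
        best_fitness = fvals[bi], mean_fitness = mean(fvals),
        best_n_selected = islands[[i]]$fitness[[bi]]$n_selected)
    }
  }
  bits <- best$chromosome
  names(bits) <- candidate_cpgs
  structure(list(
    selected_cpgs = candidate_cpgs[bits],
    best_chromosome = bits,
    best_fitness = best$fitness,
    history = do.call(rbind, history),
    candidate_cpgs = candidate_cpgs,
    n_evaluations = n_evals,
    config = config
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d/%d CpGs selected, fitness %.3f y (mean MAE %.3f), %d generations\n",
              length(x$selected_cpgs), length(x$candidate_cpgs),
              x$best_fitness$fitness, x$best_fitness$mean_mae,
              max(x$history$generation)))
  invisible(x)
}

# ---- ridge age model (refit of a selected set) -----------------------------

#' Fit a ridge age predictor on a fixed CpG set
#'
#' Refits the GA's internal model on the full training set: the ridge
#' penalty is chosen by the same seeded cross-validation as
#' [ridge_fitness()], then the coefficients are re-estimated on all
#' training samples at that penalty. Used to measure held-out error of a
#' selected CpG set (e.g. the GA winner or the planted truth).
#'
#' @inheritParams run_ga
#' @param cpgs CpGs to include (all must be columns of `M_train`).
#' @return An object of class `ridge_age_model` with a `predict` method
#'   mapping a [methyl_matrix()] (M scale) to ages in years.
#' @export
fit_ridge_age_model <- function(M_train, sheet_train, cpgs, config = ga_config()) {
  M <- if (inherits(M_train, "methyl_matrix")) M_train$values else M_train
  sheet <- validate_sample_sheet(sheet_train)
  sheet <- sheet[match(rownames(M), sheet$sample_id), , drop = FALSE]
  M <- M[, cpgs, drop = FALSE]
  ctx <- new_fitness_context(M, sheet, config)
  fit <- fitness_from_oof(ctx, oof_predictions(ctx, seq_along(cpgs)), length(cpgs))
  y <- sheet$age
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv < 1e-12] <- Inf
  Xs <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  G <- crossprod(Xs)
  e <- eigen(G, symmetric = TRUE)
  a <- crossprod(e$vectors, crossprod(Xs, y - mean(y))[, 1])[, 1]
  beta <- e$vectors %*% (a / (pmax(e$values, 0) + fit$lambda))
  structure(list(cpgs = cpgs, mu = mu, sd = sdv, beta = beta[, 1],
                 intercept = mean(y), lambda = fit$lambda, cv_fitness = fit),
            class = "ridge_age_model")
}

#' @param object A `ridge_age_model`.
#' @param newdata A [methyl_matrix()] (M scale) or matrix containing the
#'   model's CpGs.
#' @param ... Unused.
#' @rdname fit_ridge_age_model
#' @export
predict.ridge_age_model <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "methyl_matrix")) newdata$values else newdata
  Xs <- sweep(sweep(M[, object$cpgs, drop = FALSE], 2, object$mu), 2, object$sd, "/")
  as.numeric(Xs %*% object$beta) + object$intercept
}
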