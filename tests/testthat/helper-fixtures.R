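# Small simulated worlds shared across test files. Sizes are kept at
# desk scale so the whole suite stays fast; every fixture is built in
# code from a fixed seed.

tiny_truth <- function(seed = 42, noise_sd = 0.3, ...) {
  simulation_truth(
    n_cpgs = 300,
    tissues = c("cartilage", "bone"),
    tissue_sizes = c(40, 30),
    age_ranges = list(c(20, 90), c(25, 80)),
    n_age_shared = 15, n_age_specific = 5, n_identity = 30,
    noise_sd = noise_sd, seed = seed, ...)
}

tiny_world <- function(seed = 42, noise_sd = 0.3, ...) {
  truth <- tiny_truth(seed = seed, noise_sd = noise_sd, ...)
  sim <- simulate_dataset(truth)
  sim
}

# Restrict a methyl_matrix to a sample subset, preserving the class.
take_samples <- function(x, ids) {
  structure(list(values = x$values[ids, , drop = FALSE], scale = x$scale),
            class = "methyl_matrix")
}

split_world <- function(sim, fraction = 0.7, seed = 1) {
  sp <- stratified_split(sim$sheet, fraction = fraction, seed = seed)
  list(
    train = take_samples(sim$matrix, sp$train_ids),
    test = take_samples(sim$matrix, sp$test_ids),
    sheet_train = sim$sheet[match(sp$train_ids, sim$sheet$sample_id), ],
    sheet_test = sim$sheet[match(sp$test_ids, sim$sheet$sample_id), ],
    split = sp)
}
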