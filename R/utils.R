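`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and an index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483629)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Order chromosomes: fitness ascending, then fewer set bits, then index.
# Shared tie-break rule for elitism, migration and best-ever tracking.
fitness_order <- function(fitness, n_selected) {
  order(fitness, n_selected, seq_along(fitness))
}
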