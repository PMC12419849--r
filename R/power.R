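#' Cohen's d for an age-acceleration contrast
#'
#' Effect size in pooled-SD units: `d = effect / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`.
#' With equal SDs the pooled SD reduces to that SD regardless of group
#' sizes.
#'
#' @param effect_years Difference in mean age acceleration (years).
#' @param accel_sd_a,accel_sd_b Group SDs of age acceleration (years,
#'   `> 0`; `accel_sd_b` defaults to `accel_sd_a`).
#' @param n_a,n_b Group sizes (only their ratio matters; default equal).
#' @return Cohen's d (dimensionless).
#' @export
cohens_d <- function(effect_years, accel_sd_a, accel_sd_b = accel_sd_a,
                     n_a = 2, n_b = n_a) {
  if (accel_sd_a <= 0 || accel_sd_b <= 0) {
    stop("group SDs must be positive", call. = FALSE)
  }
  stopifnot(n_a >= 2 || n_b >= 2)
  pooled <- sqrt(((n_a - 1) * accel_sd_a^2 + (n_b - 1) * accel_sd_b^2) /
                   (n_a + n_b - 2))
  effect_years / pooled
}

# Vectorised Monte-Carlo power of the two-sample t-test at per-group
# size n and effect d (SD 1 per group).
mc_power <- function(n, d, alpha = 0.05, n_sims = 1e4, seed = 1,
                     alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  set.seed(sub_seed(seed, 61L + n))
  a <- matrix(stats::rnorm(n * n_sims), n)
  b <- matrix(stats::rnorm(n * n_sims, mean = d), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - n * ma^2) / (n - 1)
  vb <- (colSums(b^2) - n * mb^2) / (n - 1)
  sp <- sqrt((va + vb) / 2)
  tstat <- (mb - ma) / (sp * sqrt(2 / n))
  df <- 2 * n - 2
  if (alternative == "two.sided") {
    mean(abs(tstat) > stats::qt(1 - alpha / 2, df))
  } else {
    mean(tstat > stats::qt(1 - alpha, df))
  }
}

#' Per-group sample size for a target power
#'
#' Smallest per-group `n` at which a two-sample t-test (equal group
#' sizes, common SD) detects standardized effect `d` with at least the
#' target power at level `alpha`. The analytic backend solves the
#' noncentral-t power equation (via [stats::power.t.test()]) and rounds
#' up to the verified integer; the simulation backend searches over `n`
#' using Monte-Carlo rejection rates, matching the "simulated power"
#' reading of the procedure. Both are exposed; they agree to about one
#' sample per group.
#'
#' @param d Cohen's d (`> 0`).
#' @param power Target power (default 0.80).
#' @param alpha Significance level (default 0.05).
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @param n_sims Monte-Carlo replicates per candidate `n` (default
#'   `1e4`).
#' @param seed Seed for the simulation backend.
#' @return Integer per-group sample size (`>= 2`).
#' @export
required_sample_size <- function(d, power = 0.80, alpha = 0.05,
                                 method = c("analytic", "simulation"),
                                 alternative = c("two.sided", "one.sided"),
                                 n_sims = 1e4, seed = 1) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("`d` must be a single positive number", call. = FALSE)
  }
  if (method == "analytic") {
    alt <- if (alternative == "two.sided") "two.sided" else "one.sided"
    n0 <- stats::power.t.test(delta = d, sd = 1, sig.level = alpha,
                              power = power, alternative = alt)$n
    n <- max(2L, as.integer(ceiling(n0 - 1e-9)))
    achieved <- function(nn) stats::power.t.test(n = nn, delta = d, sd = 1,
                                                 sig.level = alpha,
                                                 alternative = alt)$power
    while (achieved(n) < power) n <- n + 1L
    n
  } else {
    pw <- function(nn) mc_power(nn, d, alpha, n_sims, seed, alternative)
    lo <- 2L
    hi <- 4L
    while (pw(hi) < power && hi < 1e6) { lo <- hi; hi <- hi * 2L }
    while (hi - lo > 1L) { # binary search on (noisy but monotone) power
      mid <- (lo + hi) %/% 2L
      if (pw(mid) >= power) hi <- mid else lo <- mid
    }
    hi
  }
}

#' Sample-size curve over a grid of effect sizes
#'
#' Turns an observed age-acceleration distribution into experiment
#' planning numbers: its SD standardizes each candidate effect size into
#' a Cohen's d, and [required_sample_size()] gives the per-group n
#' achieving the target power.
#'
#' @param errors Numeric vector of per-sample age accelerations (years,
#'   length >= 3, non-degenerate).
#' @param effect_sizes_years Effect grid (default 1.0-2.5 years in steps
#'   of 0.25).
#' @param power_target Target power (default 0.80).
#' @param alpha Significance level (default 0.05).
#' @param method Backend passed to [required_sample_size()].
#' @param ... Further arguments to [required_sample_size()].
#' @return A data frame of class `power_grid` with columns
#'   `effect_size_years`, `d` and `required_n` (per group), plus
#'   attribute `sd_acceleration`.
#' @export
power_curve <- function(errors, effect_sizes_years = seq(1, 2.5, by = 0.25),
                        power_target = 0.80, alpha = 0.05,
                        method = c("analytic", "simulation"), ...) {
  method <- match.arg(method)
  if (length(errors) < 3L) stop("need at least 3 accelerations", call. = FALSE)
  sd_acc <- stats::sd(errors)
  if (!is.finite(sd_acc) || sd_acc == 0) {
    stop("degenerate (zero-SD) acceleration vector", call. = FALSE)
  }
  d <- effect_sizes_years / sd_acc
  required_n <- vapply(d, required_sample_size, 0L, power = power_target,
                       alpha = alpha, method = method, ...)
  out <- data.frame(effect_size_years = effect_sizes_years, d = d,
                    required_n = required_n)
  attr(out, "sd_acceleration") <- sd_acc
  attr(out, "power_target") <- power_target
  attr(out, "alpha") <- alpha
  class(out) <- c("power_grid", "data.frame")
  out
}
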