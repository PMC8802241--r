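# synthetic decomposition + divergence tables for regression tests
toy_decomp <- function(D, f1, f2, dom_f1 = 0, dom_f2 = 0, var_f1 = 0,
                       var_f2 = 0) {
  n <- length(D)
  data.frame(
    cross_id = rep(sprintf("c%02d", seq_len(n)), each = 2),
    generation = rep(c("F1", "F2"), n),
    mean_mismatch = as.vector(rbind(f1, f2)),
    dominance_effect = as.vector(rbind(dom_f1, dom_f2)),
    variance_effect = as.vector(rbind(var_f1, var_f2)),
    stringsAsFactors = FALSE
  )
}
toy_div <- function(D) {
  data.frame(cross_id = sprintf("c%02d", seq_along(D)), divergence = D,
             stringsAsFactors = FALSE)
}

test_that("a noiseless planted slope is recovered exactly", {
  D <- seq(3, 10, length.out = 12)
  dec <- toy_decomp(D, f1 = 0.1 * D, f2 = 0.1 * D)
  fit <- fit_divergence_mismatch(dec, toy_div(D))
  expect_equal(fit$pooled$slope, 0.1, tolerance = 1e-6)
  expect_equal(fit$per_generation$slope, c(0.1, 0.1), tolerance = 1e-6)
})

test_that("with zero population variance the mixed model matches OLS", {
  set.seed(30)
  D <- seq(3, 10, length.out = 12)
  # generation effect but no cross-level random effect
  dec <- toy_decomp(D, f1 = 0.5 + 0.1 * D + rnorm(12, 0, 0.05),
                    f2 = 0.8 + 0.1 * D + rnorm(12, 0, 0.05))
  fit_mixed <- fit_divergence_mismatch(dec, toy_div(D), engine = "lmer")
  fit_ols <- fit_divergence_mismatch(dec, toy_div(D), engine = "lm")
  expect_equal(fit_mixed$pooled$slope, fit_ols$pooled$slope,
               tolerance = 1e-4)
})

test_that("slope estimates do not depend on the order of crosses", {
  set.seed(31)
  D <- seq(3, 10, length.out = 12)
  dec <- toy_decomp(D, f1 = 0.1 * D + rnorm(12, 0, 0.1),
                    f2 = 0.1 * D + rnorm(12, 0, 0.1))
  div <- toy_div(D)
  fit1 <- fit_divergence_mismatch(dec, div)
  perm <- sample(nrow(dec))
  fit2 <- fit_divergence_mismatch(dec[perm, ], div[sample(12), ])
  expect_equal(fit2$pooled$slope, fit1$pooled$slope, tolerance = 1e-10)
  expect_error(fit_divergence_mismatch(dec[dec$cross_id %in%
    c("c01", "c02"), ], div), "at least 3 crosses")
})

test_that("mechanism regressions dissociate planted generation effects", {
  set.seed(32)
  D <- seq(3, 10, length.out = 12)
  # dominance effect proportional to divergence in F1 only
  dec <- toy_decomp(D,
                    f1 = 0.2 * D, f2 = 0.5 + 0 * D,
                    dom_f1 = 0.2 * D + rnorm(12, 0, 0.08),
                    dom_f2 = 0.3 + rnorm(12, 0, 0.08),
                    var_f1 = 0.3 + rnorm(12, 0, 0.08),
                    var_f2 = 0.15 * D + rnorm(12, 0, 0.08))
  fits <- fit_effect_regressions(dec, toy_div(D))
  dom <- fits$dominance$per_generation
  expect_lt(dom$p[dom$generation == "F1"], 0.05)
  f2row <- dom[dom$generation == "F2", ]
  expect_true(f2row$ci_lower <= 0 && f2row$ci_upper >= 0)
  vr <- fits$variance$per_generation
  expect_lt(vr$p[vr$generation == "F2"], 0.05)
  f1row <- vr[vr$generation == "F1", ]
  expect_true(f1row$ci_lower <= 0 && f1row$ci_upper >= 0)

  # all-zero effects: both slope CIs cover 0
  dec0 <- toy_decomp(D, f1 = rnorm(12, 1, 0.1), f2 = rnorm(12, 1, 0.1),
                     dom_f1 = rnorm(12, 0.5, 0.1),
                     dom_f2 = rnorm(12, 0.5, 0.1),
                     var_f1 = rnorm(12, 0.5, 0.1),
                     var_f2 = rnorm(12, 0.5, 0.1))
  fits0 <- fit_effect_regressions(dec0, toy_div(D))
  for (f in fits0) {
    expect_true(all(f$per_generation$ci_lower <= 0 &
                      f$per_generation$ci_upper >= 0))
  }
})

test_that("interaction p-values are roughly uniform under equal slopes", {
  set.seed(33)
  D <- seq(3, 10, length.out = 12)
  p <- replicate(200, {
    dec <- toy_decomp(D, f1 = 0.1 * D + rnorm(12, 0, 0.15),
                      f2 = 0.1 * D + rnorm(12, 0, 0.15))
    fit_divergence_mismatch(dec, toy_div(D), per_generation = FALSE)$interaction$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.06)
  expect_gt(median(p), 0.25)
})

test_that("snowball counts and their growth models behave as planted", {
  set.seed(34)
  D <- seq(3, 10, length.out = 12)
  div <- toy_div(D)

  # quadratic truth: the quadratic term is detected in most replicates
  Dq <- seq(1, 10, length.out = 30)
  divq <- toy_div(Dq)
  hits_quad <- 0L
  for (i in 1:40) {
    counts <- data.frame(
      cross_id = rep(divq$cross_id, each = 2),
      generation = rep(c("F1", "F2"), 30),
      n_pairs = 105L,
      n_significant = pmin(105L, rpois(60, rep(0.9 * Dq^2, each = 2)))
    )
    f <- snowball_fit(counts, divq)
    hits_quad <- hits_quad + (f$p_quadratic[f$generation == "F1"] < 0.05)
  }
  expect_gt(hits_quad / 40, 0.6)

  # linear truth: quadratic term fires at ~alpha
  hits_lin <- 0L
  for (i in 1:100) {
    counts <- data.frame(
      cross_id = rep(div$cross_id, each = 2),
      generation = rep(c("F1", "F2"), 12),
      n_pairs = 105L,
      n_significant = rpois(24, rep(3 * D, each = 2))
    )
    f <- snowball_fit(counts, div)
    hits_lin <- hits_lin + (f$p_quadratic[f$generation == "F1"] < 0.05)
  }
  expect_lt(hits_lin / 100, 0.2)

  # all-zero counts still fit
  counts0 <- data.frame(cross_id = rep(div$cross_id, each = 2),
                        generation = rep(c("F1", "F2"), 12),
                        n_pairs = 105L, n_significant = 0L)
  f0 <- snowball_fit(counts0, div)
  expect_equal(f0$slope_linear, c(0, 0))
})

test_that("a silent simulation produces zero significant trait pairs", {
  cfg <- simulation_config(n_crosses = 4, sigma_parent = 0, family_sd = 0,
                           h_perp = 0, dominance_sd = 0,
                           n_effective_factors = Inf)
  sim <- simulate_study(cfg, seed = 99)
  std <- as_standardized_traits(sim$table)
  snow <- suppressWarnings(snowball(std))
  expect_true(all(snow$counts$n_significant == 0L))

  # with noise but no planted mechanism the rejection rate stays low
  # (mildly above alpha: the parents define the line they are tested
  # against, which deflates their own deviations slightly)
  cfg2 <- simulation_config(n_crosses = 4, h_perp = 0, dominance_sd = 0,
                            n_effective_factors = Inf)
  sim2 <- simulate_study(cfg2, seed = 99)
  snow2 <- snowball(as_standardized_traits(sim2$table))
  expect_lt(mean(snow2$counts$n_significant / snow2$counts$n_pairs), 0.25)
})

test_that("F2 trait correlations are summarized within crosses", {
  set.seed(35)
  cfg <- simulation_config(n_crosses = 6)
  sim <- simulate_study(cfg, seed = 41)
  std <- as_standardized_traits(sim$table)
  cs <- f2_correlation_summary(std)
  # traits are generated independently within families
  expect_lt(cs$median_abs_r, 0.25)
  expect_lt(abs(cs$pct_significant - 5), 7)
  expect_equal(cs$n_pairs, 6 * choose(15, 2))

  # a duplicated trait column gives r = 1 for that pair
  std2 <- std
  std2$values[, 2] <- std2$values[, 1]
  cs2 <- f2_correlation_summary(std2)
  dup <- cs2$pairs[cs2$pairs$trait_i == colnames(std2$values)[2] &
                     cs2$pairs$trait_j == colnames(std2$values)[1], ]
  expect_true(all(abs(dup$r - 1) < 1e-12))
})
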