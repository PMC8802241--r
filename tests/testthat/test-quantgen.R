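# one cross with explicit generation means and optional noise
qg_std <- function(mu, n = 10, sd = 0, n_fam = 2, seed = 1) {
  set.seed(seed)
  gens <- c("PM", "PF", "F1", "F2")
  vals <- NULL; gen <- NULL; fam <- NULL
  for (g in gens) {
    vals <- c(vals, rnorm(n, mu[[g]], sd))
    gen <- c(gen, rep(g, n))
    fam <- c(fam, paste0(g, "_f", rep_len(seq_len(n_fam), n)))
  }
  make_std(matrix(c(vals, vals * 0.5 + rnorm(length(vals), 0, sd + 0.01)),
                  ncol = 2), gen = gen, fam = fam)
}

test_that("parent difference screening behaves like a t-test", {
  std <- qg_std(list(PM = 0, PF = 5, F1 = 2.5, F2 = 2.5), n = 30, sd = 1)
  pd <- parents_differ(std, "c1", "t1")
  expect_true(pd$differ)
  expect_lt(pd$p, 1e-10)

  # single fish in a group: skipped with warning
  drop <- which(std$meta$generation == "PM")[-1]
  keep <- setdiff(seq_len(nrow(std$values)), drop)
  std1 <- standardized_traits(std$values[keep, , drop = FALSE],
                              std$meta[keep, ])
  expect_warning(pd <- parents_differ(std1, "c1", "t1"), "skipped")
  expect_true(is.na(pd$differ))
})

test_that("splitting one population at random gives ~alpha false positives", {
  set.seed(10)
  n_rep <- 1000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(15); b <- rnorm(15)
    hits <- hits + (t.test(a, b)$p.value < 0.05)
  }
  rate <- hits / n_rep
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the additive/dominance design is solved exactly on planted means", {
  # parents at 0 and 1, F1 fully marine-like (0), F2 at 0.25:
  # mu + 0.5 b_a + b_d = 0 and mu + 0.5 b_a + 0.5 b_d = 0.25
  # with mu = 0, b_a = 1 give b_d = -0.5
  std <- qg_std(list(PM = 0, PF = 1, F1 = 0, F2 = 0.25), n = 12, sd = 1e-4,
                n_fam = 3, seed = 2)
  fit <- fit_additive_dominance(std, "c1", "t1")
  expect_equal(fit$beta_additive, 1, tolerance = 0.01)
  expect_equal(fit$beta_dominance, -0.5, tolerance = 0.01)

  # pure additivity: dominance deviation ~ 0
  std <- qg_std(list(PM = 0, PF = 1, F1 = 0.5, F2 = 0.5), n = 12, sd = 1e-4,
                n_fam = 3, seed = 3)
  fit <- fit_additive_dominance(std, "c1", "t1")
  expect_lt(abs(fit$beta_dominance), 0.01)
  expect_equal(fit$beta_additive, 1, tolerance = 0.01)
})

test_that("planted additive and dominance coefficients are recovered", {
  set.seed(20)
  b_a <- 0.8; b_d <- 0.3
  gens <- c("PM", "PF", "F1", "F2")
  a_idx <- c(PM = 0, PF = 1, F1 = 0.5, F2 = 0.5)
  h_idx <- c(PM = 0, PF = 0, F1 = 1, F2 = 0.5)
  n_fam <- 6; n_per <- 10
  gen <- rep(gens, each = n_fam * n_per)
  fam <- paste0(gen, "_f", rep(rep(seq_len(n_fam), each = n_per), 4))
  fam_eff <- rnorm(length(unique(fam)), 0, 0.15)
  names(fam_eff) <- unique(fam)
  y <- b_a * a_idx[gen] + b_d * h_idx[gen] + fam_eff[fam] +
    rnorm(length(gen), 0, 0.3)
  std <- make_std(cbind(y, rnorm(length(y))), gen = gen, fam = fam)
  fit <- fit_additive_dominance(std, "c1", "t1")
  expect_equal(fit$model, "lmm")
  expect_lt(abs(fit$beta_dominance - b_d), 2 * fit$se_dominance)

  # likelihood-ratio option agrees on direction and significance
  fit_lrt <- fit_additive_dominance(std, "c1", "t1", method = "lrt")
  expect_equal(fit_lrt$beta_dominance, fit$beta_dominance)
  expect_lt(fit_lrt$p_dominance, 0.05)
})

test_that("balanced no-family-effect fits agree with OLS on generation means", {
  set.seed(21)
  std <- qg_std(list(PM = 0, PF = 1, F1 = 0.7, F2 = 0.5), n = 20, sd = 0.2,
                n_fam = 2, seed = 4)
  fit <- fit_additive_dominance(std, "c1", "t1")
  gen <- std$meta$generation
  df <- data.frame(
    value = std$values[, "t1"],
    additive = c(PM = 0, PF = 1, F1 = 0.5, F2 = 0.5)[gen],
    het = c(PM = 0, PF = 0, F1 = 1, F2 = 0.5)[gen]
  )
  ols <- coef(lm(value ~ additive + het, data = df))
  expect_equal(fit$beta_additive, unname(ols["additive"]), tolerance = 0.02)
  expect_equal(fit$beta_dominance, unname(ols["het"]), tolerance = 0.02)
})

test_that("dominance coefficients scale the hybrid mean between the parents", {
  mk <- function(f1) {
    qg_std(list(PM = 0, PF = 2, F1 = f1, F2 = 1), n = 20, sd = 0.05,
           seed = 5)
  }
  expect_equal(dominance_coefficient(mk(0), "c1", "F1", "t1"), 0,
               tolerance = 0.05)
  expect_equal(dominance_coefficient(mk(2), "c1", "F1", "t1"), 1,
               tolerance = 0.05)
  expect_equal(dominance_coefficient(mk(1), "c1", "F1", "t1"), 0.5,
               tolerance = 0.05)
  # transgressive hybrid mean beyond the freshwater parent
  expect_gt(dominance_coefficient(mk(2.8), "c1", "F1", "t1"), 1)

  # invariant to affine rescaling of the trait axis
  std <- mk(1.4)
  d0 <- dominance_coefficient(std, "c1", "F1", "t1")
  std2 <- std
  std2$values[, "t1"] <- 2 * std$values[, "t1"] + 3
  expect_equal(dominance_coefficient(std2, "c1", "F1", "t1"), d0,
               tolerance = 1e-10)

  # indistinguishable parents: not computed
  std_null <- qg_std(list(PM = 0, PF = 0.01, F1 = 0, F2 = 0), n = 5, sd = 1,
                     seed = 6)
  expect_true(is.na(dominance_coefficient(std_null, "c1", "F1", "t1")))
})

test_that("family trait variance averages within-family variances", {
  # two families with variances 1 and 3 -> 2
  v1 <- c(-1, 0, 1) * sqrt(1 / var(c(-1, 0, 1)))
  v2 <- c(-1, 0, 1) * sqrt(3 / var(c(-1, 0, 1)))
  std_all <- make_std(matrix(c(v1, v2, 0, 0, 1, 1, 0.5), ncol = 1,
                             dimnames = list(NULL, "t1")),
                      gen = c(rep("F2", 6), "PM", "PM", "PF", "PF", "F1"),
                      fam = c(rep(c("a", "b"), each = 3),
                              "pm1", "pm1", "pf1", "pf1", "f11"))
  fv <- family_trait_variance(std_all, "c1", "F2")
  expect_equal(fv$variance, 2, tolerance = 1e-12)

  # constant trait -> zero variance
  stdc <- make_std(matrix(c(1, 1, 1, 1, 0, 0, 1, 1), ncol = 1,
                          dimnames = list(NULL, "t1")),
                   gen = c("F2", "F2", "F2", "F2", "PM", "PM", "PF", "PF"),
                   fam = c("a", "a", "b", "b", "m", "m", "f", "f"))
  expect_equal(family_trait_variance(stdc, "c1", "F2")$variance, 0)

  # singleton families are skipped with a warning
  stds <- make_std(matrix(c(1, 2, 5, 0, 0, 1, 1), ncol = 1,
                          dimnames = list(NULL, "t1")),
                   gen = c("F2", "F2", "F2", "PM", "PM", "PF", "PF"),
                   fam = c("a", "a", "lone", "m", "m", "f", "f"))
  expect_warning(fv <- family_trait_variance(stds, "c1", "F2"), "skipped")
  expect_equal(fv$variance, var(c(1, 2)))
})

test_that("F2 family variance scales with per-trait segregation input", {
  # plant per-trait F2 SDs proportional to per-trait divergence and check
  # the estimated variance tracks divergence^2
  set.seed(22)
  div_levels <- c(2, 4, 8)
  est <- vapply(div_levels, function(D) {
    s <- 0.5 * D
    vals <- c(rnorm(200, 0, s), rep(0, 2), rep(D, 2), 0.5 * D)
    std <- make_std(matrix(vals, ncol = 1, dimnames = list(NULL, "t1")),
                    gen = c(rep("F2", 200), "PM", "PM", "PF", "PF", "F1"),
                    fam = c(rep(c("a", "b"), 100), "m", "m", "f", "f", "h"))
    family_trait_variance(std, "c1", "F2")$variance
  }, numeric(1))
  ratio <- est / (0.5 * div_levels)^2
  expect_true(all(abs(ratio - 1) < 0.35))
})

test_that("a fully additive simulation yields ~5% dominance false positives", {
  set.seed(23)
  cfg <- simulation_config(n_crosses = 4, h_perp = 0, dominance_sd = 0,
                           n_effective_factors = Inf)
  hits <- 0L; total <- 0L
  for (rep_i in 1:2) {
    sim <- simulate_study(cfg, seed = 3000 + rep_i)
    std <- as_standardized_traits(sim$table)
    for (cr in cross_ids(std)) {
      for (tr in colnames(std$values)) {
        fit <- fit_additive_dominance(std, cr, tr)
        hits <- hits + (fit$p_dominance < 0.05)
        total <- total + 1L
      }
    }
  }
  rate <- hits / total  # 120 tests; loose 3-sigma band around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})
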