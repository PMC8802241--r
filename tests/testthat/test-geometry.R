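test_that("divergence matches closed forms and a sum-of-squares oracle", {
  expect_equal(divergence(rep(1, 15), rep(1, 15)), 0)
  expect_equal(divergence(rep(0, 15), rep(1, 15)), sqrt(15))
  set.seed(1)
  for (i in 1:20) {
    p <- sample(2:15, 1)
    a <- rnorm(p); b <- rnorm(p)
    oracle <- sqrt(sum(vapply(seq_len(p), function(j) (b[j] - a[j])^2,
                              numeric(1))))
    expect_equal(divergence(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(divergence(1:3, 1:4), "equal length")
})

test_that("mismatch is the perpendicular distance to the parental line", {
  pm <- c(0, 0); pf <- c(4, 0)
  expect_equal(mismatch(c(2, 3), pm, pf), 3)
  expect_equal(mismatch((pm + pf) / 2, pm, pf), 0)
  expect_equal(mismatch(pm, pm, pf), 0)
  expect_equal(mismatch(pf, pm, pf), 0)
  # transgressive foot of the perpendicular (outside the segment)
  expect_equal(mismatch(c(10, 2), pm, pf), 2)
  # coincident parents: distance to the point, with a warning
  expect_warning(d <- mismatch(c(3, 4), c(0, 0), c(0, 0)), "coincide")
  expect_equal(d, 5)
})

test_that("mismatch agrees with the grid-search oracle", {
  set.seed(2)
  for (i in 1:25) {
    p <- sample(2:15, 1)
    pm <- rnorm(p)
    d <- rnorm(p)
    d <- d / sqrt(sum(d^2)) * runif(1, 1, 3)
    pf <- pm + d
    # keep the perpendicular foot inside the scanned range of t
    f <- pm + runif(1, -1.5, 2.5) * d + rnorm(p, sd = 0.5)
    closed <- mismatch(f, pm, pf)
    grid <- grid_line_distance(f, pm, pf, -5, 6, 1e-5)
    expect_lt(abs(closed - grid), 1e-6)
  }
})

test_that("mismatch respects the symmetries of the geometry", {
  set.seed(3)
  p <- 15
  pm <- rnorm(p); pf <- rnorm(p)
  f <- matrix(rnorm(5 * p), 5)
  d0 <- mismatch(f, pm, pf)
  # swap parent labels
  expect_equal(mismatch(f, pf, pm), d0, tolerance = 1e-12)
  # global translation
  shift <- rnorm(p)
  expect_equal(mismatch(sweep(f, 2, shift, "+"), pm + shift, pf + shift), d0,
               tolerance = 1e-9)
  # orthogonal rotation
  q <- random_rotation(p)
  expect_equal(mismatch(f %*% q, as.vector(pm %*% q), as.vector(pf %*% q)),
               d0, tolerance = 1e-9)
  # uniform scaling
  expect_equal(mismatch(3.5 * f, 3.5 * pm, 3.5 * pf), 3.5 * d0,
               tolerance = 1e-9)
  # zero iff on the line
  t_grid <- c(-1.3, 0, 0.5, 1, 2.2)
  on_line <- t(vapply(t_grid, function(t) pm + t * (pf - pm), numeric(p)))
  expect_equal(mismatch(on_line, pm, pf), rep(0, 5), tolerance = 1e-9)
})

test_that("population means are unweighted means of family means", {
  # families of sizes 10 and 1 with family means 0 and 1 -> 0.5, not 1/11
  values <- matrix(c(rep(0, 10), 1), ncol = 1)
  std <- make_std(values, gen = "PF", fam = c(rep("a", 10), "b"))
  expect_equal(unname(population_mean(std, "fw")), 0.5)

  # one family: family mean = population mean
  std1 <- make_std(matrix(rnorm(8), 4), gen = "PF", fam = "a")
  expect_equal(population_mean(std1, "fw"), colMeans(std1$values))

  # balanced families: equals the individual-level mean
  set.seed(4)
  v <- matrix(rnorm(24), 12)
  stdb <- make_std(v, gen = "PF", fam = rep(c("a", "b", "c"), each = 4))
  expect_equal(unname(population_mean(stdb, "fw")), unname(colMeans(v)),
               tolerance = 1e-12)

  expect_error(population_mean(std1, "nope"), "empty population")
})

test_that("decomposition is additive, non-negative, and matches symmetry cases", {
  # all hybrids at the midparent
  std <- make_cross_std(c(0, 0), c(4, 0),
                        hybrids = matrix(rep(c(2, 0), 6), ncol = 2,
                                         byrow = TRUE))
  dec <- decompose_mismatch(std, "c1", "F2")
  expect_equal(dec$dominance_effect, 0, tolerance = 1e-12)
  expect_equal(dec$variance_effect, 0, tolerance = 1e-12)

  # mean on the line, individuals offset +/- delta perpendicular
  delta <- 0.7
  hy <- matrix(c(2, delta, 2, -delta, 2, delta, 2, -delta), ncol = 2,
               byrow = TRUE)
  std <- make_cross_std(c(0, 0), c(4, 0), hybrids = hy)
  dec <- decompose_mismatch(std, "c1", "F2")
  expect_equal(dec$dominance_effect, 0, tolerance = 1e-12)
  expect_equal(dec$variance_effect, delta, tolerance = 1e-12)

  # exact additivity and Jensen positivity on random hybrids
  set.seed(5)
  for (avg in c("individual", "family")) {
    hy <- matrix(rnorm(60, sd = 2), ncol = 3)
    std <- make_cross_std(rnorm(3), rnorm(3) + 3, hybrids = hy,
                          hybrid_fam = rep(c("h1", "h2"), each = 10))
    dec <- decompose_mismatch(std, "c1", "F2", averaging = avg)
    expect_equal(dec$mean_mismatch,
                 dec$dominance_effect + dec$variance_effect,
                 tolerance = 1e-12)
    expect_gte(dec$variance_effect, 0)
  }
})

test_that("variance effect converges to the half-normal mean in 2-D", {
  # parents span axis 1; hybrids have perpendicular N(0, s^2) noise only
  set.seed(6)
  s <- 0.8
  n <- 20000
  hy <- cbind(rnorm(n, 2, 0.5), rnorm(n, 0, s))
  std <- make_cross_std(c(0, 0), c(4, 0), hybrids = hy)
  dec <- decompose_mismatch(std, "c1", "F2", averaging = "individual")
  mc_se <- s * sqrt((1 - 2 / pi)) / sqrt(n)
  expect_lt(abs(dec$variance_effect - s * sqrt(2 / pi)),
            3 * mc_se + abs(dec$dominance_effect))
})

test_that("parental deviation matches the chi-distribution mean", {
  set.seed(7)
  p <- 15
  n <- 6000
  pm_true <- rep(0, p); pf_true <- c(rep(0, p - 1), 8)
  vals <- rbind(
    matrix(rnorm(n * p), n) + matrix(pm_true, n, p, byrow = TRUE),
    matrix(rnorm(n * p), n) + matrix(pf_true, n, p, byrow = TRUE)
  )
  std <- make_std(vals, gen = rep(c("PM", "PF"), each = n),
                  fam = rep(c("m1", "m2", "f1", "f2"), each = n / 2))
  dev <- parent_deviation(std, "c1")
  chi_mean <- sqrt(2) * gamma(p / 2) / gamma((p - 1) / 2)  # E[chi_{p-1}]
  mc_se <- sqrt((p - 1 - chi_mean^2) / n)
  expect_lt(abs(dev$mean_deviation[dev$role == "PM"] - chi_mean), 4 * mc_se)
  expect_lt(abs(dev$mean_deviation[dev$role == "PF"] - chi_mean), 4 * mc_se)

  # invariant to swapping which population is called marine
  swapped <- std
  swapped$meta$generation <- c(PM = "PF", PF = "PM")[std$meta$generation]
  swapped$meta$population <- rev(std$meta$population)
  dev2 <- parent_deviation(swapped, "c1")
  expect_equal(sort(dev2$mean_deviation), sort(dev$mean_deviation),
               tolerance = 1e-12)

  # zero-variance parents sit on their own line
  std0 <- make_cross_std(c(0, 0), c(3, 0), hybrids = matrix(c(1, 1), 1))
  dev0 <- parent_deviation(std0, "c1")
  expect_equal(dev0$mean_deviation, c(0, 0), tolerance = 1e-12)
})

test_that("pairwise mismatch is the 2-D restriction of the full metric", {
  set.seed(8)
  # only two traits nonzero: pairwise equals full mismatch
  p <- 6
  pm <- c(1, -1, 0, 0, 0, 0); pf <- c(3, 2, 0, 0, 0, 0)
  hy <- cbind(matrix(rnorm(10 * 2), 10), matrix(0, 10, 4))
  std <- make_cross_std(pm, pf, hybrids = hy, hybrid_gen = "F1")
  pw <- pairwise_mismatch(std, "c1", "t1", "t2", generations = "F1")
  full <- mismatch(hy, pm, pf)
  expect_equal(pw$d_mm, unname(full), tolerance = 1e-10)

  # a hybrid far off the pairwise line scores higher than near-line hybrids
  pm <- c(0, 0); pf <- c(4, 4)
  hy <- rbind(c(2, 2.1), c(1, 0.8), c(0.5, 3.5))
  std <- make_cross_std(pm, pf, hybrids = hy, hybrid_gen = "F1")
  pw <- pairwise_mismatch(std, "c1", "t1", "t2", generations = "F1")
  expect_gt(pw$d_mm[3], max(pw$d_mm[1:2]))

  # interpolating hybrids have zero pairwise mismatch
  expect_lt(pw$d_mm[1], 0.1)
})

test_that("hybrid-parent distances bound the mismatch", {
  pm <- c(0, 0, 0); pf <- c(6, 0, 0)
  hy <- rbind(pm, (pm + pf) / 2)
  std <- make_cross_std(pm, pf, hybrids = hy, hybrid_gen = "F1")
  pd <- parent_distances(std, "c1", "F1")
  expect_equal(pd$dist_pm, c(0, 3), tolerance = 1e-12)
  expect_equal(pd$dist_pf, c(6, 3), tolerance = 1e-12)

  set.seed(9)
  hy <- matrix(rnorm(30 * 3, sd = 3), ncol = 3)
  std <- make_cross_std(pm, pf, hybrids = hy, hybrid_gen = "F2")
  pd <- parent_distances(std, "c1", "F2")
  d <- mismatch(hy, pm, pf)
  expect_true(all(d <= pmin(pd$dist_pm, pd$dist_pf) + 1e-12))
})
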