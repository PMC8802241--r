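#' Configuration for the synthetic cross generator
#'
#' Defines a study of marine x freshwater crosses generated directly in the
#' standardized trait space: one shared marine population (phenotype
#' centred at the origin) crossed with `n_crosses` freshwater populations
#' displaced by `divergence[i]` standardized units along a random direction.
#'
#' F1 hybrids are displaced from the midparent by a dominance vector whose
#' component perpendicular to the parental axis has norm `h_perp *
#' divergence`, so the mismatch of the true F1 mean grows linearly with
#' divergence by construction; F2 means carry `f2_dominance_fraction` of
#' the same displacement (0.5 under the usual halving of dominance in
#' recombinants). F2 phenotypic variance adds a segregation component per
#' trait, `delta_t^2 / (8 * n_effective_factors)` with `delta_t` the
#' per-trait parental difference -- the Castle-Wright form under
#' `n_effective_factors` freely segregating factors -- so segregating
#' variation, and through it mismatch, grows with divergence. Families
#' receive independent Gaussian intercepts on every trait.
#'
#' Default sample structure follows the study design: a shared marine
#' population of 6 families, 6 freshwater parental families, 6 F1 families
#' and 3 F2 families per cross, with roughly 100/30/30/60 fish per
#' population and category.
#'
#' @param n_crosses Number of marine x freshwater crosses (default 12).
#' @param n_traits Number of traits p (default 15; at least 2, since
#'   mismatch needs a perpendicular subspace).
#' @param divergence Vector of parental divergences, recycled to
#'   `n_crosses` (default evenly spaced 3 to 10 standardized units).
#' @param sigma_parent Within-family SD per trait in parents and F1
#'   (default 0.3 standardized units).
#' @param family_sd SD of the per-family trait intercepts (default 0.15).
#' @param h_perp Perpendicular dominance displacement of the F1 mean per
#'   unit divergence (default 0.16).
#' @param dominance_sd SD of the per-trait dominance coefficients around
#'   0.5 used to build the raw dominance vector (default 0.3).
#' @param f2_dominance_fraction Fraction of the F1 dominance displacement
#'   carried by the F2 mean (default 0.5).
#' @param n_effective_factors Castle-Wright effective factor number n_e
#'   controlling segregation variance (default 2.68, calibrated once so
#'   that the planted F2 variance-effect slope on divergence equals 0.12
#'   under the default design; `Inf` disables segregation variance).
#' @param marine_families,marine_family_size Shared marine population
#'   structure (default 6 x 17).
#' @param parent_families,parent_family_size Freshwater parental structure
#'   per cross (default 6 x 5).
#' @param f1_families,f1_family_size F1 structure per cross (default 6 x 5).
#' @param f2_families,f2_family_size F2 structure per cross (default 3 x 20).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_crosses = 12, n_traits = 15,
                              divergence = seq(3, 10, length.out = n_crosses),
                              sigma_parent = 0.3, family_sd = 0.15,
                              h_perp = 0.16, dominance_sd = 0.3,
                              f2_dominance_fraction = 0.5,
                              n_effective_factors = 2.68,
                              marine_families = 6, marine_family_size = 17,
                              parent_families = 6, parent_family_size = 5,
                              f1_families = 6, f1_family_size = 5,
                              f2_families = 3, f2_family_size = 20) {
  if (n_traits < 2) {
    stop("n_traits must be at least 2 (mismatch needs a perpendicular ",
         "subspace)", call. = FALSE)
  }
  divergence <- rep_len(divergence, n_crosses)
  if (any(divergence <= 0)) stop("divergence values must be > 0", call. = FALSE)
  if (sigma_parent < 0 || family_sd < 0 || h_perp < 0 || dominance_sd < 0) {
    stop("SDs and h_perp must be non-negative", call. = FALSE)
  }
  if (n_effective_factors <= 0) {
    stop("n_effective_factors must be positive (use Inf to disable ",
         "segregation variance)", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' @exportS3Method base::print
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$n_crosses, " crosses, ", x$n_traits,
      " traits, divergence ", round(min(x$divergence), 2), "-",
      round(max(x$divergence), 2), "\n", sep = "")
  cat("  sigma_parent=", x$sigma_parent, " family_sd=", x$family_sd,
      " h_perp=", x$h_perp, " n_e=", x$n_effective_factors, "\n", sep = "")
  invisible(x)
}

# deterministic child seed for cross `index` under master seed `seed`
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629) + 1L
}

.unit_vector <- function(p) {
  v <- rnorm(p)
  v / sqrt(sum(v^2))
}

# Dominance displacement of the F1 mean for one cross: per-trait dominance
# coefficients d_t ~ N(0.5, dominance_sd) generate a raw displacement
# (d_t - 0.5) * delta_t from the midparent; its component perpendicular to
# the parental axis is rescaled to norm h_perp * D (the along-axis
# component, which causes no mismatch, is kept as drawn).
.cross_effects <- function(config, D) {
  p <- config$n_traits
  u <- .unit_vector(p)
  delta_traits <- D * u
  d_t <- rnorm(p, mean = 0.5, sd = config$dominance_sd)
  raw <- (d_t - 0.5) * delta_traits
  par_comp <- sum(raw * u) * u
  perp <- raw - par_comp
  nperp <- sqrt(sum(perp^2))
  if (config$h_perp == 0) {
    perp <- perp * 0
  } else if (nperp < 1e-12) {
    w <- .unit_vector(p)
    w <- w - sum(w * u) * u
    perp <- w / sqrt(sum(w^2)) * config$h_perp * D
  } else {
    perp <- perp / nperp * config$h_perp * D
  }
  list(u = u, delta = par_comp + perp, dominance_coefficients = d_t)
}

# one block of families: mean + family intercept + individual noise
.gen_block <- function(mean_vec, sd_vec, config, n_fam, fam_size,
                       population, generation, cross_id, label) {
  p <- length(mean_vec)
  n <- n_fam * fam_size
  fam_idx <- rep(seq_len(n_fam), each = fam_size)
  intercepts <- matrix(rnorm(n_fam * p, sd = config$family_sd), n_fam, p)
  noise <- matrix(rnorm(n * p), n, p) %*% diag(sd_vec, p)
  values <- matrix(mean_vec, n, p, byrow = TRUE) +
    intercepts[fam_idx, , drop = FALSE] + noise
  meta <- data.frame(
    individual_id = sprintf("%s_i%03d", label, seq_len(n)),
    population = population,
    cross_id = cross_id,
    generation = generation,
    family_id = sprintf("%s_f%d", label, fam_idx),
    stringsAsFactors = FALSE
  )
  list(values = values, meta = meta)
}

#' Simulate one marine x freshwater cross
#'
#' Generates parental, F1 and F2 individuals for cross `index` of a
#' configuration, together with the generative ground truth.
#'
#' @param config A [simulation_config()].
#' @param index Cross index (1-based; selects `divergence[index]`).
#' @param seed Integer seed for this cross (derived from a master seed by
#'   [simulate_study()]).
#' @param include_marine Also generate this cross's own marine parental
#'   sample (set FALSE when a shared marine population is generated once
#'   at the study level).
#' @return List with `values` (matrix), `meta` (data frame) and `truth`
#'   (divergence, direction, dominance displacement, F2 segregation SDs).
#' @export
simulate_cross <- function(config, index, seed = NULL,
                           include_marine = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$n_traits
  D <- config$divergence[index]
  eff <- .cross_effects(config, D)
  pm_mean <- rep(0, p)
  pf_mean <- D * eff$u
  mid <- (pm_mean + pf_mean) / 2
  f1_mean <- mid + eff$delta
  f2_mean <- mid + config$f2_dominance_fraction * eff$delta
  seg_var <- (D * eff$u)^2 / (8 * config$n_effective_factors)
  if (!is.finite(config$n_effective_factors)) seg_var <- rep(0, p)
  f2_sd <- sqrt(config$sigma_parent^2 + seg_var)

  cr <- sprintf("cross%02d", index)
  fw <- sprintf("fw%02d", index)
  blocks <- list()
  if (include_marine) {
    blocks$pm <- .gen_block(pm_mean, rep(config$sigma_parent, p), config,
                            config$marine_families,
                            config$marine_family_size,
                            "marine", "PM", cr, paste0(cr, "_PM"))
  }
  blocks$pf <- .gen_block(pf_mean, rep(config$sigma_parent, p), config,
                          config$parent_families, config$parent_family_size,
                          fw, "PF", cr, paste0(cr, "_PF"))
  blocks$f1 <- .gen_block(f1_mean, rep(config$sigma_parent, p), config,
                          config$f1_families, config$f1_family_size,
                          fw, "F1", cr, paste0(cr, "_F1"))
  blocks$f2 <- .gen_block(f2_mean, f2_sd, config,
                          config$f2_families, config$f2_family_size,
                          fw, "F2", cr, paste0(cr, "_F2"))
  values <- do.call(rbind, lapply(blocks, `[[`, "values"))
  meta <- do.call(rbind, c(lapply(blocks, `[[`, "meta"),
                           list(make.row.names = FALSE)))
  truth <- list(
    cross_id = cr, divergence = D, direction = eff$u,
    dominance_displacement = eff$delta,
    dominance_coefficients = eff$dominance_coefficients,
    f1_mean = f1_mean, f2_mean = f2_mean, f2_sd = f2_sd,
    expected_f1_dominance_effect = config$h_perp * D,
    expected_f2_dominance_effect =
      config$f2_dominance_fraction * config$h_perp * D
  )
  list(values = values, meta = meta, truth = truth)
}

#' Simulate a full divergence-mismatch study
#'
#' Generates one shared marine population plus all crosses of the
#' configuration and returns the data as a wide `trait_table` (the same
#' schema [read_trait_table()] consumes) together with a versioned truth
#' record for parameter-recovery tests. Identical seeds give identical
#' tables.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed; per-cross child seeds are derived
#'   deterministically.
#' @param space `"standardized"` (default): trait values are emitted
#'   directly in the standardized space and the table is analysed with
#'   [as_standardized_traits()]. `"raw"`: values are mapped onto raw
#'   measurement scales (standard length, allometry, fixation categories,
#'   absent spines, count traits; requires the default 15-trait registry)
#'   to exercise the preprocessing stages.
#' @return List with `table` (a `trait_table`) and `truth` (list; element
#'   `crosses` holds the per-cross ground truth).
#' @export
simulate_study <- function(config = simulation_config(), seed = 1,
                           space = c("standardized", "raw")) {
  space <- match.arg(space)
  p <- config$n_traits
  traits <- if (p == 15) stickleback_traits()$trait
            else sprintf("trait_%02d", seq_len(p))
  set.seed(.child_seed(seed, 0))
  marine <- .gen_block(rep(0, p), rep(config$sigma_parent, p), config,
                       config$marine_families, config$marine_family_size,
                       "marine", "PM", NA_character_, "marine")
  values <- marine$values
  meta <- marine$meta
  truth_crosses <- vector("list", config$n_crosses)
  for (i in seq_len(config$n_crosses)) {
    cs <- simulate_cross(config, i, seed = .child_seed(seed, i),
                         include_marine = FALSE)
    values <- rbind(values, cs$values)
    meta <- rbind(meta, cs$meta)
    truth_crosses[[i]] <- cs$truth
  }
  colnames(values) <- traits
  table <- cbind(
    meta,
    data.frame(standard_length = 40, fixation_score = 0L,
               swim_bladder_ok = TRUE, second_dorsal_spine_present = TRUE),
    as.data.frame(values)
  )
  rownames(table) <- NULL
  truth <- list(version = 1L, seed = seed, space = space,
                config = unclass(config), crosses = truth_crosses)
  if (space == "raw") {
    if (p != 15) {
      stop("raw-space simulation requires the default 15-trait registry",
           call. = FALSE)
    }
    table <- .to_raw_space(table, traits, seed)
  }
  table <- structure(table, class = c("trait_table", "data.frame"),
                     trait_names = traits)
  list(table = table, truth = truth)
}

# Map standardized-space simulated values onto raw measurement scales so
# the preprocessing stages have something realistic to undo: lognormal
# standard length with per-trait allometric slopes, multiplicative
# fixation-position effects on the affected traits, occasional absent
# spines/girdle recorded as 0, integer count traits, and a few flagged
# fish for the exclusion rules.
.to_raw_space <- function(table, traits, seed) {
  set.seed(.child_seed(seed, 10007))
  reg <- stickleback_traits()
  n <- nrow(table)
  sl <- exp(rnorm(n, log(40), 0.08))
  table$standard_length <- sl
  table$fixation_score <- sample(0:2, n, replace = TRUE,
                                 prob = c(0.6, 0.3, 0.1))
  fix_eff <- c(0.06, 0, -0.06)
  base_mm <- c(snout_length = 4, head_length = 12, gape_width = 3,
               body_depth = 10, body_width = 5, first_dorsal_spine = 4,
               second_dorsal_spine = 4.5, pelvic_spine = 6,
               pelvic_girdle = 8, pectoral_fin = 9, gill_raker_length = 1)
  base_count <- c(plate_count = 20, dorsal_fin_rays = 12, anal_fin_rays = 9,
                  gill_raker_count = 20)
  for (tr in traits) {
    i <- match(tr, reg$trait)
    z <- table[[tr]]
    if (reg$kind[i] == "linear") {
      slope <- runif(1, 0.9, 1.4)
      val <- log(base_mm[[tr]]) - slope * log(40) + slope * log(sl) + 0.05 * z
      if (reg$fixation_affected[i]) {
        val <- val + fix_eff[table$fixation_score + 1L]
      }
      table[[tr]] <- exp(val)
    } else {
      table[[tr]] <- pmax(0L, as.integer(round(base_count[[tr]] + 1.5 * z)))
    }
  }
  # absent structures in the most derived freshwater populations
  for (tr in c("first_dorsal_spine", "pelvic_spine", "pelvic_girdle")) {
    derived <- table$generation %in% c("PF", "F2") &
      !is.na(table$cross_id) &
      table$cross_id %in% sprintf("cross%02d", 9:12)
    absent <- derived & stats::runif(n) < 0.05
    table[[tr]][absent] <- 0
  }
  flag <- sample(which(table$generation == "F2"), 4)
  table$second_dorsal_spine_present[flag[1:3]] <- FALSE
  table$swim_bladder_ok[flag[4]] <- FALSE
  table
}

#' Write a simulation truth record as JSON
#'
#' @param truth Truth record from [simulate_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Expected dominance effects under the generative model
#'
#' Monte-Carlo expectation of the *estimated* dominance effect (the
#' mismatch of the estimated mean hybrid phenotype relative to the
#' estimated parental axis) for each cross and hybrid generation. The
#' estimated population means of a balanced design are Gaussian around the
#' true means with per-trait variance `(family_sd^2 + sigma^2 / n) / K`
#' for `K` families of `n` fish, so the expectation can be computed by
#' sampling mean vectors directly, without simulating individuals. This is
#' the unbiased comparator for parameter-recovery tests: the estimated
#' dominance effect is a norm and therefore biased upward relative to the
#' planted `h_perp * divergence` at finite sample size.
#'
#' @param config A [simulation_config()].
#' @param n_draws Monte-Carlo draws per cross (default 4000).
#' @param seed Seed for the oracle draws.
#' @return Data frame: `cross_id`, `divergence`, `generation`,
#'   `expected_dominance_effect`.
#' @export
expected_dominance_effects <- function(config, n_draws = 4000, seed = 1) {
  set.seed(seed)
  p <- config$n_traits
  mean_se <- function(sd_vec, K, n) sqrt((config$family_sd^2 + sd_vec^2 / n) / K)
  se_pm <- mean_se(rep(config$sigma_parent, p), config$marine_families,
                   config$marine_family_size)
  se_pf <- mean_se(rep(config$sigma_parent, p), config$parent_families,
                   config$parent_family_size)
  se_f1 <- mean_se(rep(config$sigma_parent, p), config$f1_families,
                   config$f1_family_size)
  out <- list()
  for (i in seq_len(config$n_crosses)) {
    D <- config$divergence[i]
    dom <- matrix(0, n_draws, 2)
    for (s in seq_len(n_draws)) {
      eff <- .cross_effects(config, D)
      pf_mean <- D * eff$u
      mid <- pf_mean / 2
      seg <- (D * eff$u)^2 / (8 * config$n_effective_factors)
      if (!is.finite(config$n_effective_factors)) seg <- rep(0, p)
      se_f2 <- mean_se(sqrt(config$sigma_parent^2 + seg),
                       config$f2_families, config$f2_family_size)
      pm_hat <- rnorm(p, 0, se_pm)
      pf_hat <- pf_mean + rnorm(p, 0, se_pf)
      f1_hat <- mid + eff$delta + rnorm(p, 0, se_f1)
      f2_hat <- mid + config$f2_dominance_fraction * eff$delta +
        rnorm(p, 0, se_f2)
      dom[s, 1] <- mismatch(f1_hat, pm_hat, pf_hat)
      dom[s, 2] <- mismatch(f2_hat, pm_hat, pf_hat)
    }
    out[[i]] <- data.frame(
      cross_id = sprintf("cross%02d", i), divergence = D,
      generation = c("F1", "F2"),
      expected_dominance_effect = colMeans(dom),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Expected dominance-effect slope on divergence
#'
#' Least-squares slope of the expected estimated dominance effect (from
#' [expected_dominance_effects()]) on divergence, per generation.
#'
#' @inheritParams expected_dominance_effects
#' @return Named numeric vector with entries `F1` and `F2`.
#' @export
expected_dominance_slope <- function(config, n_draws = 4000, seed = 1) {
  ed <- expected_dominance_effects(config, n_draws = n_draws, seed = seed)
  vapply(c(F1 = "F1", F2 = "F2"), function(g) {
    d <- ed[ed$generation == g, ]
    unname(coef(lm(expected_dominance_effect ~ divergence, data = d))[2])
  }, numeric(1))
}
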