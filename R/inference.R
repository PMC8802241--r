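# Shared fitting engine for the divergence regressions.
#
# `data` must hold columns value, divergence, generation (factor or
# character with levels F1/F2) and cross_id (one freshwater population per
# cross, used as the random-intercept grouping). Mixed models are fit with
# lmerTest (Satterthwaite denominator df); on failure the engine downgrades
# to ordinary least squares, which is also the exact limit of the mixed
# model when the population variance component is zero.
.fit_mixed_regression <- function(data, alpha = 0.05,
                                  engine = c("lmer", "lm"),
                                  interaction = TRUE,
                                  per_generation = TRUE) {
  engine <- match.arg(engine)
  data$generation <- factor(data$generation, levels = c("F1", "F2"))
  two_gen <- nlevels(droplevels(data$generation)) == 2L
  if (length(unique(data$cross_id)) < 3L) {
    stop("rank error: need at least 3 crosses", call. = FALSE)
  }

  fit_lmer <- function(formula) {
    tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(formula, data = data)
      )),
      error = function(e) NULL
    )
  }
  coef_row <- function(fit, term) {
    if (inherits(fit, "lmerModLmerTest")) {
      cf <- coef(summary(fit))
      c(est = cf[term, "Estimate"], se = cf[term, "Std. Error"],
        df = cf[term, "df"], stat = cf[term, "t value"],
        p = cf[term, "Pr(>|t|)"])
    } else {
      cf <- coef(summary(fit))
      c(est = cf[term, "Estimate"], se = cf[term, "Std. Error"],
        df = fit$df.residual, stat = cf[term, "t value"],
        p = cf[term, "Pr(>|t|)"])
    }
  }
  fit_model <- function(fixed) {
    fit <- NULL
    used <- "lm"
    if (engine == "lmer") {
      fit <- fit_lmer(stats::as.formula(paste(fixed, "+ (1 | cross_id)")))
      if (!is.null(fit)) used <- "lmm"
    }
    if (is.null(fit)) fit <- lm(stats::as.formula(fixed), data = data)
    list(fit = fit, used = used)
  }

  out <- list(alpha = alpha)

  if (interaction && two_gen) {
    m <- fit_model("value ~ divergence * generation")
    term <- "divergence:generationF2"
    out$interaction <- as.list(coef_row(m$fit, term))
    out$engine <- m$used
  }

  pooled_fixed <- if (two_gen) "value ~ divergence + generation"
                  else "value ~ divergence"
  m <- fit_model(pooled_fixed)
  row <- coef_row(m$fit, "divergence")
  ci <- row[["est"]] + c(-1, 1) * qt(1 - alpha / 2, row[["df"]]) * row[["se"]]
  out$pooled <- list(slope = row[["est"]], se = row[["se"]], df = row[["df"]],
                     ci_lower = ci[1], ci_upper = ci[2], p = row[["p"]])
  out$engine <- m$used

  if (per_generation) {
    gens <- levels(droplevels(data$generation))
    if (two_gen) {
      m <- fit_model("value ~ 0 + generation + divergence:generation")
      pg <- do.call(rbind, lapply(gens, function(g) {
        row <- coef_row(m$fit, paste0("generation", g, ":divergence"))
        ci <- row[["est"]] +
          c(-1, 1) * qt(1 - alpha / 2, row[["df"]]) * row[["se"]]
        data.frame(generation = g, slope = row[["est"]], se = row[["se"]],
                   df = row[["df"]], ci_lower = ci[1], ci_upper = ci[2],
                   p = row[["p"]], stringsAsFactors = FALSE)
      }))
    } else {
      row <- coef_row(m$fit, "divergence")
      ci <- row[["est"]] +
        c(-1, 1) * qt(1 - alpha / 2, row[["df"]]) * row[["se"]]
      pg <- data.frame(generation = gens, slope = row[["est"]],
                       se = row[["se"]], df = row[["df"]],
                       ci_lower = ci[1], ci_upper = ci[2], p = row[["p"]],
                       stringsAsFactors = FALSE)
    }
    out$per_generation <- pg
  }
  out
}

#' Divergence-mismatch regression
#'
#' Tests whether mean hybrid mismatch increases with the magnitude of
#' parental phenotypic divergence. One mean-mismatch value per cross and
#' hybrid generation is analysed (population is the replicate) with
#' divergence, hybrid generation and their interaction as predictors and a
#' random intercept for the freshwater population. When the interaction is
#' not significant the pooled (common) slope from the additive model is the
#' headline estimate.
#'
#' @param decomposition Output of [mismatch_decomposition()] (needs
#'   `cross_id`, `generation`, `mean_mismatch`).
#' @param divergence Output of [cross_divergence()] (needs `cross_id`,
#'   `divergence`).
#' @param alpha Significance level for CIs and the interaction test.
#' @param engine `"lmer"` (mixed model, default) or `"lm"`.
#' @param interaction,per_generation Logical; compute the interaction test
#'   and the per-generation slopes (disable for speed in simulation loops).
#' @return An object of class `mismatch_regression`: a list with elements
#'   `pooled` (slope, SE, df, CI, p), `interaction`, `per_generation` (data
#'   frame), `engine`, `response` and `data`.
#' @export
fit_divergence_mismatch <- function(decomposition, divergence, alpha = 0.05,
                                    engine = c("lmer", "lm"),
                                    interaction = TRUE,
                                    per_generation = TRUE) {
  engine <- match.arg(engine)
  data <- merge(decomposition[, c("cross_id", "generation", "mean_mismatch")],
                divergence[, c("cross_id", "divergence")], by = "cross_id")
  names(data)[names(data) == "mean_mismatch"] <- "value"
  out <- .fit_mixed_regression(data, alpha = alpha, engine = engine,
                               interaction = interaction,
                               per_generation = per_generation)
  out$response <- "mean_mismatch"
  out$data <- data
  class(out) <- "mismatch_regression"
  out
}

#' Mechanism regressions: dominance and variance effects on divergence
#'
#' Fits the same model form as [fit_divergence_mismatch()] with the
#' dominance effect and the variance effect as responses, giving
#' per-generation slopes with confidence intervals and the divergence x
#' generation interaction test. Dominance is expected to drive the
#' divergence-mismatch relationship in F1 hybrids, segregation variance in
#' F2 hybrids.
#'
#' @inheritParams fit_divergence_mismatch
#' @return Named list of two `mismatch_regression` objects: `dominance`
#'   and `variance`.
#' @export
fit_effect_regressions <- function(decomposition, divergence, alpha = 0.05,
                                   engine = c("lmer", "lm"),
                                   interaction = TRUE,
                                   per_generation = TRUE) {
  engine <- match.arg(engine)
  one <- function(col) {
    data <- merge(decomposition[, c("cross_id", "generation", col)],
                  divergence[, c("cross_id", "divergence")], by = "cross_id")
    names(data)[names(data) == col] <- "value"
    out <- .fit_mixed_regression(data, alpha = alpha, engine = engine,
                                 interaction = interaction,
                                 per_generation = per_generation)
    out$response <- col
    out$data <- data
    class(out) <- "mismatch_regression"
    out
  }
  list(dominance = one("dominance_effect"), variance = one("variance_effect"))
}

#' @exportS3Method base::print
print.mismatch_regression <- function(x, ...) {
  cat("<mismatch_regression> response:", x$response,
      " engine:", x$engine, "\n")
  cat(sprintf("  pooled slope: %.4f (SE %.4f, 95%% CI [%.4f, %.4f], p = %.3g)\n",
              x$pooled$slope, x$pooled$se, x$pooled$ci_lower,
              x$pooled$ci_upper, x$pooled$p))
  if (!is.null(x$interaction)) {
    cat(sprintf("  divergence x generation interaction: p = %.3g\n",
                x$interaction$p))
  }
  if (!is.null(x$per_generation)) {
    for (i in seq_len(nrow(x$per_generation))) {
      r <- x$per_generation[i, ]
      cat(sprintf("  %s slope: %.4f [%.4f, %.4f]\n", r$generation, r$slope,
                  r$ci_lower, r$ci_upper))
    }
  }
  invisible(x)
}

#' Count significantly mismatched trait pairs per cross
#'
#' For every pair of traits and every hybrid generation of a cross, the
#' hybrids' pairwise mismatch values are compared against the parental
#' individuals' pairwise mismatch for the same trait pair (the baseline
#' produced by within-population variation) with a one-sided Welch t-test;
#' the pair counts as mismatched when hybrids exceed the baseline at level
#' `alpha` (uncorrected).
#'
#' @param x A [standardized_traits()] object.
#' @param alpha Significance level.
#' @param generations Hybrid generations to score.
#' @return Data frame: `cross_id`, `generation`, `n_pairs`,
#'   `n_significant`.
#' @export
snowball_counts <- function(x, alpha = 0.05, generations = c("F1", "F2")) {
  traits <- colnames(x$values)
  pairs <- utils::combn(traits, 2)
  out <- list()
  for (cr in cross_ids(x)) {
    cp <- cross_parent_means(x, cr)
    pr <- .parent_rows(x, cr)
    par_rows <- c(pr$pm, pr$pf)
    hyb_rows <- lapply(generations, function(g) .hybrid_rows(x, cr, g))
    names(hyb_rows) <- generations
    n_sig <- setNames(integer(length(generations)), generations)
    for (k in seq_len(ncol(pairs))) {
      keep <- pairs[, k]
      pm2 <- cp$pm[keep]; pf2 <- cp$pf[keep]
      base <- suppressWarnings(
        mismatch(x$values[par_rows, keep, drop = FALSE], pm2, pf2))
      for (g in generations) {
        rows <- hyb_rows[[g]]
        if (length(rows) < 2L) next
        hyb <- suppressWarnings(
          mismatch(x$values[rows, keep, drop = FALSE], pm2, pf2))
        p <- tryCatch(t.test(hyb, base, alternative = "greater")$p.value,
                      error = function(e) NA_real_)
        # excess below numerical noise never counts as mismatch
        if (!is.na(p) && p < alpha && mean(hyb) - mean(base) > 1e-8) {
          n_sig[g] <- n_sig[g] + 1L
        }
      }
    }
    out[[cr]] <- data.frame(cross_id = cr, generation = generations,
                            n_pairs = ncol(pairs),
                            n_significant = as.integer(n_sig),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Linear versus quadratic growth of mismatched-pair counts
#'
#' Fits, per hybrid generation, `count ~ divergence` and
#' `count ~ divergence + divergence^2` on the identity scale and reports
#' whether the quadratic term improves the fit (its added-term p-value).
#' A quadratic increase is the phenotypic analogue of the snowball
#' accumulation of pairwise incompatibilities.
#'
#' @param counts Output of [snowball_counts()].
#' @param divergence Output of [cross_divergence()].
#' @return Data frame with one row per generation: linear slope and
#'   p-value, quadratic coefficient and p-value.
#' @export
snowball_fit <- function(counts, divergence) {
  data <- merge(counts, divergence[, c("cross_id", "divergence")],
                by = "cross_id")
  out <- lapply(split(data, data$generation), function(d) {
    lin <- lm(n_significant ~ divergence, data = d)
    quad <- lm(n_significant ~ divergence + I(divergence^2), data = d)
    cl <- coef(summary(lin)); cq <- coef(summary(quad))
    data.frame(
      generation = d$generation[1],
      slope_linear = cl["divergence", "Estimate"],
      p_linear = cl["divergence", "Pr(>|t|)"],
      coef_quadratic = cq["I(divergence^2)", "Estimate"],
      p_quadratic = cq["I(divergence^2)", "Pr(>|t|)"],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Snowball analysis of mismatched trait pairs
#'
#' Convenience wrapper: [snowball_counts()] followed by [snowball_fit()].
#'
#' @inheritParams snowball_counts
#' @param divergence Optional [cross_divergence()] table (computed from `x`
#'   when omitted).
#' @return List with `counts` and `fits`.
#' @export
snowball <- function(x, alpha = 0.05, generations = c("F1", "F2"),
                     divergence = NULL) {
  if (is.null(divergence)) divergence <- cross_divergence(x)
  counts <- snowball_counts(x, alpha = alpha, generations = generations)
  list(counts = counts, fits = snowball_fit(counts, divergence),
       alpha = alpha)
}

#' Correlations between trait pairs in F2 hybrids
#'
#' Pearson correlations between all trait pairs among F2 individuals,
#' computed within each cross (so that between-cross mean differences do
#' not inflate the correlations) and pooled across crosses. Low, mostly
#' non-significant correlations justify analysing the traits in the
#' original space rather than reducing dimensions.
#'
#' @param x A [standardized_traits()] object.
#' @param generation Generation to summarize (default `"F2"`).
#' @param alpha Significance level.
#' @param pooled Pool individuals across crosses instead of computing
#'   within-cross correlations (default FALSE).
#' @return List with `median_abs_r`, `pct_significant` (percent of pairs
#'   with p < `alpha`), `n_pairs` and the per-pair table.
#' @export
f2_correlation_summary <- function(x, generation = "F2", alpha = 0.05,
                                   pooled = FALSE) {
  meta <- x$meta
  groups <- if (pooled) {
    list(all = which(meta$generation == generation))
  } else {
    ids <- cross_ids(x)
    setNames(lapply(ids, function(cr) .hybrid_rows(x, cr, generation)), ids)
  }
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    n <- length(rows)
    if (n < 4L) next
    R <- cor(x$values[rows, , drop = FALSE])
    ut <- upper.tri(R)
    r <- R[ut]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    idx <- which(ut, arr.ind = TRUE)
    out[[g]] <- data.frame(
      group = g,
      trait_i = colnames(R)[idx[, "col"]],
      trait_j = rownames(R)[idx[, "row"]],
      r = r, p = p, n = n, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  list(median_abs_r = median(abs(tab$r)),
       pct_significant = 100 * mean(tab$p < alpha),
       n_pairs = nrow(tab), pairs = tab)
}
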