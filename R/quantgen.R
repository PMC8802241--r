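#' Test whether the parent populations differ for a trait
#'
#' Welch two-sample t-test on standardized trait values between the marine
#' and freshwater parent individuals of a cross. Dominance coefficients are
#' only interpretable for traits where the parents are statistically
#' distinguishable.
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param trait Trait name.
#' @param alpha Significance level (default 0.05).
#' @param on `"individuals"` (default) or `"family_means"`: the unit on
#'   which the test is run.
#' @return List with `differ` (logical, NA when undefined), `p`,
#'   `n_pm`, `n_pf`.
#' @export
parents_differ <- function(x, cross_id, trait, alpha = 0.05,
                           on = c("individuals", "family_means")) {
  on <- match.arg(on)
  rows <- .parent_rows(x, cross_id)
  get_vals <- function(idx) {
    v <- x$values[idx, trait]
    if (on == "family_means") {
      fam <- as.character(x$meta$family_id[idx])
      as.numeric(rowsum(v, fam) / as.vector(rowsum(rep(1, length(fam)), fam)))
    } else {
      as.numeric(v)
    }
  }
  a <- get_vals(rows$pm)
  b <- get_vals(rows$pf)
  if (length(a) < 2L || length(b) < 2L) {
    warning("fewer than 2 observations in a parent group; trait `", trait,
            "` skipped", call. = FALSE)
    return(list(differ = NA, p = NA_real_, n_pm = length(a), n_pf = length(b)))
  }
  tt <- t.test(a, b)
  list(differ = tt$p.value < alpha, p = tt$p.value,
       n_pm = length(a), n_pf = length(b))
}

#' Per-trait additive/dominance line-cross model
#'
#' Fits, for one trait in one cross, a linear mixed model of standardized
#' trait values on (i) an additive index, the fraction of the genome that
#' is freshwater (PM = 0, F1 = F2 = 0.5, PF = 1), and (ii) a dominance
#' deviation, the expected fraction of the genome heterozygous (PM = PF =
#' 0, F1 = 1, F2 = 0.5), with a random intercept per family. The p-value
#' for the dominance deviation uses the Satterthwaite approximation to the
#' denominator degrees of freedom (`method = "satterthwaite"`) or a
#' likelihood-ratio test (`method = "lrt"`). When the mixed fit fails
#' (e.g. a single family), the model is downgraded to ordinary least
#' squares and flagged in the `model` column.
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param trait Trait name.
#' @param method `"satterthwaite"` (default) or `"lrt"` for the dominance
#'   p-value.
#' @return One-row data frame: `cross_id`, `trait`, `beta_additive`,
#'   `beta_dominance`, `se_dominance`, `p_dominance`, `model`.
#' @export
fit_additive_dominance <- function(x, cross_id, trait,
                                   method = c("satterthwaite", "lrt")) {
  method <- match.arg(method)
  pr <- .parent_rows(x, cross_id)
  rows <- c(pr$pm, pr$pf, .hybrid_rows(x, cross_id, "F1"),
            .hybrid_rows(x, cross_id, "F2"))
  gen <- x$meta$generation[rows]
  if (!all(GENERATIONS %in% gen)) {
    stop("all four generation categories (PM, PF, F1, F2) are required for ",
         "cross `", cross_id, "`", call. = FALSE)
  }
  df <- data.frame(
    value = as.numeric(x$values[rows, trait]),
    additive = c(PM = 0, PF = 1, F1 = 0.5, F2 = 0.5)[gen],
    het = c(PM = 0, PF = 0, F1 = 1, F2 = 0.5)[gen],
    family = as.character(x$meta$family_id[rows]),
    stringsAsFactors = FALSE
  )
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ additive + het + (1 | family), data = df)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(summary(fit))
    p_dom <- if (method == "lrt") {
      full <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ additive + het + (1 | family), data = df,
                   REML = FALSE)))
      red <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ additive + (1 | family), data = df, REML = FALSE)))
      anova(red, full)[2, "Pr(>Chisq)"]
    } else {
      cf["het", "Pr(>|t|)"]
    }
    data.frame(cross_id = cross_id, trait = trait,
               beta_additive = cf["additive", "Estimate"],
               beta_dominance = cf["het", "Estimate"],
               se_dominance = cf["het", "Std. Error"],
               p_dominance = p_dom,
               model = "lmm", stringsAsFactors = FALSE)
  } else {
    ols <- lm(value ~ additive + het, data = df)
    cf <- coef(summary(ols))
    data.frame(cross_id = cross_id, trait = trait,
               beta_additive = cf["additive", "Estimate"],
               beta_dominance = cf["het", "Estimate"],
               se_dominance = cf["het", "Std. Error"],
               p_dominance = cf["het", "Pr(>|t|)"],
               model = "ols", stringsAsFactors = FALSE)
  }
}

#' Dominance coefficient of a hybrid generation for one trait
#'
#' Position of the mean hybrid phenotype on the trait axis rescaled so that
#' the marine parental mean is 0 and the freshwater parental mean is 1.
#' Values below 0 or above 1 are transgressive. Population means use the
#' unweighted family-mean convention. Not computed (NA) when the parents
#' are not statistically distinguishable for the trait.
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param generation `"F1"` or `"F2"`.
#' @param trait Trait name.
#' @param alpha Significance level for the parent-difference screen.
#' @param screen Apply the parent-difference screen (default TRUE).
#' @return Scalar dominance coefficient, or NA when screened out.
#' @export
dominance_coefficient <- function(x, cross_id, generation, trait,
                                  alpha = 0.05, screen = TRUE) {
  if (screen) {
    pd <- parents_differ(x, cross_id, trait, alpha = alpha)
    if (!isTRUE(pd$differ)) return(NA_real_)
  }
  cp <- cross_parent_means(x, cross_id)
  rows <- .hybrid_rows(x, cross_id, generation)
  if (!length(rows)) {
    stop("no ", generation, " rows for cross `", cross_id, "`", call. = FALSE)
  }
  hmean <- population_mean(x, rows = rows)
  (hmean[[trait]] - cp$pm[[trait]]) / (cp$pf[[trait]] - cp$pm[[trait]])
}

#' Within-family trait variance, averaged across families
#'
#' Sample variance of each trait within each family of a generation, then
#' the unweighted mean across families. Families with a single individual
#' carry no variance information and are skipped with a warning.
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param generation Generation label.
#' @return Data frame with one row per trait: `cross_id`, `generation`,
#'   `trait`, `variance`, `n_families`.
#' @export
family_trait_variance <- function(x, cross_id, generation) {
  rows <- if (generation %in% c("F1", "F2")) {
    .hybrid_rows(x, cross_id, generation)
  } else {
    pr <- .parent_rows(x, cross_id)
    if (generation == "PM") pr$pm else pr$pf
  }
  if (!length(rows)) {
    stop("no ", generation, " rows for cross `", cross_id, "`", call. = FALSE)
  }
  fam <- as.character(x$meta$family_id[rows])
  sizes <- table(fam)
  keep_fams <- names(sizes)[sizes >= 2]
  if (length(keep_fams) < length(sizes)) {
    warning(length(sizes) - length(keep_fams),
            " famil(ies) of size 1 skipped", call. = FALSE)
  }
  if (!length(keep_fams)) {
    stop("no family with at least 2 individuals", call. = FALSE)
  }
  v <- x$values[rows, , drop = FALSE]
  per_fam <- vapply(keep_fams, function(f) {
    apply(v[fam == f, , drop = FALSE], 2, var)
  }, numeric(ncol(v)))
  if (is.null(dim(per_fam))) per_fam <- matrix(per_fam, nrow = ncol(v))
  data.frame(
    cross_id = cross_id, generation = generation,
    trait = colnames(v),
    variance = rowMeans(per_fam),
    n_families = length(keep_fams),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Dominance summary for every cross and trait
#'
#' Runs the parent-difference screen, the additive/dominance mixed model
#' and the F1/F2 dominance coefficients for all crosses and traits.
#'
#' @param x A [standardized_traits()] object.
#' @param alpha Significance level for the parent-difference screen.
#' @param method Dominance p-value method; see [fit_additive_dominance()].
#' @return Data frame with one row per cross x trait: test results, model
#'   coefficients and dominance coefficients (`d_f1`, `d_f2`; NA when the
#'   parents do not differ).
#' @export
dominance_table <- function(x, alpha = 0.05,
                            method = c("satterthwaite", "lrt")) {
  method <- match.arg(method)
  out <- list()
  for (cr in cross_ids(x)) {
    cp <- cross_parent_means(x, cr)
    f1_rows <- .hybrid_rows(x, cr, "F1")
    f2_rows <- .hybrid_rows(x, cr, "F2")
    f1_mean <- if (length(f1_rows)) population_mean(x, rows = f1_rows)
    f2_mean <- if (length(f2_rows)) population_mean(x, rows = f2_rows)
    for (tr in colnames(x$values)) {
      pd <- parents_differ(x, cr, tr, alpha = alpha)
      fit <- fit_additive_dominance(x, cr, tr, method = method)
      dcoef <- function(hmean) {
        if (is.null(hmean) || !isTRUE(pd$differ)) return(NA_real_)
        (hmean[[tr]] - cp$pm[[tr]]) / (cp$pf[[tr]] - cp$pm[[tr]])
      }
      fit$parents_differ <- isTRUE(pd$differ)
      fit$p_parents <- pd$p
      fit$d_f1 <- dcoef(f1_mean)
      fit$d_f2 <- dcoef(f2_mean)
      out[[paste(cr, tr)]] <- fit
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
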