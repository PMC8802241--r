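#' Run the full divergence-mismatch analysis
#'
#' Orchestrates the stages end to end: (optional) simulation or reading of
#' a trait table, preprocessing (raw space only), per-cross divergence,
#' mismatch decomposition, parental baselines, the divergence-mismatch and
#' mechanism regressions, the per-trait dominance table, family-wise trait
#' variances, the F2 trait-correlation summary and the snowball analysis.
#' All stage outputs can be written as plain CSV plus a JSON run report.
#'
#' @param table A `trait_table`, a path to one, or NULL when `sim_config`
#'   is given.
#' @param sim_config Optional [simulation_config()]; when given, data are
#'   simulated with [simulate_study()] under `seed`.
#' @param seed Master seed for simulation (required with `sim_config`).
#' @param space `"standardized"` when the trait columns are already in
#'   standardized units (simulated data), `"raw"` to run the full
#'   preprocessing chain first.
#' @param trait_cfg A [trait_config()] for reading/preprocessing raw data.
#' @param averaging Decomposition averaging convention; see
#'   [decompose_mismatch()].
#' @param alpha Significance level used throughout.
#' @param do_dominance,do_snowball Toggle the per-trait dominance table and
#'   the snowball analysis (the two slowest stages).
#' @param out_dir Optional output directory for stage CSVs and
#'   `report.json`.
#' @param engine Regression engine; see [fit_divergence_mismatch()].
#' @return An object of class `mismatch_report`: a list with the stage
#'   tables and fitted regressions.
#' @export
run_pipeline <- function(table = NULL, sim_config = NULL, seed = NULL,
                         space = c("standardized", "raw"),
                         trait_cfg = trait_config(),
                         averaging = c("family", "individual"),
                         alpha = 0.05, do_dominance = TRUE,
                         do_snowball = TRUE, out_dir = NULL,
                         engine = c("lmer", "lm")) {
  space <- match.arg(space)
  averaging <- match.arg(averaging)
  engine <- match.arg(engine)
  truth <- NULL
  t0 <- Sys.time()

  if (!is.null(sim_config)) {
    if (is.null(seed)) stop("`seed` is required with `sim_config`",
                            call. = FALSE)
    sim <- simulate_study(sim_config, seed = seed, space = space)
    table <- sim$table
    truth <- sim$truth
  } else if (is.character(table)) {
    if (!file.exists(table)) stop("file not found: ", table, call. = FALSE)
    sep <- if (grepl("\\.tsv$|\\.txt$", table)) "\t" else ","
    table <- validate_trait_table(
      read.csv(table, sep = sep, stringsAsFactors = FALSE),
      trait_cfg, raw = (space == "raw")
    )
  } else if (is.null(table)) {
    stop("give `table` or `sim_config`", call. = FALSE)
  }

  std <- if (space == "raw") {
    preprocess(table, trait_cfg)
  } else {
    as_standardized_traits(table)
  }

  div <- cross_divergence(std)
  decomp <- mismatch_decomposition(std, averaging = averaging)
  pdev <- do.call(rbind, c(lapply(cross_ids(std), function(cr) {
    parent_deviation(std, cr)
  }), list(make.row.names = FALSE)))
  ind_mm <- individual_mismatch(std)

  reg_mismatch <- fit_divergence_mismatch(decomp, div, alpha = alpha,
                                          engine = engine)
  reg_effects <- fit_effect_regressions(decomp, div, alpha = alpha,
                                        engine = engine)

  fam_var <- do.call(rbind, c(unlist(lapply(cross_ids(std), function(cr) {
    lapply(c("F1", "F2"), function(g) {
      suppressWarnings(family_trait_variance(std, cr, g))
    })
  }), recursive = FALSE), list(make.row.names = FALSE)))

  cor_sum <- f2_correlation_summary(std, alpha = alpha)
  dom_tbl <- if (do_dominance) {
    suppressWarnings(dominance_table(std, alpha = alpha))
  }
  snow <- if (do_snowball) snowball(std, alpha = alpha, divergence = div)

  report <- structure(list(
    seed = seed, alpha = alpha, averaging = averaging, space = space,
    n_individuals = nrow(std$values), n_traits = ncol(std$values),
    divergence = div, decomposition = decomp, parent_deviation = pdev,
    individual_mismatch = ind_mm,
    regression_mismatch = reg_mismatch, regression_effects = reg_effects,
    family_variance = fam_var, f2_correlations = cor_sum,
    dominance = dom_tbl, snowball = snow, truth = truth,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "mismatch_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @exportS3Method base::print
print.mismatch_report <- function(x, ...) {
  cat("<mismatch_report> ", nrow(x$divergence), " crosses, ",
      x$n_individuals, " individuals, ", x$n_traits, " traits\n", sep = "")
  cat(sprintf("  divergence range: %.2f - %.2f\n",
              min(x$divergence$divergence), max(x$divergence$divergence)))
  cat(sprintf("  divergence-mismatch pooled slope: %.4f [%.4f, %.4f]\n",
              x$regression_mismatch$pooled$slope,
              x$regression_mismatch$pooled$ci_lower,
              x$regression_mismatch$pooled$ci_upper))
  pg <- x$regression_effects$dominance$per_generation
  cat(sprintf("  dominance-effect slopes: F1 %.4f, F2 %.4f\n",
              pg$slope[pg$generation == "F1"],
              pg$slope[pg$generation == "F2"]))
  pg <- x$regression_effects$variance$per_generation
  cat(sprintf("  variance-effect slopes:  F1 %.4f, F2 %.4f\n",
              pg$slope[pg$generation == "F1"],
              pg$slope[pg$generation == "F2"]))
  invisible(x)
}

# regression object -> flat rows for the JSON/CSV report
.regression_summary <- function(reg) {
  rows <- data.frame(
    term = "pooled", generation = NA_character_,
    estimate = reg$pooled$slope, se = reg$pooled$se, df = reg$pooled$df,
    ci_lower = reg$pooled$ci_lower, ci_upper = reg$pooled$ci_upper,
    p = reg$pooled$p, stringsAsFactors = FALSE
  )
  if (!is.null(reg$interaction)) {
    rows <- rbind(rows, data.frame(
      term = "interaction", generation = NA_character_,
      estimate = reg$interaction$est, se = reg$interaction$se,
      df = reg$interaction$df, ci_lower = NA_real_, ci_upper = NA_real_,
      p = reg$interaction$p, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(reg$per_generation)) {
    pg <- reg$per_generation
    rows <- rbind(rows, data.frame(
      term = "per_generation", generation = pg$generation,
      estimate = pg$slope, se = pg$se, df = pg$df,
      ci_lower = pg$ci_lower, ci_upper = pg$ci_upper, p = pg$p,
      stringsAsFactors = FALSE
    ))
  }
  rows$response <- reg$response
  rows$engine <- reg$engine
  rows
}

#' Write a run report to disk
#'
#' Writes every stage table as CSV plus a `report.json` aggregating the
#' regression results, correlation summary and snowball fits.
#'
#' @param report A `mismatch_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                row.names = FALSE)
    }
  }
  wr(report$divergence, "divergence")
  wr(report$decomposition, "decomposition")
  wr(report$parent_deviation, "parent_deviation")
  wr(report$individual_mismatch, "individual_mismatch")
  wr(report$family_variance, "family_variance")
  wr(report$dominance, "dominance")
  wr(report$f2_correlations$pairs, "f2_correlations")
  if (!is.null(report$snowball)) {
    wr(report$snowball$counts, "snowball_counts")
    wr(report$snowball$fits, "snowball_fits")
  }
  regs <- rbind(.regression_summary(report$regression_mismatch),
                .regression_summary(report$regression_effects$dominance),
                .regression_summary(report$regression_effects$variance))
  wr(regs, "regressions")
  json <- list(
    seed = report$seed, alpha = report$alpha, averaging = report$averaging,
    space = report$space, n_individuals = report$n_individuals,
    n_traits = report$n_traits,
    package_version = as.character(utils::packageVersion("hybridmismatch")),
    regressions = regs,
    f2_correlations = report$f2_correlations[c("median_abs_r",
                                               "pct_significant", "n_pairs")],
    snowball_fits = report$snowball$fits
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
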