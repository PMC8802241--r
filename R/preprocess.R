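#' Substitute absent skeletal structures with 0.1 mm
#'
#' Spines and the pelvic girdle can be entirely absent in freshwater fish;
#' a raw value of 0 has no logarithm, so absent structures are recorded as
#' 0.1 mm before log-transformation. Only traits with an
#' `absence_substitution_mm` entry in the registry are touched.
#'
#' @param table A `trait_table`.
#' @param config A [trait_config()].
#' @return The table with zeros replaced for registered traits.
#' @export
substitute_absences <- function(table, config = trait_config()) {
  reg <- config$traits
  for (i in which(!is.na(reg$absence_substitution_mm))) {
    tr <- reg$trait[i]
    v <- table[[tr]]
    neg <- which(!is.na(v) & v < 0)
    if (length(neg)) {
      stop("value error: negative measurement for trait `", tr,
           "`, row(s) ", paste(utils::head(neg, 5), collapse = ", "),
           call. = FALSE)
    }
    v[!is.na(v) & v == 0] <- reg$absence_substitution_mm[i]
    table[[tr]] <- v
  }
  table
}

#' Allometric size correction
#'
#' Replaces each linear measurement by the residual of a simple ln-ln
#' regression of the trait on standard length, fitted once across the
#' entire dataset (all populations and generations pooled). Count traits
#' pass through unchanged. The fitted intercept and slope are stored in the
#' table's transform record.
#'
#' If all fish have identical standard length the regression slope is
#' indeterminate; the trait is then mean-centred on the ln scale with a
#' warning, which is all the downstream geometry requires.
#'
#' @param table A `trait_table`, after [substitute_absences()].
#' @param config A [trait_config()].
#' @param per_population Fit the allometry separately within each
#'   population instead of pooled (off by default; the pooled fit is the
#'   canonical analysis).
#' @return The corrected table; linear trait columns now hold unitless
#'   ln-scale residuals.
#' @export
size_correct <- function(table, config = trait_config(),
                         per_population = FALSE) {
  sl <- table$standard_length
  if (any(is.na(sl)) || any(sl <= 0)) {
    stop("value error: standard_length must be present and > 0 for all fish",
         call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("fit error: need at least 3 individuals for the allometric fit",
         call. = FALSE)
  }
  record <- attr(table, "transform_record")
  if (is.null(record)) record <- list()
  record$size <- list()
  log_sl <- log(sl)
  reg <- config$traits
  warned_constant_sl <- FALSE
  for (i in which(reg$size_correct & reg$kind == "linear")) {
    tr <- reg$trait[i]
    v <- table[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("value error: non-positive value for trait `", tr, "`, row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; absent structures must be substituted first ",
           "(see substitute_absences)", call. = FALSE)
    }
    log_v <- log(v)
    fit_one <- function(y, x) {
      ok <- !is.na(y)
      if (var(x[ok]) < .Machine$double.eps) {
        if (!warned_constant_sl) {
          warning("standard length is constant; mean-centring ln-scale ",
                  "traits instead of fitting allometric slopes",
                  call. = FALSE)
          warned_constant_sl <<- TRUE
        }
        list(intercept = mean(y[ok]), slope = NA_real_,
             resid = y - mean(y[ok]))
      } else {
        cf <- coef(lm(y ~ x, subset = ok))
        list(intercept = unname(cf[1]), slope = unname(cf[2]),
             resid = y - (cf[1] + cf[2] * x))
      }
    }
    if (per_population) {
      res <- rep(NA_real_, length(log_v))
      rec <- list()
      for (pop in unique(table$population)) {
        idx <- which(table$population == pop)
        f <- fit_one(log_v[idx], log_sl[idx])
        res[idx] <- f$resid
        rec[[pop]] <- f[c("intercept", "slope")]
      }
      record$size[[tr]] <- rec
      table[[tr]] <- res
    } else {
      f <- fit_one(log_v, log_sl)
      record$size[[tr]] <- f[c("intercept", "slope")]
      table[[tr]] <- f$resid
    }
  }
  attr(table, "transform_record") <- record
  attr(table, "size_corrected") <- TRUE
  table
}

#' Fixation-position correction
#'
#' Fish preserved with the mouth open measure differently for gape width,
#' snout length and head length. Each affected trait is residualized on the
#' fixation score (0, 1 or 2) treated as a categorical factor, i.e. the
#' category mean is subtracted, after size correction (sequential
#' residualization). Category effects are stored in the transform record; a
#' category with no members contributes no adjustment (warning).
#'
#' @param table A size-corrected `trait_table` with `fixation_score`
#'   populated.
#' @param config A [trait_config()].
#' @return The corrected table.
#' @export
fixation_correct <- function(table, config = trait_config()) {
  score <- table$fixation_score
  if (any(is.na(score)) || !all(score %in% 0:2)) {
    stop("value error: fixation_score must be 0, 1 or 2 for all fish",
         call. = FALSE)
  }
  absent <- setdiff(0:2, unique(score))
  if (length(absent)) {
    warning("fixation categor", if (length(absent) > 1) "ies " else "y ",
            paste(absent, collapse = ", "),
            " have no members and contribute no adjustment", call. = FALSE)
  }
  record <- attr(table, "transform_record")
  if (is.null(record)) record <- list()
  record$fixation <- list()
  reg <- config$traits
  for (tr in reg$trait[reg$fixation_affected]) {
    v <- table[[tr]]
    eff <- tapply(v, factor(score, levels = 0:2), mean, na.rm = TRUE)
    adj <- eff[as.character(score)]
    adj[is.na(adj)] <- 0
    table[[tr]] <- v - as.numeric(adj)
    record$fixation[[tr]] <- as.list(setNames(as.numeric(eff), names(eff)))
  }
  attr(table, "transform_record") <- record
  table
}

#' Z-standardize traits across the entire dataset
#'
#' Each trait column (parents and hybrids pooled) is centred to mean 0 and
#' scaled to SD 1 (sample SD, denominator n - 1). Required because trait
#' divergence has very different magnitudes for different traits (e.g. 30
#' armor plates versus 1 mm of spine). Rows with missing trait values must
#' be removed first ([drop_incomplete()]).
#'
#' @param table A corrected `trait_table`.
#' @param config A [trait_config()].
#' @return A [standardized_traits()] object carrying the accumulated
#'   transform record.
#' @export
standardize <- function(table, config = trait_config()) {
  traits <- trait_names(config)
  values <- as.matrix(as.data.frame(table)[, traits, drop = FALSE])
  if (anyNA(values)) {
    stop("missing trait values present; drop incomplete rows first ",
         "(see drop_incomplete)", call. = FALSE)
  }
  mu <- colMeans(values)
  sigma <- apply(values, 2, sd)
  zero <- sigma < .Machine$double.eps
  if (any(zero)) {
    stop("zero-variance trait(s): ", paste(traits[zero], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(values, 2, mu), 2, sigma, "/")
  record <- attr(table, "transform_record")
  if (is.null(record)) record <- list()
  record$scale <- list(mean = as.list(setNames(mu, traits)),
                       sd = as.list(setNames(sigma, traits)))
  meta <- as.data.frame(table)[, c("individual_id", "population", "cross_id",
                                   "generation", "family_id"), drop = FALSE]
  standardized_traits(z, meta, transforms = record)
}

#' Drop fish with incomplete trait measurements
#'
#' Multivariate mismatch needs every trait measured on every included fish;
#' fish missing any registered trait are removed and logged in a
#' `dropped_incomplete` attribute.
#'
#' @param table A `trait_table`.
#' @param config A [trait_config()].
#' @return The complete-case table.
#' @export
drop_incomplete <- function(table, config = trait_config()) {
  traits <- trait_names(config)
  keep <- complete.cases(as.data.frame(table)[, traits, drop = FALSE])
  dropped <- table$individual_id[!keep]
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_names", "transform_record", "size_corrected",
              "exclusion_log")) {
    attr(out, a) <- attr(table, a)
  }
  attr(out, "dropped_incomplete") <- dropped
  class(out) <- class(table)
  out
}

#' Full preprocessing pipeline
#'
#' Runs, in order: outlier exclusions, absence substitution, allometric
#' size correction, fixation correction, complete-case filtering and
#' z-standardization.
#'
#' @inheritParams size_correct
#' @return A [standardized_traits()] object. The exclusion and
#'   incompleteness logs from the intermediate steps are carried in the
#'   `exclusions` and `dropped_incomplete` attributes.
#' @export
preprocess <- function(table, config = trait_config(),
                       per_population = FALSE) {
  table <- apply_exclusions(table)
  excl <- exclusion_log(table)
  table <- substitute_absences(table, config)
  table <- size_correct(table, config, per_population = per_population)
  table <- fixation_correct(table, config)
  table <- drop_incomplete(table, config)
  out <- standardize(table, config)
  attr(out, "exclusions") <- excl
  attr(out, "dropped_incomplete") <- attr(table, "dropped_incomplete")
  out
}

#' Project new raw fish into an existing standardized space
#'
#' Applies a stored transform record (allometric intercept/slope, fixation
#' category effects, grand mean and SD per trait) to a new raw trait table,
#' reproducing the space of the original dataset without refitting.
#'
#' @param record A transform record, i.e. `x$transforms` from a
#'   [standardized_traits()] object produced by [preprocess()].
#' @param table A raw `trait_table` of new fish (after exclusions).
#' @param config A [trait_config()].
#' @return A numeric matrix of standardized trait values.
#' @export
project_traits <- function(record, table, config = trait_config()) {
  if (is.null(record$scale)) {
    stop("transform record has no standardization entry", call. = FALSE)
  }
  table <- substitute_absences(table, config)
  traits <- trait_names(config)
  reg <- config$traits
  out <- matrix(NA_real_, nrow(table), length(traits),
                dimnames = list(table$individual_id, traits))
  log_sl <- log(table$standard_length)
  for (tr in traits) {
    v <- table[[tr]]
    i <- match(tr, reg$trait)
    if (reg$size_correct[i] && reg$kind[i] == "linear") {
      f <- record$size[[tr]]
      v <- if (is.na(f$slope)) log(v) - f$intercept
           else log(v) - (f$intercept + f$slope * log_sl)
    }
    if (reg$fixation_affected[i] && !is.null(record$fixation[[tr]])) {
      eff <- record$fixation[[tr]]
      adj <- vapply(as.character(table$fixation_score), function(s) {
        e <- eff[[s]]
        if (is.null(e) || is.na(e)) 0 else e
      }, numeric(1))
      v <- v - adj
    }
    out[, tr] <- (v - record$scale$mean[[tr]]) / record$scale$sd[[tr]]
  }
  out
}
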