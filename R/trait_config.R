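#' Default stickleback trait registry
#'
#' The 15 analysed traits: 11 linear measurements (mm) and 4 meristic counts.
#' Eye diameter is excluded by default because of its low measurement
#' repeatability. Gape width, snout length and head length are flagged as
#' affected by fixation position (whether the mouth was preserved open).
#' First dorsal spine, pelvic spine and pelvic girdle can be absent in
#' freshwater fish; absent structures are recorded as 0 and substituted with
#' 0.1 mm before log-transformation.
#'
#' @return A data frame with columns `trait`, `kind` (`"linear"` or
#'   `"count"`), `size_correct`, `fixation_affected` and
#'   `absence_substitution_mm` (NA when no substitution applies).
#' @export
#' @examples
#' stickleback_traits()
stickleback_traits <- function() {
  tr <- data.frame(
    trait = c(
      "snout_length", "head_length", "gape_width", "body_depth", "body_width",
      "first_dorsal_spine", "second_dorsal_spine", "pelvic_spine",
      "pelvic_girdle", "pectoral_fin", "gill_raker_length",
      "plate_count", "dorsal_fin_rays", "anal_fin_rays", "gill_raker_count"
    ),
    kind = c(rep("linear", 11), rep("count", 4)),
    stringsAsFactors = FALSE
  )
  tr$size_correct <- tr$kind == "linear"
  tr$fixation_affected <- tr$trait %in% c("gape_width", "snout_length", "head_length")
  tr$absence_substitution_mm <- ifelse(
    tr$trait %in% c("first_dorsal_spine", "pelvic_spine", "pelvic_girdle"),
    0.1, NA_real_
  )
  tr
}

#' Build an analysis configuration
#'
#' Bundles the trait registry with the analysis-wide settings: the
#' significance level used for parent-difference screening and pairwise
#' tests, and the tolerance below which two parental mean phenotypes are
#' treated as coincident (the parental line is then undefined and mismatch
#' falls back to point distance).
#'
#' @param traits Trait registry data frame; see [stickleback_traits()] for
#'   the required columns.
#' @param alpha Significance level for hypothesis tests (default 0.05).
#' @param parent_tolerance Euclidean distance below which parental means are
#'   considered coincident (default 1e-10, standardized units).
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(traits = stickleback_traits(), alpha = 0.05,
                         parent_tolerance = 1e-10) {
  required <- c("trait", "kind", "size_correct", "fixation_affected",
                "absence_substitution_mm")
  if (!is.data.frame(traits) || !all(required %in% names(traits))) {
    stop("`traits` must be a data frame with columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(traits$trait)) {
    stop("trait registry contains duplicated trait names", call. = FALSE)
  }
  if (!all(traits$kind %in% c("linear", "count"))) {
    stop("trait `kind` must be \"linear\" or \"count\"", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(traits = traits, alpha = alpha, parent_tolerance = parent_tolerance),
    class = "trait_config"
  )
}

#' @exportS3Method base::print
print.trait_config <- function(x, ...) {
  cat("<trait_config> ", nrow(x$traits), " traits (",
      sum(x$traits$kind == "linear"), " linear, ",
      sum(x$traits$kind == "count"), " count); alpha = ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Read or write an analysis configuration as YAML
#'
#' The YAML layout mirrors [trait_config()]: a `traits` map keyed by trait
#' name and top-level `alpha` and `parent_tolerance` entries. This lets the
#' column headers of an external archive be mapped onto the registry without
#' code changes.
#'
#' @param path File path of the YAML configuration.
#' @return `read_trait_config()` returns a `trait_config`;
#'   `write_trait_config()` returns `path` invisibly.
#' @export
read_trait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  tr <- do.call(rbind, lapply(names(y$traits), function(nm) {
    t <- y$traits[[nm]]
    data.frame(
      trait = nm,
      kind = t$kind,
      size_correct = isTRUE(t$size_correct),
      fixation_affected = isTRUE(t$fixation_affected),
      absence_substitution_mm =
        if (is.null(t$absence_substitution_mm)) NA_real_
        else as.numeric(t$absence_substitution_mm),
      stringsAsFactors = FALSE
    )
  }))
  trait_config(
    traits = tr,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    parent_tolerance = if (is.null(y$parent_tolerance)) 1e-10 else y$parent_tolerance
  )
}

#' @rdname read_trait_config
#' @param config A `trait_config` object.
#' @export
write_trait_config <- function(config, path) {
  stopifnot(inherits(config, "trait_config"))
  traits <- setNames(lapply(seq_len(nrow(config$traits)), function(i) {
    row <- config$traits[i, ]
    out <- list(kind = row$kind, size_correct = row$size_correct,
                fixation_affected = row$fixation_affected)
    if (!is.na(row$absence_substitution_mm)) {
      out$absence_substitution_mm <- row$absence_substitution_mm
    }
    out
  }), config$traits$trait)
  yaml::write_yaml(
    list(alpha = config$alpha, parent_tolerance = config$parent_tolerance,
         traits = traits),
    path
  )
  invisible(path)
}

#' Trait names registered in a configuration
#' @param config A `trait_config`.
#' @return Character vector of trait names.
#' @export
trait_names <- function(config) config$traits$trait

.metadata_columns <- c(
  "individual_id", "population", "cross_id", "generation", "family_id",
  "standard_length", "fixation_score", "swim_bladder_ok",
  "second_dorsal_spine_present"
)
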