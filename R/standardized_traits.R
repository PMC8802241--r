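#' Standardized trait matrix
#'
#' Container for the unitless trait space in which all geometry happens: an
#' individuals-by-traits matrix of size-corrected, fixation-corrected,
#' z-standardized values, together with the row metadata (population,
#' cross, generation, family) and the transform record needed to project a
#' new raw fish into the same space.
#'
#' @param values Numeric matrix, individuals in rows, traits in columns
#'   (column names are trait names).
#' @param meta Data frame with one row per individual and columns
#'   `individual_id`, `population`, `cross_id`, `generation`, `family_id`.
#' @param transforms Optional transform record produced by the
#'   preprocessing steps (allometric slopes, fixation category effects,
#'   grand means and SDs).
#' @return An object of class `standardized_traits`.
#' @export
standardized_traits <- function(values, meta, transforms = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("`values` must have trait names as column names", call. = FALSE)
  }
  need <- c("individual_id", "population", "cross_id", "generation", "family_id")
  if (!all(need %in% names(meta))) {
    stop("`meta` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(values) != nrow(meta)) {
    stop("`values` and `meta` must have the same number of rows", call. = FALSE)
  }
  if (!all(meta$generation %in% GENERATIONS)) {
    stop("generation labels must be in {PM, PF, F1, F2}", call. = FALSE)
  }
  rownames(values) <- meta$individual_id
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, transforms = transforms),
            class = "standardized_traits")
}

#' @exportS3Method base::print
print.standardized_traits <- function(x, ...) {
  cat("<standardized_traits> ", nrow(x$values), " individuals x ",
      ncol(x$values), " traits\n", sep = "")
  tab <- table(x$meta$generation)
  cat("  generations:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  cat("  crosses:", length(cross_ids(x)), "\n")
  invisible(x)
}

#' @export
dim.standardized_traits <- function(x) dim(x$values)

#' Wrap a table already expressed in standardized units
#'
#' Used for simulated data generated directly in the standardized trait
#' space: no transformation is applied, the trait columns are taken as-is.
#'
#' @param table A `trait_table` (or plain data frame) whose trait columns
#'   are already standardized.
#' @param traits Character vector of trait column names; defaults to the
#'   `trait_names` attribute of `table`.
#' @return A `standardized_traits` object (with `transforms = NULL`).
#' @export
as_standardized_traits <- function(table, traits = attr(table, "trait_names")) {
  if (is.null(traits)) stop("no trait names available", call. = FALSE)
  missing_cols <- setdiff(traits, names(table))
  if (length(missing_cols)) {
    stop("missing trait column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(as.data.frame(table)[, traits, drop = FALSE])
  meta <- as.data.frame(table)[, c("individual_id", "population", "cross_id",
                                   "generation", "family_id"), drop = FALSE]
  standardized_traits(values, meta)
}

#' Cross identifiers present in a standardized matrix
#' @param x A `standardized_traits` object.
#' @return Sorted character vector of `cross_id`s carried by hybrid or
#'   freshwater-parent rows.
#' @export
cross_ids <- function(x) {
  keep <- x$meta$generation %in% c("PF", "F1", "F2") & !is.na(x$meta$cross_id)
  sort(unique(x$meta$cross_id[keep]))
}

# Row indices of the parents of a cross. PM rows may be cross-specific or
# shared (cross_id NA/empty), matching the single marine ancestral
# population crossed to every freshwater population.
.parent_rows <- function(x, cross_id) {
  m <- x$meta
  pm <- which(m$generation == "PM" &
                (is.na(m$cross_id) | m$cross_id == "" | m$cross_id == cross_id))
  pf <- which(m$generation == "PF" & !is.na(m$cross_id) & m$cross_id == cross_id)
  if (!length(pm)) stop("no PM rows for cross `", cross_id, "`", call. = FALSE)
  if (!length(pf)) stop("no PF rows for cross `", cross_id, "`", call. = FALSE)
  list(pm = pm, pf = pf)
}

.hybrid_rows <- function(x, cross_id, generation) {
  m <- x$meta
  which(m$generation == generation & !is.na(m$cross_id) &
          m$cross_id == cross_id)
}
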