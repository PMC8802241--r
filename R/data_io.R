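#' Read a per-individual trait table
#'
#' Reads a wide CSV/TSV (one row per fish) holding the metadata columns
#' (`individual_id`, `population`, `cross_id`, `generation`, `family_id`,
#' `standard_length`, `fixation_score`, `swim_bladder_ok`,
#' `second_dorsal_spine_present`) plus one column per registered trait, and
#' validates it against the trait registry.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param config A [trait_config()].
#' @return A validated `trait_table` (a data frame).
#' @seealso [validate_trait_table()], [apply_exclusions()]
#' @export
read_trait_table <- function(path, config = trait_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_trait_table(df, config)
}

#' Validate a raw trait table against the registry
#'
#' Checks the schema (all metadata and trait columns present), the
#' generation labels (`PM`, `PF`, `F1`, `F2`), uniqueness of
#' `individual_id`, integer-valued non-negative counts, and referential
#' integrity of crosses: every `cross_id` appearing in hybrid rows must have
#' freshwater-parent (`PF`) rows with the same `cross_id` and
#' marine-parent (`PM`) rows with either the same `cross_id` or a shared
#' marine population (`cross_id` = NA).
#'
#' @param df A data frame.
#' @param config A [trait_config()].
#' @param raw Table holds raw measurements (default). Set FALSE for tables
#'   already in standardized units, where count traits are continuous and
#'   the integer check does not apply.
#' @return The validated data frame with class `trait_table` and a
#'   `trait_names` attribute.
#' @export
validate_trait_table <- function(df, config = trait_config(), raw = TRUE) {
  traits <- trait_names(config)
  missing_cols <- setdiff(c(.metadata_columns, traits), names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_gen <- !df$generation %in% GENERATIONS
  if (any(bad_gen)) {
    stop("value error: generation label outside {PM, PF, F1, F2} in row(s) ",
         paste(utils::head(which(bad_gen), 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$individual_id)) {
    dup <- unique(df$individual_id[duplicated(df$individual_id)])
    stop("integrity error: duplicate individual_id: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  for (col in c("standard_length", traits)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(coerced))
      if (length(bad)) {
        stop("value error: unparseable values in column `", col,
             "`, row(s) ", paste(utils::head(bad, 5), collapse = ", "),
             call. = FALSE)
      }
      df[[col]] <- coerced
    }
  }
  count_traits <- if (raw) {
    trait_names(config)[config$traits$kind == "count"]
  } else {
    character(0)
  }
  for (col in count_traits) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad)) {
      stop("value error: count trait `", col,
           "` must be a non-negative integer, row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  hyb <- df$generation %in% c("F1", "F2")
  shared_pm <- df$generation == "PM" & (is.na(df$cross_id) | df$cross_id == "")
  for (cr in unique(df$cross_id[hyb])) {
    has_pf <- any(df$generation == "PF" & !is.na(df$cross_id) & df$cross_id == cr)
    has_pm <- any(shared_pm) ||
      any(df$generation == "PM" & !is.na(df$cross_id) & df$cross_id == cr)
    if (!has_pf) {
      stop("integrity error: cross `", cr, "` has hybrid rows but no PF rows",
           call. = FALSE)
    }
    if (!has_pm) {
      stop("integrity error: cross `", cr,
           "` has hybrid rows but no PM rows (and no shared marine rows)",
           call. = FALSE)
    }
  }
  for (col in c("swim_bladder_ok", "second_dorsal_spine_present")) {
    df[[col]] <- as.logical(df[[col]])
  }
  structure(df, class = c("trait_table", "data.frame"), trait_names = traits)
}

#' Remove flagged outlier individuals
#'
#' Drops fish with a missing second dorsal spine (extreme outliers in the
#' standardized space) and fish that failed to inflate their swim bladder.
#' The removals are recorded in an `exclusion_log` attribute (one entry per
#' removed fish, with the reason). Idempotent: re-applying to an already
#' filtered table removes nothing.
#'
#' @param table A `trait_table`.
#' @return The filtered table; retrieve the log with [exclusion_log()].
#' @export
apply_exclusions <- function(table) {
  spine <- !table$second_dorsal_spine_present
  bladder <- !table$swim_bladder_ok
  spine[is.na(spine)] <- FALSE
  bladder[is.na(bladder)] <- FALSE
  ids_spine <- table$individual_id[spine]
  ids_bladder <- table$individual_id[bladder & !spine]
  log <- data.frame(
    individual_id = c(ids_spine, ids_bladder),
    reason = c(rep("missing second dorsal spine", length(ids_spine)),
               rep("swim bladder not inflated", length(ids_bladder))),
    stringsAsFactors = FALSE
  )
  out <- table[!(spine | bladder), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all individuals excluded", call. = FALSE)
  attr(out, "trait_names") <- attr(table, "trait_names")
  attr(out, "exclusion_log") <- log
  class(out) <- class(table)
  out
}

#' @rdname apply_exclusions
#' @export
exclusion_log <- function(table) {
  log <- attr(table, "exclusion_log")
  if (is.null(log)) {
    data.frame(individual_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  } else {
    log
  }
}

#' Write a trait table as CSV with a stable column order
#'
#' Columns are written as the metadata block followed by the registered
#' traits in registry order, so repeated runs produce byte-comparable files.
#'
#' @param table A `trait_table`.
#' @param path Output file path.
#' @param config A [trait_config()]; defaults to the registry recorded on
#'   the table.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, config = NULL) {
  traits <- if (is.null(config)) attr(table, "trait_names") else trait_names(config)
  if (is.null(traits)) stop("no trait registry available", call. = FALSE)
  cols <- c(.metadata_columns, traits)
  write.csv(as.data.frame(table)[, cols, drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a long-format trait table
#'
#' Convenience reader for data stored as one row per (fish, trait)
#' measurement with columns `individual_id`, `trait`, `value` plus the
#' per-fish metadata. The table is pivoted to the canonical wide layout and
#' validated.
#'
#' @inheritParams read_trait_table
#' @return A validated `trait_table`.
#' @export
read_trait_table_long <- function(path, config = trait_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  long <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("individual_id", "trait", "value")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(.metadata_columns, names(long))
  meta <- unique(long[, meta_cols, drop = FALSE])
  if (anyDuplicated(meta$individual_id)) {
    stop("integrity error: inconsistent metadata across rows of the same ",
         "individual", call. = FALSE)
  }
  wide <- stats::reshape(
    long[, c("individual_id", "trait", "value")],
    idvar = "individual_id", timevar = "trait", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  df <- merge(meta, wide, by = "individual_id", sort = FALSE)
  validate_trait_table(df, config)
}
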