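#' Population mean phenotype as the unweighted mean of family means
#'
#' All population-level mean phenotypes are computed by first averaging
#' within each family and then averaging the family means without weighting
#' by family size, so that large families do not dominate the estimate.
#'
#' @param x A [standardized_traits()] object.
#' @param population Population label to average over (ignored when `rows`
#'   is given).
#' @param rows Optional integer row indices to average over instead.
#' @return Named numeric vector (one entry per trait).
#' @export
population_mean <- function(x, population = NULL, rows = NULL) {
  if (is.null(rows)) {
    if (is.null(population)) stop("give `population` or `rows`", call. = FALSE)
    rows <- which(x$meta$population == population)
  }
  if (!length(rows)) stop("empty population", call. = FALSE)
  colMeans(.family_means(x$values[rows, , drop = FALSE],
                         x$meta$family_id[rows]))
}

# family-wise trait means (families in rows)
.family_means <- function(values, family) {
  family <- as.character(family)
  counts <- rowsum(rep(1, length(family)), family)
  rowsum(values, family) / as.vector(counts)
}

#' Multivariate phenotypic divergence between two mean phenotypes
#'
#' The Euclidean norm of the difference between the freshwater and marine
#' population mean phenotypes in the standardized trait space.
#'
#' @param pm,pf Equal-length numeric vectors (marine and freshwater mean
#'   phenotypes).
#' @return Non-negative scalar.
#' @export
divergence <- function(pm, pf) {
  if (length(pm) != length(pf)) {
    stop("mean vectors must have equal length", call. = FALSE)
  }
  sqrt(sum((pf - pm)^2))
}

#' Perpendicular trait mismatch of hybrid phenotypes
#'
#' The mismatch of a hybrid is the shortest (perpendicular) Euclidean
#' distance between its phenotype and the infinite line through the two
#' parental mean phenotypes. The foot of the perpendicular may fall outside
#' the segment between the parents (transgressive hybrids), which is why
#' the whole line is used. When the parental means coincide (within `tol`)
#' the line is undefined and the distance to the common parental point is
#' returned with a warning.
#'
#' @param f Numeric vector (one phenotype) or matrix (individuals in rows).
#' @param pm,pf Parental mean phenotype vectors.
#' @param tol Tolerance below which parental means are coincident.
#' @return Numeric vector of non-negative mismatch values, one per row of
#'   `f`.
#' @export
mismatch <- function(f, pm, pf, tol = 1e-10) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (ncol(f) != length(pm) || length(pm) != length(pf)) {
    stop("phenotype and parental mean vectors must have equal length",
         call. = FALSE)
  }
  d <- pf - pm
  nd <- sqrt(sum(d^2))
  w <- sweep(f, 2, pm)
  if (nd < tol) {
    warning("parental mean phenotypes coincide; returning distance to the ",
            "common parental point", call. = FALSE)
    return(sqrt(rowSums(w^2)))
  }
  u <- d / nd
  proj <- as.vector(w %*% u)
  resid <- w - tcrossprod(proj, u)
  sqrt(rowSums(resid^2))
}

#' Parental mean phenotypes and divergence of one cross
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @return List with `pm`, `pf` (mean vectors, unweighted family-mean
#'   convention) and `divergence`.
#' @export
cross_parent_means <- function(x, cross_id) {
  rows <- .parent_rows(x, cross_id)
  pm <- population_mean(x, rows = rows$pm)
  pf <- population_mean(x, rows = rows$pf)
  list(pm = pm, pf = pf, divergence = divergence(pm, pf))
}

#' Divergence table for all crosses
#'
#' @param x A [standardized_traits()] object.
#' @return Data frame with one row per cross: `cross_id`,
#'   `freshwater_population`, `divergence`.
#' @export
cross_divergence <- function(x) {
  ids <- cross_ids(x)
  out <- lapply(ids, function(cr) {
    cp <- cross_parent_means(x, cr)
    pf_rows <- .parent_rows(x, cr)$pf
    data.frame(cross_id = cr,
               freshwater_population = x$meta$population[pf_rows[1]],
               divergence = cp$divergence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-individual mismatch values
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Single cross, or NULL for all crosses.
#' @param generations Generations to include (default hybrids only).
#' @param tol Coincident-parent tolerance.
#' @return Data frame: `individual_id`, `cross_id`, `generation`,
#'   `family_id`, `d_mm`.
#' @export
individual_mismatch <- function(x, cross_id = NULL,
                                generations = c("F1", "F2"), tol = 1e-10) {
  ids <- if (is.null(cross_id)) cross_ids(x) else cross_id
  out <- lapply(ids, function(cr) {
    cp <- cross_parent_means(x, cr)
    rows <- unlist(lapply(generations, function(g) .hybrid_rows(x, cr, g)))
    if (!length(rows)) return(NULL)
    data.frame(
      individual_id = x$meta$individual_id[rows],
      cross_id = cr,
      generation = x$meta$generation[rows],
      family_id = x$meta$family_id[rows],
      d_mm = mismatch(x$values[rows, , drop = FALSE], cp$pm, cp$pf, tol),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Decompose mean hybrid mismatch into dominance and variance effects
#'
#' The dominance effect is the mismatch of the mean hybrid phenotype: it is
#' nonzero only when net dominance displaces the generation mean off the
#' parental line. The variance effect is the average excess of individual
#' mismatch over the dominance effect, driven by phenotypic (in F2,
#' segregation) variation around the hybrid mean. Under `"family"`
#' averaging, individual excesses are averaged within each family and the
#' family values averaged without weighting; under `"individual"` averaging
#' all hybrids are pooled. Either way the identity
#' `mean_mismatch = dominance_effect + variance_effect` holds exactly, and
#' the variance effect is non-negative (Jensen's inequality, since distance
#' to a line is convex).
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param generation `"F1"` or `"F2"`.
#' @param averaging `"family"` (family means first, the default reporting
#'   convention) or `"individual"`.
#' @param tol Coincident-parent tolerance.
#' @return One-row data frame: `cross_id`, `generation`, `n_individuals`,
#'   `n_families`, `dominance_effect`, `variance_effect`, `mean_mismatch`.
#' @export
decompose_mismatch <- function(x, cross_id, generation,
                               averaging = c("family", "individual"),
                               tol = 1e-10) {
  averaging <- match.arg(averaging)
  cp <- cross_parent_means(x, cross_id)
  rows <- .hybrid_rows(x, cross_id, generation)
  if (!length(rows)) {
    stop("no ", generation, " rows for cross `", cross_id, "`", call. = FALSE)
  }
  v <- x$values[rows, , drop = FALSE]
  fam <- as.character(x$meta$family_id[rows])
  d_ind <- mismatch(v, cp$pm, cp$pf, tol)
  if (averaging == "family") {
    hmean <- colMeans(.family_means(v, fam))
    dominance <- mismatch(hmean, cp$pm, cp$pf, tol)
    fam_excess <- rowsum(d_ind - dominance, fam) /
      as.vector(rowsum(rep(1, length(fam)), fam))
    variance <- mean(fam_excess)
  } else {
    hmean <- colMeans(v)
    dominance <- mismatch(hmean, cp$pm, cp$pf, tol)
    variance <- mean(d_ind) - dominance
  }
  data.frame(
    cross_id = cross_id, generation = generation,
    n_individuals = length(rows), n_families = length(unique(fam)),
    dominance_effect = as.numeric(dominance),
    variance_effect = as.numeric(variance),
    mean_mismatch = as.numeric(dominance + variance),
    stringsAsFactors = FALSE
  )
}

#' Mismatch decomposition for every cross and hybrid generation
#'
#' @inheritParams decompose_mismatch
#' @param generations Hybrid generations to decompose.
#' @return Data frame with one row per cross x generation; see
#'   [decompose_mismatch()].
#' @export
mismatch_decomposition <- function(x, averaging = c("family", "individual"),
                                   generations = c("F1", "F2"),
                                   tol = 1e-10) {
  averaging <- match.arg(averaging)
  out <- list()
  for (cr in cross_ids(x)) {
    for (g in generations) {
      if (length(.hybrid_rows(x, cr, g))) {
        out[[paste(cr, g)]] <-
          decompose_mismatch(x, cr, g, averaging = averaging, tol = tol)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Baseline mismatch of parental individuals
#'
#' Individuals from the parent populations themselves deviate from the line
#' connecting the parental means because of their phenotypic variation;
#' their average deviation (family means first, then the population
#' average) is the natural baseline against which hybrid mismatch is
#' compared.
#'
#' @inheritParams decompose_mismatch
#' @return Data frame with one row per parent population of the cross:
#'   `cross_id`, `role` (`PM`/`PF`), `population`, `mean_deviation`.
#' @export
parent_deviation <- function(x, cross_id, tol = 1e-10) {
  cp <- cross_parent_means(x, cross_id)
  rows <- .parent_rows(x, cross_id)
  one <- function(idx, role) {
    d <- mismatch(x$values[idx, , drop = FALSE], cp$pm, cp$pf, tol)
    fam <- as.character(x$meta$family_id[idx])
    fmean <- rowsum(d, fam) / as.vector(rowsum(rep(1, length(fam)), fam))
    data.frame(cross_id = cross_id, role = role,
               population = x$meta$population[idx[1]],
               mean_deviation = mean(fmean), stringsAsFactors = FALSE)
  }
  rbind(one(rows$pm, "PM"), one(rows$pf, "PF"))
}

#' Pairwise (two-trait) mismatch
#'
#' Mismatch restricted to the plane of two named traits: the perpendicular
#' distance to the line joining the parental means within that plane. When
#' the parents do not differ in the plane (within `tol`) the distance to
#' the common parental point is returned with a warning.
#'
#' @param x A [standardized_traits()] object.
#' @param cross_id Cross identifier.
#' @param trait_i,trait_j Trait names.
#' @param generations Generations of individuals to score (default all
#'   four, so parental baselines are available).
#' @param tol Coincident-parent tolerance.
#' @return Data frame: `individual_id`, `generation`, `family_id`,
#'   `trait_i`, `trait_j`, `d_mm`.
#' @export
pairwise_mismatch <- function(x, cross_id, trait_i, trait_j,
                              generations = GENERATIONS, tol = 1e-10) {
  stopifnot(trait_i %in% colnames(x$values), trait_j %in% colnames(x$values))
  cp <- cross_parent_means(x, cross_id)
  pr <- .parent_rows(x, cross_id)
  keep <- c(trait_i, trait_j)
  m <- x$meta
  rows <- which((m$generation %in% intersect(generations, c("F1", "F2")) &
                   !is.na(m$cross_id) & m$cross_id == cross_id) |
                  (m$generation == "PM" & "PM" %in% generations &
                     seq_len(nrow(m)) %in% pr$pm) |
                  (m$generation == "PF" & "PF" %in% generations &
                     seq_len(nrow(m)) %in% pr$pf))
  data.frame(
    individual_id = m$individual_id[rows],
    generation = m$generation[rows],
    family_id = m$family_id[rows],
    trait_i = trait_i, trait_j = trait_j,
    d_mm = mismatch(x$values[rows, keep, drop = FALSE],
                    cp$pm[keep], cp$pf[keep], tol),
    stringsAsFactors = FALSE
  )
}

#' Distances of hybrids to each parental mean phenotype
#'
#' Euclidean distances of each hybrid to the marine and to the freshwater
#' mean phenotype; both grow with divergence, placing hybrids increasingly
#' far from either potential fitness optimum.
#'
#' @inheritParams decompose_mismatch
#' @return Data frame: `individual_id`, `cross_id`, `generation`,
#'   `family_id`, `dist_pm`, `dist_pf`.
#' @export
parent_distances <- function(x, cross_id, generation) {
  cp <- cross_parent_means(x, cross_id)
  rows <- .hybrid_rows(x, cross_id, generation)
  if (!length(rows)) {
    stop("no ", generation, " rows for cross `", cross_id, "`", call. = FALSE)
  }
  v <- x$values[rows, , drop = FALSE]
  data.frame(
    individual_id = x$meta$individual_id[rows],
    cross_id = cross_id, generation = generation,
    family_id = x$meta$family_id[rows],
    dist_pm = sqrt(rowSums(sweep(v, 2, cp$pm)^2)),
    dist_pf = sqrt(rowSums(sweep(v, 2, cp$pf)^2)),
    stringsAsFactors = FALSE
  )
}
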