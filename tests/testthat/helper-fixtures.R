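# Small in-code fixtures shared across the test files.

# a minimal two-trait registry for toy tables
toy_config <- function() {
  trait_config(traits = data.frame(
    trait = c("body_depth", "plate_count"),
    kind = c("linear", "count"),
    size_correct = c(TRUE, FALSE),
    fixation_affected = c(FALSE, FALSE),
    absence_substitution_mm = c(NA_real_, NA_real_),
    stringsAsFactors = FALSE
  ))
}

# wide toy trait table: one cross, all four generations
toy_table <- function(n_per_gen = 1, traits = c(body_depth = 5, plate_count = 20)) {
  gens <- rep(c("PM", "PF", "F1", "F2"), each = n_per_gen)
  n <- length(gens)
  df <- data.frame(
    individual_id = sprintf("fish%02d", seq_len(n)),
    population = ifelse(gens == "PM", "marine", "fw01"),
    cross_id = ifelse(gens == "PM", NA_character_, "cross01"),
    generation = gens,
    family_id = paste0(gens, "_f1"),
    standard_length = 40,
    fixation_score = 0L,
    swim_bladder_ok = TRUE,
    second_dorsal_spine_present = TRUE,
    stringsAsFactors = FALSE
  )
  for (tr in names(traits)) df[[tr]] <- traits[[tr]]
  df
}

# standardized_traits object built directly from a matrix of phenotypes;
# `gen`, `fam`, `cross` recycled to nrow(values)
make_std <- function(values, gen, fam = "f1", cross = "c1", pop = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || any(colnames(values) == "") ||
      anyDuplicated(colnames(values))) {
    colnames(values) <- paste0("t", seq_len(ncol(values)))
  }
  n <- nrow(values)
  gen <- rep_len(gen, n)
  if (is.null(pop)) pop <- ifelse(gen == "PM", "marine", "fw")
  meta <- data.frame(
    individual_id = sprintf("id%04d", seq_len(n)),
    population = rep_len(pop, n),
    cross_id = rep_len(cross, n),
    generation = gen,
    family_id = rep_len(fam, n),
    stringsAsFactors = FALSE
  )
  standardized_traits(values, meta)
}

# one-cross standardized dataset: parents at pm/pf (replicated, optionally
# with noise), hybrids given explicitly
make_cross_std <- function(pm, pf, hybrids, hybrid_gen = "F2",
                           hybrid_fam = "hf1", n_parents = 2) {
  pm_m <- matrix(pm, n_parents, length(pm), byrow = TRUE)
  pf_m <- matrix(pf, n_parents, length(pf), byrow = TRUE)
  values <- rbind(pm_m, pf_m, as.matrix(hybrids))
  gen <- c(rep("PM", n_parents), rep("PF", n_parents),
           rep_len(hybrid_gen, nrow(as.matrix(hybrids))))
  fam <- c(rep("pmf1", n_parents), rep("pff1", n_parents),
           rep_len(hybrid_fam, nrow(as.matrix(hybrids))))
  make_std(values, gen, fam)
}

# random orthogonal matrix via QR
random_rotation <- function(p) {
  qr_obj <- qr(matrix(rnorm(p * p), p))
  q <- qr.Q(qr_obj)
  q %*% diag(sign(diag(qr.R(qr_obj))), p)
}
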