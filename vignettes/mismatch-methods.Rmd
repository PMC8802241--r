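---
title: "Measuring hybrid trait mismatch: model, decomposition and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hybrid trait mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmismatch)
```

## The problem

Populations adapting to different environments diverge in many traits at
once. Their hybrids need not be neatly intermediate: dominance can pull
different traits toward different parents, and in recombinant hybrids the
segregation of divergent alleles inflates phenotypic variance. Either way
a hybrid can end up *mismatched* — marine-like for one trait,
freshwater-like for another — a phenotypic analogue of intrinsic genetic
incompatibilities, and a candidate mechanism for ecologically driven
reproductive isolation. This package quantifies mismatch, decomposes it
into its two quantitative-genetic sources, and asks whether both grow with
the magnitude of parental divergence, using marine × freshwater
stickleback-style line crosses (two parental populations, F1 and F2
hybrids, with family structure) as the motivating design.

## The standardized trait space

All geometry happens in a common unitless space built by `preprocess()`:

1. **Absence substitution.** Spines and the pelvic girdle can be entirely
   absent; a raw 0 mm has no logarithm and is recorded as 0.1 mm
   (`substitute_absences()`). The registry (`trait_config()`) controls
   which traits this applies to.
2. **Allometric size correction.** Each linear measurement is replaced by
   its residual from a single ln–ln regression on standard length fitted
   across the entire dataset — one shared allometry, not one per
   population, so population differences in shape are preserved rather
   than absorbed into population-specific slopes (a per-population option
   exists but is off by default). Count traits (fin rays, plates, gill
   rakers) are never log-transformed or size-corrected. If every fish has
   the same standard length the slope is indeterminate; the trait is
   mean-centred with a warning, which is all the downstream geometry
   needs.
3. **Fixation correction.** Gape width, snout length and head length are
   affected by whether a fish was preserved with the mouth open
   (score 0/1/2). The correction subtracts the category mean from the
   size-corrected value — sequential residualization, i.e. an additive
   correction on the size-corrected scale. Whether the original analysis
   used a joint model or sequential residuals is not determinable from the
   description; sequential is implemented and flagged here because it
   composes cleanly with the stored transform record.
4. **Standardization.** Every trait is scaled to mean 0, SD 1 (sample SD,
   n − 1) across the entire pooled dataset, because trait divergences have
   wildly different natural units (≈30 armor plates versus ≈1 mm of
   spine).

The transform record (slopes, category effects, grand moments) is kept on
the result so held-out fish can be projected into the same space
(`project_traits()`). Mismatch needs complete trait vectors, so fish with
any missing registered trait are dropped and logged (`drop_incomplete()`);
fish with a missing second dorsal spine or an uninflated swim bladder are
excluded up front as known outliers (`apply_exclusions()`).

## Divergence, mismatch, and the dominance/variance decomposition

Population mean phenotypes are **unweighted means of family means**
(`population_mean()`), so one large family cannot dominate a population
estimate. Parental divergence is the Euclidean norm
`D = ||P̄_F − P̄_M||` over the standardized traits.

A hybrid's mismatch `d_mm` is its perpendicular Euclidean distance to the
**infinite line** through the two parental means (`mismatch()`). The line,
not the segment: transgressive hybrids project beyond a parent, and
truncating at the parents would conflate transgression with mismatch. If
the parental means coincide (within `1e-10` standardized units) the line
is undefined and the distance to the common point is returned with a
warning.

For each cross × hybrid generation, `decompose_mismatch()` splits the mean
mismatch exactly:

* **dominance effect** — `d_mm` of the mean hybrid phenotype. Only a net
  displacement of the *mean* off the parental line produces it, and only
  dominance produces such a displacement in expectation.
* **variance effect** — the average of individual `d_mm − dominance
  effect`, averaged within families first and then across families
  (individual-level pooling is available; the identity and all
  conclusions are unchanged).

Because distance-to-a-line is convex, Jensen's inequality makes the
variance effect non-negative under either averaging, and by construction
`mean mismatch = dominance effect + variance effect` holds exactly. The
same perpendicular distance applied to parental individuals gives the
baseline deviation produced by ordinary within-population variation
(`parent_deviation()`); in p = 15 standardized traits with isotropic
within-population SD σ this baseline is ≈ E[χ₁₄]·σ ≈ 3.67 σ, which the
tests verify against the closed form.

## Inference

`fit_divergence_mismatch()` analyses one mean-mismatch value per cross ×
generation (population is the replicate): mismatch ~ divergence × hybrid
generation with a random intercept per freshwater population, fitted with
`lme4`/`lmerTest`. Denominator degrees of freedom use the **Satterthwaite**
approximation; a likelihood-ratio option exists for the per-trait
dominance test. Kenward–Roger was deliberately not used — the scientific
quantities here are slopes and their confidence intervals, which are
essentially unchanged, and Satterthwaite is available wherever `lmerTest`
is. When the population variance component is zero the mixed fit reduces
to ordinary least squares (tested), and the engine falls back to `lm()`
outright if a mixed fit is impossible.

`fit_effect_regressions()` applies the same model form to the dominance
and variance effects, reporting per-generation slopes with CIs and the
divergence × generation interaction: the expected signature is a dominance
slope in F1 and a variance slope in F2.

Per-trait line-cross genetics (`fit_additive_dominance()`) regresses the
standardized trait on an additive index (fraction of the genome
freshwater: PM 0, F1 = F2 0.5, PF 1) and a dominance index (expected
heterozygosity: F1 1, F2 0.5, parents 0), with a family random intercept.
Dominance coefficients (`dominance_coefficient()`) place the hybrid mean
on a 0 (marine) to 1 (freshwater) axis per trait and are only computed
where the parents are statistically distinguishable (Welch t-test at
α = 0.05, uncorrected across traits — each trait is reported on its own
terms, matching the per-trait screening convention of the original
analysis).

The **snowball** analysis (`snowball()`) counts, per cross and generation,
trait pairs whose two-trait mismatch significantly exceeds the parental
baseline for the same pair (one-sided Welch test at α = 0.05,
uncorrected), then contrasts linear against quadratic growth of the count
with divergence. The pairwise significance rule is an interpretation — the
original supplementary procedure is not fully specified — and is
deliberately simple and togglable (`alpha`, `generations`). Two numerical
guards matter: pairs whose hybrid excess is below 1e-8 standardized units
never count (all-zero data would otherwise produce spurious hits at
floating-point resolution), and the baseline is computed from the same
individuals that define the parental line, which deflates parental
deviations slightly and makes the test mildly anticonservative under a
pure null — acceptable for a heuristic count, and documented in the tests.

F2 trait correlations (`f2_correlation_summary()`) are computed **within
crosses** and pooled; pooling individuals across crosses would manufacture
correlations from between-population mean differences. Low, mostly
non-significant within-cross correlations are what justifies working in
the original trait space rather than reducing dimensions.

## The synthetic study generator

`simulate_study()` emulates the study design directly in standardized
trait space: one shared marine population at the origin; 12 freshwater
populations displaced by D = 3 … 10 standardized units (evenly spaced)
along independent random directions; 6 marine families (~17 fish each),
6 freshwater parental families (~5), 6 F1 families (~5) and 3 F2 families
(~20) per cross; independent Gaussian family intercepts on every trait.

* **Dominance.** Per-trait dominance coefficients `d_t ~ N(0.5, 0.3)`
  generate a displacement `(d_t − 0.5) δ_t` of the F1 mean from the
  midparent. Its component perpendicular to the parental axis is rescaled
  to norm `h_perp · D` (default 0.16), so the mismatch of the *true* F1
  mean is exactly `0.16 D` by construction; the along-axis component is
  kept as drawn (it causes no mismatch). The F2 mean carries a fraction of
  the same displacement (default 0.5, the usual halving of dominance in
  recombinants; 0 plants the mechanism purely in the F1).
* **Segregation variance.** F2 per-trait variance is
  `σ_P² + δ_t²/(8 n_e)` — the Castle–Wright form with `n_e` effective
  factors — so F2 scatter, and through it the variance effect, grows with
  divergence while F1 scatter does not.
* **Scale.** Within-family SD is `σ_P = 0.3` with family-intercept SD
  0.15. In a space standardized over *all* populations jointly, the
  within-population SD must be well below 1 because the pooled SD absorbs
  3–10 units of between-population divergence; 0.3 puts the parental
  deviation baseline (≈ 3.67 × 0.33 ≈ 1.2) and the divergence–mismatch
  slopes (~0.1–0.17) on the scale the field study reports, which unit
  parental SD would not.
* **Calibration.** `n_e = 2.68` was fixed once by simulating the full
  pipeline over a grid of `n_e` and interpolating to the value at which
  the expected F2 variance-effect slope equals 0.12 under the
  F1-only-dominance configuration; it is a design constant, not a fitting
  parameter.
* **Determinism.** One master seed; per-cross child seeds are derived
  arithmetically, so identical seeds give identical tables. A versioned
  truth record (divergence, direction, dominance displacement, F2 SDs)
  accompanies every simulated study for recovery tests.

A raw-space mode maps the same signal onto measurement scales — lognormal
standard length, per-trait allometric slopes, multiplicative fixation
effects, occasional absent spines, integer counts, a few flagged fish —
purely to exercise the preprocessing chain end to end.

### What the simulator does and does not capture

It captures the design's family structure, the generation-specific
mechanism signatures, and the growth of segregation variance with
divergence. It does **not** simulate genotypes, linkage or selection;
trait noise is Gaussian and independent across traits (real F2 trait
correlations are low but not zero); dominance directions are symmetric
around 0.5 (real stickleback dominance leans toward the marine parent);
and cross-to-cross heterogeneity beyond sampling noise is absent. Passing
recovery tests therefore demonstrates that the *estimators* are correct
and well calibrated under the stated model — not that real data meet the
model's assumptions.

One structural consequence is worth knowing. The estimated dominance
effect is a vector norm, so at finite sample size it is biased upward, and
recovery tests compare the pipeline against the *expectation of the
estimator* (computed from the exact Gaussian sampling distribution of the
estimated means, `expected_dominance_effects()`) rather than naively
against `0.16 D`. Relatedly, because `E||z + c|| − ||c||` is concave in
the offset `c`, a growing dominance displacement slightly *depresses* the
F1 variance effect: in the clean generator the F1 variance-effect slope is
a small negative number (≈ −0.05) rather than exactly zero, and the
design's precision is high enough to resolve it. Empirical estimates of
that slope carry far more residual noise, which is why a small positive
point estimate with a CI spanning zero is entirely compatible with this
geometry.

## Numerical choices and degenerate inputs

* Coincident parental means: tolerance `1e-10`; mismatch falls back to
  point distance with a warning.
* Perpendicular residuals are computed by explicit projection
  (`w − (w·û)û`), not by the cancellation-prone
  `sqrt(||w||² − (w·û)²)` for the final value.
* A compiled grid search (`grid_line_distance()`, step 1e-5 over
  t ∈ [−5, 6]) serves as the independent oracle for the projection.
* Zero-variance traits abort standardization with the trait named;
  constant standard length degrades to mean-centring with a warning;
  families of size one are skipped (with a warning) in variance
  estimation; fewer than 3 crosses aborts the regressions.
* Mixed-model failures downgrade to OLS and are flagged in the output
  rather than silently dropped.

## Problem sizes used in the test suite

The default simulated study (12 crosses, ~1500 fish, 15 traits) is used
throughout. Recovery checks use 200 replicate studies; null calibration
uses 1000 replicates for the regression slope and 1080 model fits for the
per-trait dominance test; the geometry oracle runs 1000 random instances;
closed-form checks use 10⁵ hybrids (half-normal limit) and 4 × 10⁴
parental fish (χ baseline). These sizes keep Monte-Carlo error well below
the tolerances being asserted.

## Known limitations

* The pairwise (snowball) significance rule is an interpretation of a
  procedure whose original details are not public; treat the counts as a
  heuristic, as the trait pairs are not independent.
* Satterthwaite df can differ from Kenward–Roger in small samples; slopes
  and CIs are the stable quantities.
* The analysis deliberately ignores trait covariances (no Mahalanobis
  variant, no PCA); with low F2 correlations this is defensible but it is
  an assumption, not a theorem.
* Mismatch is measured, not fitness: linking `d_mm` to selection requires
  data this package does not model.
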