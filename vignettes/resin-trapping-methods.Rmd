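---
title: "Methods: measuring trapping uniformity and assemblage bias in resins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring trapping uniformity and assemblage bias in resins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resintrap)
```

## The scientific question

Resin exuded on a tree trunk acts as a passive entomological trap. Whether
the fossil assemblage (oryctocoenosis) in the resulting amber reflects the
living community (biocoenosis) depends on *how* the resin trapped: a resin
that stays sticky for a long time traps arthropods wherever and whenever
they land, spreading inclusions uniformly across pieces; a fast-drying
resin traps only during brief sticky windows, concentrating the few
inclusions it catches in a few lumps. `resintrap` quantifies this
difference from nothing more than piece masses and inclusion counts, and
compares the taxonomic composition of what different traps catch.

## The uniformity exponent

### Model

For a collection of pieces, let `P(empty | m)` be the probability that a
piece of mass `m` (grams) contains no arthropod inclusions. We estimate it
by binning masses and inverting the empirical conditional with Bayes'
theorem:

\[ P(\mathrm{empty}\mid m) \;=\;
   \frac{f(m \mid \mathrm{empty})\, P(\mathrm{empty})}{f(m)} . \]

Algebraically this reduces to the direct frequency `n_empty / n_total`
within each bin; the package computes it by the Bayes route and the test
suite verifies the identity to machine precision on random collections.
The curve is then fitted with

\[ \log P(\mathrm{empty}\mid m) = \log(a) + b \log(m) \]

by ordinary least squares over the occupied bins. The slope `b` is the
**uniformity exponent**:

* `b = 0` — the flat limit: emptiness is independent of mass, which happens
  when all inclusions are concentrated in essentially one piece;
* `b` strongly negative — big pieces are reliably non-empty, the signature
  of spatially uniform trapping. The uniform Poisson limit
  `P(empty | m) = exp(-λ m^β)` decays faster than any power law, so in
  practice a uniform process yields a large finite `|b|` over the observed
  mass range (the analytic form is exposed as `analytic_empty_prob()` and
  used as an oracle in the tests).

Crucially, `b` is insensitive to overall trapping *intensity*: halving the
arthropod density around the tree shifts `log(a)` (a parallel offset of the
curve) but leaves the shape, hence `b`, unchanged. A difference in `b`
between two collections therefore indicates a difference in trapping
*pattern*, not merely in the abundance of arthropods.

### Binning and numerical choices

* **Default bin width 0.01 g** — the recording resolution of the masses.
  With small collections this produces many singleton bins whose
  probabilities are 0 or 1; the fit still works but is noisy.
* **Logarithmic binning** (`log_bins = n`) — equal bins in `log m`,
  recommended for collections under ~1000 pieces; the analyses and tests in
  this package use 12–15 log bins. The bin abscissa is the arithmetic
  midpoint by default (`midpoint = "geometric"` is available for log bins).
* **Zero-probability bins are dropped, never pseudo-counted.** A bin with
  `P = 0` carries no log-space information, and any pseudo-count would pull
  the slope towards an arbitrary floor. The number of dropped bins is
  recorded on the fit (`n_bins_dropped`).
* **Mass cutoffs.** `min_mass_g` excludes pieces below a threshold before
  binning — field collections are often biased against tiny pieces, which
  are undercollected and distort the small-mass end of the curve. A 0.5 g
  cutoff is the documented choice for collections of sticky resins whose
  smallest pieces (down to 0.01 g) were demonstrably undersampled. A
  separate fit-time cutoff (`fit_min_mass_g`) restricts the fitted bins
  without re-binning.
* **At least 3 usable bins** are required for a reported fit.
* **Uncertainty.** The OLS slope standard error is reported by default, but
  binned points are not independent observations of pieces; a piece-level
  bootstrap (resample pieces, re-bin, re-fit; `bootstrap = 1000` seeded
  replicates) is provided and preferred for publication-grade errors.

The sign convention: `b` is simply the fitted slope, so decreasing curves
give negative `b` and "more negative = more uniform". Fits on exact inputs
(a constructed `P = m^-2` curve) recover `b = -2`, `log a = 0`, `r² = 1`
bit-exactly.

## Accumulation power laws

Inclusion totals versus inspected mass across localities are fitted with
`N = c m^β`, `β` box-constrained to `[2/3, 1]`. We read the bounds as
scaling limits — trapping proportional to lump surface (`area ∝ m^(2/3)`)
at one end and to volume at the other — though we treat them as a modelling
constraint, not an asserted mechanism. The fit is least squares in log–log
space with clip-and-refit: if the unconstrained slope leaves the box, `β`
is pinned at the violated bound and the prefactor refitted alone (the
closed-form intercept at fixed slope). A brute-force grid search over
`(β, log c)` in the test suite confirms the constrained optimum. Zero-count
localities cannot enter a log fit and are excluded (none exist in the
packaged table); a Poisson-regression mode (`method = "poisson"`, log link)
retains them for zero-heavy synthetic data. Standard errors come from a
case-resampling bootstrap (default 1000 replicates, seeded), matching the
percentile-band construction used for plotting at the 68% level.

On the packaged locality table both groups pin a bound: the
Agathis-family group (pooling Agathis, Agathis-like and cheirolepidiaceous
sources, which are chemically alike) fits `β = 1` with a tiny prefactor,
the Hymenaea group `β = 2/3` with a prefactor two orders of magnitude
larger, so the Hymenaea curve lies far above at any realistic mass.
Localities whose inspected mass is printed as a range are resolved to the
midpoint; "circa" masses are flagged approximate but included (they are
part of the published accumulation pattern).

## Composition analyses

* **Profiles.** Counts are converted to probability profiles with a
  Jeffreys-style pseudocount of 0.5 per cell (configurable, 0 allowed for
  textbook checks) so that taxa absent from one sample do not force
  degenerate distances.
* **Bhattacharyya distance** `D = -ln Σ√(pᵢqᵢ)`; the coefficient is clipped
  to `(0, 1]` before the log, and disjoint supports map to a finite cap
  (default 50) so ordination stays finite. `D` is symmetric,
  non-negative and zero iff the profiles agree, but it does not obey the
  triangle inequality in general — hence the next point.
* **Classical (Torgerson) MDS** is used because per-axis "variance
  explained" is defined by its eigenvalues; non-metric MDS has no such
  decomposition. Negative eigenvalues (expected for a non-Euclidean
  dissimilarity) are truncated; their total magnitude is reported so the
  user can judge the distortion. Variance explained is computed over the
  positive eigenvalues only.
* **Clustering** is complete-linkage agglomeration on `1 − Spearman ρ`
  between sample rows (average ranks for ties), the combination whose merge
  heights are monotone. Dendrograms export to Newick.
* **Flying vs non-flying.** Counts are aggregated per sample into flying
  and non-flying insect totals under an editable classification
  (`extdata/flying_classes.csv`): winged insect orders are flying; ants
  (Formicidae), Collembola and Zygentoma are non-flying; non-insect
  arthropods are excluded. Homogeneity is tested by Pearson chi-square
  without continuity correction (standardised residuals `(O−E)/√E` per
  cell); a seeded Monte-Carlo p-value is available for small expected
  counts, and a table with an expected zero is refused rather than patched.

## The simulator: what it emulates and what it does not

`simulate_pieces()` draws lognormal piece masses (defaults: log-mean 0,
log-sd 1 — median 1 g with a long right tail, matching the heavy-tailed
lump sizes of field collections), snapped to the 0.01 g grid, and inclusion
counts from four regimes spanning the uniform-to-concentrated continuum:

| model | mechanism | uniformity knob |
|---|---|---|
| `poisson` | uniform trapping, `N ~ Pois(λ m^β)` | — (the uniform limit) |
| `negative_binomial` | overdispersed, mean `λ m^β`, size `k` | `dispersion_k` (k→∞ is Poisson) |
| `episodic` | sticky window: with prob. `p` a piece traps `Pois(λ m^β)`, else nothing | `sticky_fraction_p` |
| `concentrated` | the collection's Poisson total in one uniformly chosen piece | — (the clustered limit) |

`β ∈ [2/3, 1]` expresses surface- versus volume-proportional trapping,
mirroring the accumulation constraint. Every configuration carries a
mandatory seed; identical configurations are byte-identical through CSV.
`uniformity_sweep()` re-simulates along a grid of the uniformity knob with
a shared mass sample and reports the `b` trajectory, which is monotone in
the knob — the package's central validation.

The simulator reproduces the *statistical* regimes the estimators must
distinguish, and only those. It does not model resin flow or
polymerisation chemistry, arthropod attraction or escape, piece
fragmentation after hardening, or collection bias (beyond what `min_mass_g`
mimics). Passing tests therefore show that the estimators recover the
trapping pattern *given* the model family; they cannot certify that a field
collection satisfies the model assumptions — in real data, mass-dependent
collection bias is visible as a change of slope at small masses and should
be handled with the documented cutoff.

Study conditions used by the validation suite (chosen as realistic field
scales, and kept fixed): 1000 pieces for the concentrated limit, 5000 for
the episodic sweep and the uniform-versus-episodic contrast (intensities
λ = 3 versus λ = 300 at `p = 0.01`, equal expected yields), 10⁴ pieces for
the Poisson-limit bin-by-bin comparison (each bin checked within 3 binomial
standard errors; only bins satisfying the normal-approximation rule
`n·p·(1−p) ≥ 5` are compared), and 100 seeded replicates of 6 + 6 samples
of 500 counts for the two-profile MDS separation (profile Bhattacharyya
divergence 0.196, well above the ~0.15 needed for reliable axis-1
separation at these totals).

## Known limitations

* The exact published exponents for specific field collections depend on
  unstated binning details (aggregation of singleton 0.01 g bins, abscissa
  convention); reproducing a printed value to two decimals requires the
  original piece-level table and the same binning, so the package records
  every binning choice in the fit's settings.
* The box constraint makes `se_beta` at an active bound a one-sided
  quantity; the bootstrap distribution is the honest summary there.
* Bhattacharyya-MDS coordinates are identified only up to rotation and
  reflection; compare configurations by distances or Procrustes, not by
  raw coordinates.
* A sweep point with zero trapping intensity yields an all-empty
  collection whose probability curve is identically 1 — a valid flat fit
  (`b = 0`), reported as such rather than as a failure.
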