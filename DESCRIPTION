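Package: resintrap
Title: Quantitative Taphonomy of Arthropod Entrapment in Tree Resins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical tools for comparing how tree resins trap
    arthropods, aimed at actuotaphonomic studies of amber, copal and
    modern (Defaunation) resin. Estimates the probability that a resin
    piece of a given mass carries no arthropod inclusions via Bayes
    inversion of binned frequencies, and fits a log-log power law whose
    slope b measures the spatial uniformity of trapping. Fits
    count-versus-mass accumulation power laws with the exponent
    box-constrained to the surface-to-volume scaling range [2/3, 1].
    Compares assemblage compositions across trap types with Bhattacharyya
    distances, classical multidimensional scaling, complete-linkage
    clustering under a rank-correlation distance, and flying versus
    non-flying contingency analysis. Includes a seeded simulator of
    resin-trapping regimes (uniform Poisson, overdispersed, episodic
    sticky-window, fully concentrated) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
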