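#' Configuration for the resin-trapping piece simulator
#'
#' Describes one simulated collection of resin pieces. Piece masses are
#' lognormal (heavy-tailed lump sizes), floored and rounded to the 0.01 g
#' recording grid. Inclusion counts follow one of four trapping regimes
#' spanning the uniform-to-concentrated continuum:
#'
#' * `"poisson"` — spatially uniform trapping: `N ~ Poisson(lambda * m^beta)`.
#' * `"negative_binomial"` — overdispersed trapping with mean
#'   `lambda * m^beta` and dispersion `dispersion_k` (k -> Inf recovers the
#'   Poisson model); the canonical continuous uniformity knob.
#' * `"episodic"` — the sticky-window regime of fast-drying resin: with
#'   probability `sticky_fraction_p` a piece was exuded while still sticky
#'   and traps `Poisson(lambda * m^beta)` inclusions, otherwise it traps
#'   nothing.
#' * `"concentrated"` — the extreme clustered limit: the whole collection's
#'   Poisson total is placed in one uniformly chosen piece.
#'
#' @param n_pieces number of pieces.
#' @param mass_log_mean,mass_log_sd lognormal parameters of the piece mass
#'   in grams (defaults 0 and 1: median 1 g, long right tail).
#' @param lambda_per_g trapping intensity (inclusions per gram at 1 g).
#' @param beta mass-scaling exponent in `[2/3, 1]` (surface vs volume
#'   trapping).
#' @param model one of `"poisson"`, `"negative_binomial"`, `"episodic"`,
#'   `"concentrated"`.
#' @param dispersion_k negative-binomial dispersion (required for that
#'   model).
#' @param sticky_fraction_p probability in `(0, 1]` that a piece is exuded
#'   within the sticky window (required for the episodic model).
#' @param seed RNG seed (mandatory: every simulated collection is
#'   reproducible).
#' @return a list of class `trap_sim_config`.
#' @export
trap_sim_config <- function(n_pieces, mass_log_mean = 0, mass_log_sd = 1,
                            lambda_per_g = 1, beta = 1,
                            model = c("poisson", "negative_binomial",
                                      "episodic", "concentrated"),
                            dispersion_k = NULL, sticky_fraction_p = NULL,
                            seed) {
  model <- match.arg(model)
  stopifnot(n_pieces >= 1, mass_log_sd > 0, lambda_per_g >= 0,
            beta >= 2 / 3 - 1e-12, beta <= 1 + 1e-12)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (model == "negative_binomial") {
    if (is.null(dispersion_k) || dispersion_k <= 0)
      stop("negative_binomial model requires dispersion_k > 0")
  }
  if (model == "episodic") {
    if (is.null(sticky_fraction_p) || sticky_fraction_p <= 0 ||
        sticky_fraction_p > 1)
      stop("episodic model requires sticky_fraction_p in (0, 1]")
  }
  structure(list(n_pieces = as.integer(n_pieces),
                 mass_log_mean = mass_log_mean, mass_log_sd = mass_log_sd,
                 lambda_per_g = lambda_per_g, beta = beta, model = model,
                 dispersion_k = dispersion_k,
                 sticky_fraction_p = sticky_fraction_p,
                 seed = as.integer(seed)),
            class = "trap_sim_config")
}

#' Simulate a collection of resin pieces
#'
#' @param config a [trap_sim_config()].
#' @return a [piece_collection]; identical config (including seed) gives an
#'   identical collection.
#' @examples
#' pc <- simulate_pieces(trap_sim_config(100, lambda_per_g = 2,
#'                                       model = "poisson", seed = 1))
#' mean(pc$n_inclusions == 0)
#' @export
simulate_pieces <- function(config) {
  stopifnot(inherits(config, "trap_sim_config"))
  set.seed(config$seed)
  n <- config$n_pieces
  m <- pmax(round_mass(stats::rlnorm(n, config$mass_log_mean,
                                     config$mass_log_sd)), 0.01)
  mu <- config$lambda_per_g * m^config$beta
  counts <- switch(config$model,
    poisson = stats::rpois(n, mu),
    negative_binomial = stats::rnbinom(n, size = config$dispersion_k, mu = mu),
    episodic = stats::rbinom(n, 1L, config$sticky_fraction_p) *
      stats::rpois(n, mu),
    concentrated = {
      total <- stats::rpois(1L, sum(mu))
      cnt <- integer(n)
      cnt[sample.int(n, 1L)] <- total
      cnt
    })
  piece_collection(m, counts,
                   label = sprintf("sim_%s_seed%d", config$model, config$seed),
                   tree_group = "other", resin_class = "defaunation")
}

#' Configuration for the taxon-composition simulator
#'
#' Each trap type (resin, yellow sticky trap, Malaise trap) has a
#' multinomial taxon profile; every simulated sample of a type draws its
#' taxon counts from that profile.
#'
#' @param profiles named list of probability vectors (one per trap type,
#'   e.g. `resin`, `yellow_sticky`, `malaise`), all over the same taxa and
#'   each summing to 1. Taxon names are taken from the first profile.
#' @param totals named numeric vector, total count per sample for each trap
#'   type (recycled over that type's samples).
#' @param n_samples named integer vector, samples per trap type.
#' @param seed RNG seed (mandatory).
#' @return a list of class `composition_sim_config`.
#' @export
composition_sim_config <- function(profiles, totals, n_samples, seed) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            !is.null(names(profiles)))
  len <- unique(vapply(profiles, length, integer(1)))
  if (length(len) != 1L) stop("profiles must cover the same taxon set")
  for (p in profiles) {
    stopifnot(all(p >= 0))
    if (abs(sum(p) - 1) > 1e-8) stop("each profile must sum to 1")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  types <- names(profiles)
  stopifnot(all(types %in% names(totals)), all(types %in% names(n_samples)),
            all(totals >= 0), all(n_samples >= 1))
  structure(list(profiles = profiles, totals = totals,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "composition_sim_config")
}

#' Simulate a samples-by-taxa count matrix
#'
#' @param config a [composition_sim_config()].
#' @param level taxonomic level label for the result.
#' @return a `taxon_counts` matrix; sample ids are `<type>_<i>`.
#' @export
simulate_taxon_counts <- function(config, level = "order") {
  stopifnot(inherits(config, "composition_sim_config"))
  set.seed(config$seed)
  taxa <- names(config$profiles[[1L]])
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_along(config$profiles[[1L]]))
  rows <- list()
  for (type in names(config$profiles)) {
    prof <- config$profiles[[type]]
    for (i in seq_len(config$n_samples[[type]])) {
      cnt <- as.integer(stats::rmultinom(1L, config$totals[[type]], prof))
      rows[[sprintf("%s_%d", type, i)]] <- cnt
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- taxa
  taxon_counts(m, level = level)
}

#' Sweep the uniformity knob and track the fitted exponent
#'
#' Runs [simulate_pieces()] + [uniformity_exponent()] for each value of the
#' model's uniformity parameter (`sticky_fraction_p` for the episodic
#' model, `dispersion_k` for the negative binomial), holding the intensity,
#' mass distribution and seed fixed so the grid points share one mass
#' sample. As the parameter moves towards the uniform regime, the fitted
#' `b` is expected to become more negative (larger `|b|`).
#'
#' @param base a [trap_sim_config()] of the episodic or negative_binomial
#'   model; its uniformity parameter is overridden per grid point.
#' @param grid numeric vector of parameter values, sorted ascending in
#'   uniformity.
#' @param log_bins,fit_min_mass_g passed to [uniformity_exponent()]
#'   (logarithmic binning is the sensible choice at simulator sample
#'   sizes).
#' @return data.frame with columns `param`, `b`, `se_b`, `n_bins_used`,
#'   `error` (NA, or the error message if a grid point could not be
#'   fitted).
#' @export
uniformity_sweep <- function(base, grid, log_bins = 12, fit_min_mass_g = NULL) {
  stopifnot(inherits(base, "trap_sim_config"),
            base$model %in% c("episodic", "negative_binomial"))
  knob <- if (base$model == "episodic") "sticky_fraction_p" else "dispersion_k"
  out <- lapply(grid, function(v) {
    cfg <- unclass(base)
    cfg[[knob]] <- v
    cfg <- do.call(trap_sim_config, cfg)
    res <- tryCatch({
      pc <- simulate_pieces(cfg)
      fit <- uniformity_exponent(pc, log_bins = log_bins,
                                 fit_min_mass_g = fit_min_mass_g)
      data.frame(param = v, b = fit$b, se_b = fit$se_b,
                 n_bins_used = fit$n_bins_used, error = NA_character_)
    }, error = function(e) {
      data.frame(param = v, b = NA_real_, se_b = NA_real_,
                 n_bins_used = NA_integer_, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, out)
}
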