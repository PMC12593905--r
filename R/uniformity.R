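#' Estimate P(no inclusions | piece mass) by Bayes inversion
#'
#' Bins piece masses, then inverts the empirical conditional: from the mass
#' density of empty pieces `f(m | empty)`, the overall mass density `f(m)`
#' and the marginal empty fraction `P(empty)`, Bayes' theorem gives
#' `P(empty | m) = f(m | empty) * P(empty) / f(m)` per bin. Algebraically
#' this reduces to the direct conditional frequency `n_empty / n_total`
#' within each bin, which the returned object satisfies to machine
#' precision.
#'
#' Two binning schemes are offered: fixed-width bins (default width 0.01 g,
#' the recording resolution of the masses) and logarithmic bins (equal width
#' in `log(m)`), recommended for collections with fewer than ~1000 pieces
#' where 0.01 g bins are mostly singletons.
#'
#' @param collection a [piece_collection].
#' @param bin_width_g fixed bin width in grams (ignored if `log_bins` set).
#' @param min_mass_g optional lower mass cutoff; pieces below it are dropped
#'   before binning (used for collections with a collection bias against
#'   small pieces).
#' @param log_bins optional integer: number of logarithmic bins spanning the
#'   observed mass range. `NULL` (default) selects fixed-width binning.
#' @param midpoint `"arithmetic"` (default) or `"geometric"` bin abscissa.
#' @return object of class `empty_mass_pdf`: a list with `bins` (data.frame
#'   with `lower_g`, `upper_g`, `mid_g`, `n_total`, `n_empty`, `p_empty`;
#'   `p_empty` is `NA` for unoccupied bins), `p_empty_marginal`, `n_pieces`,
#'   `n_excluded` (below cutoff) and the binning `settings`.
#' @examples
#' pc <- piece_collection(c(1, 1, 2, 2, 2), c(0L, 1L, 0L, 0L, 3L))
#' pdf <- estimate_empty_pdf(pc)
#' pdf$p_empty_marginal               # 0.6
#' subset(pdf$bins, n_total > 0)$p_empty  # 0.5, 2/3
#' @export
estimate_empty_pdf <- function(collection, bin_width_g = 0.01,
                               min_mass_g = NULL, log_bins = NULL,
                               midpoint = c("arithmetic", "geometric")) {
  stopifnot(inherits(collection, "piece_collection"))
  midpoint <- match.arg(midpoint)
  if (!is.null(log_bins)) stopifnot(log_bins >= 1)
  stopifnot(bin_width_g > 0)
  m <- collection$mass_g
  empty <- collection$n_inclusions == 0L
  n_excluded <- 0L
  if (!is.null(min_mass_g)) {
    keep <- m >= min_mass_g
    n_excluded <- sum(!keep)
    m <- m[keep]; empty <- empty[keep]
  }
  if (length(m) == 0L) stop("no pieces left to bin (empty collection or cutoff too high)")

  if (is.null(log_bins)) {
    # bins anchored at zero: bin k covers [k*w, (k+1)*w)
    idx <- floor(m / bin_width_g + 1e-9)
    lo <- idx * bin_width_g
    all_idx <- seq.int(min(idx), max(idx))
    edges_lo <- all_idx * bin_width_g
    edges_hi <- edges_lo + bin_width_g
    pos <- match(idx, all_idx)
  } else {
    edges <- exp(seq(log(min(m)), log(max(m)), length.out = log_bins + 1L))
    edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
    pos <- findInterval(m, edges, rightmost.closed = TRUE)
    pos[pos > log_bins] <- log_bins
    edges_lo <- edges[-length(edges)]
    edges_hi <- edges[-1L]
  }
  nb <- length(edges_lo)
  n_total <- tabulate(pos, nbins = nb)
  n_empty <- tabulate(pos[empty], nbins = nb)

  # Bayes inversion: P(empty|m) = f(m|empty) P(empty) / f(m)
  n <- length(m)
  n_emp <- sum(empty)
  p_empty_marg <- n_emp / n
  f_m <- n_total / n
  p_empty <- rep(NA_real_, nb)
  occ <- n_total > 0L
  if (n_emp > 0L) {
    f_m_empty <- n_empty / n_emp
    p_empty[occ] <- f_m_empty[occ] * p_empty_marg / f_m[occ]
  } else {
    p_empty[occ] <- 0
  }

  mid <- if (midpoint == "arithmetic") (edges_lo + edges_hi) / 2 else
    sqrt(edges_lo * edges_hi)
  bins <- data.frame(lower_g = edges_lo, upper_g = edges_hi, mid_g = mid,
                     n_total = n_total, n_empty = n_empty, p_empty = p_empty)
  structure(list(bins = bins,
                 p_empty_marginal = p_empty_marg,
                 n_pieces = n, n_excluded = n_excluded,
                 settings = list(bin_width_g = bin_width_g,
                                 min_mass_g = min_mass_g,
                                 log_bins = log_bins,
                                 midpoint = midpoint)),
            class = "empty_mass_pdf")
}

#' @export
print.empty_mass_pdf <- function(x, ...) {
  occ <- x$bins[x$bins$n_total > 0L, ]
  cat(sprintf("Empty-piece PDF: %d pieces in %d occupied bins (of %d); P(empty) = %.4f\n",
              x$n_pieces, nrow(occ), nrow(x$bins), x$p_empty_marginal))
  if (x$n_excluded > 0L)
    cat(sprintf("  %d piece(s) below the %.2f g cutoff excluded\n",
                x$n_excluded, x$settings$min_mass_g))
  invisible(x)
}

#' Fit a power law to the empty-piece probability curve
#'
#' Ordinary least squares of `log P(empty | m)` on `log m` over the occupied
#' bins, using the model `log P = log(a) + b log(m)`. The slope `b` is the
#' uniformity exponent: values near 0 indicate inclusions concentrated in
#' few pieces, strongly negative values a spatially uniform trapping process
#' (the uniform Poisson limit decays exponentially, i.e. an effectively
#' infinite exponent). Bins with `P = 0` cannot enter a log fit and are
#' dropped, never pseudo-counted; their number is recorded.
#'
#' @param pdf an [estimate_empty_pdf()] result.
#' @param min_mass_g optional lower cutoff applied to bin midpoints before
#'   fitting (in addition to any cutoff applied at binning time).
#' @return object of class `power_law_fit`: list with `log_a`, `b`, `se_b`,
#'   `r_squared`, `n_bins_used`, `n_bins_dropped` (occupied bins with P = 0
#'   or below cutoff), `mass_range_g`, the fitted points (`log_m`, `log_p`,
#'   weights `n_total`) and `settings`.
#' @examples
#' pc <- piece_collection(rep(c(1, 2, 4, 8), each = 4),
#'                        rep(c(0L, 0L, 0L, 1L), 4))
#' fit_power_law(estimate_empty_pdf(pc, log_bins = 4))
#' @export
fit_power_law <- function(pdf, min_mass_g = NULL) {
  stopifnot(inherits(pdf, "empty_mass_pdf"))
  b <- pdf$bins
  occ <- b$n_total > 0L
  use <- occ & !is.na(b$p_empty) & b$p_empty > 0
  if (!is.null(min_mass_g)) use <- use & b$mid_g >= min_mass_g
  n_dropped <- sum(occ) - sum(use)
  if (sum(use) < 3L)
    stop("insufficient data: need at least 3 bins with positive P(empty|m), have ",
         sum(use))
  log_m <- log(b$mid_g[use])
  log_p <- log(b$p_empty[use])
  fit <- stats::lm(log_p ~ log_m)
  sm <- suppressWarnings(summary(fit))  # exact power laws trip the perfect-fit warning
  cf <- sm$coefficients
  r2 <- if (stats::var(log_p) == 0) 1 else sm$r.squared
  structure(list(log_a = unname(cf[1L, 1L]),
                 b = unname(cf[2L, 1L]),
                 se_b = unname(cf[2L, 2L]),
                 r_squared = r2,
                 n_bins_used = sum(use),
                 n_bins_dropped = n_dropped,
                 mass_range_g = range(b$mid_g[use]),
                 log_m = log_m, log_p = log_p,
                 n_total = b$n_total[use],
                 settings = c(pdf$settings, list(fit_min_mass_g = min_mass_g))),
            class = "power_law_fit")
}

#' Uniformity exponent of a piece collection
#'
#' One-call pipeline: estimate the empty-piece probability curve by Bayes
#' inversion of binned frequencies, then fit the log-log power law. The
#' returned exponent `b` measures the spatial uniformity of arthropod
#' inclusions: `b` near 0 means the inclusions sit in a few pieces
#' (clustered trapping, the fast-drying regime), strongly negative `b`
#' means trapping was uniform over the resin surface.
#'
#' @inheritParams estimate_empty_pdf
#' @param fit_min_mass_g optional cutoff on bin midpoints at fit time.
#' @param bootstrap number of piece-level bootstrap replicates for `se_b`
#'   (resample pieces, re-bin, re-fit). 0 (default) reports the OLS slope
#'   standard error only; binned points violate OLS independence, so the
#'   bootstrap is recommended for publication-grade uncertainty.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `c("uniformity_fit", "power_law_fit")`; as
#'   [fit_power_law()] plus `se_b_boot` (if bootstrapped), the `pdf` used,
#'   and the collection label in `settings`.
#' @examples
#' set.seed(1)
#' pc <- simulate_pieces(trap_sim_config(n_pieces = 2000, lambda_per_g = 2,
#'                                       model = "poisson", seed = 7))
#' uniformity_exponent(pc, log_bins = 12)
#' @export
uniformity_exponent <- function(collection, bin_width_g = 0.01,
                                min_mass_g = NULL, log_bins = NULL,
                                midpoint = c("arithmetic", "geometric"),
                                fit_min_mass_g = NULL,
                                bootstrap = 0, seed = NULL) {
  midpoint <- match.arg(midpoint)
  pdf <- estimate_empty_pdf(collection, bin_width_g = bin_width_g,
                            min_mass_g = min_mass_g, log_bins = log_bins,
                            midpoint = midpoint)
  fit <- fit_power_law(pdf, min_mass_g = fit_min_mass_g)
  fit$pdf <- pdf
  fit$settings$label <- attr(collection, "label")
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- vapply(seq_len(bootstrap), function(i) {
      idx <- sample.int(nrow(collection), replace = TRUE)
      pc <- piece_collection(collection$mass_g[idx],
                             collection$n_inclusions[idx])
      tryCatch({
        p <- estimate_empty_pdf(pc, bin_width_g = bin_width_g,
                                min_mass_g = min_mass_g, log_bins = log_bins,
                                midpoint = midpoint)
        fit_power_law(p, min_mass_g = fit_min_mass_g)$b
      }, error = function(e) NA_real_)
    }, numeric(1))
    fit$se_b_boot <- stats::sd(bs, na.rm = TRUE)
    fit$n_boot_ok <- sum(!is.na(bs))
  }
  class(fit) <- c("uniformity_fit", "power_law_fit")
  fit
}

#' Closed-form empty-piece probability under uniform Poisson trapping
#'
#' Under spatially uniform trapping with intensity `lambda_per_g` and
#' mass-scaling exponent `beta` (2/3 for purely surface trapping, 1 for
#' volume scaling), the inclusion count of a piece of mass `m` is
#' Poisson(`lambda * m^beta`), so
#' `P(empty | m) = exp(-lambda * m^beta)`. Used as the analytic oracle for
#' the uniform limit.
#'
#' @param lambda_per_g trapping intensity, inclusions per gram (>= 0).
#' @param beta mass-scaling exponent in `[2/3, 1]`.
#' @param m piece mass in grams (> 0); vectorised.
#' @return `P(empty | m)` in `[0, 1]`.
#' @examples
#' analytic_empty_prob(1, 1, 1)  # exp(-1)
#' @export
analytic_empty_prob <- function(lambda_per_g, beta, m) {
  stopifnot(lambda_per_g >= 0, beta >= 2 / 3 - 1e-12, beta <= 1 + 1e-12,
            all(m > 0))
  exp(-lambda_per_g * m^beta)
}

# ---- methods for power_law_fit / uniformity_fit ----

#' @export
print.power_law_fit <- function(x, ...) {
  lbl <- x$settings$label
  cat("Power-law fit of P(empty | m): log P = log(a) + b log(m)\n")
  if (!is.null(lbl)) cat("  collection:", lbl, "\n")
  cat(sprintf("  b (uniformity exponent) = %.4f  (OLS se = %.4f%s)\n",
              x$b, x$se_b,
              if (!is.null(x$se_b_boot))
                sprintf(", bootstrap se = %.4f", x$se_b_boot) else ""))
  cat(sprintf("  log(a) = %.4f,  r^2 = %.4f\n", x$log_a, x$r_squared))
  cat(sprintf("  %d bins used (%d occupied bins dropped), mass range %.2f-%.2f g\n",
              x$n_bins_used, x$n_bins_dropped,
              x$mass_range_g[1], x$mass_range_g[2]))
  invisible(x)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  print(object)
  cat("\nInterpretation: b near 0 -> inclusions concentrated in few pieces;\n")
  cat("strongly negative b -> spatially uniform trapping (Poisson limit is\n")
  cat("an exponential decay, i.e. effectively infinite |b|).\n")
  invisible(object)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(log_a = object$log_a, b = object$b)
}

#' Predicted empty-piece probability from a fitted power law
#'
#' @param object a `power_law_fit`.
#' @param newdata optional data.frame with column `mass_g` (or a numeric
#'   vector of masses); defaults to the fitted bin midpoints.
#' @param ... unused.
#' @return predicted `P(empty | m)`, capped at 1.
#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  m <- if (is.null(newdata)) exp(object$log_m)
  else if (is.data.frame(newdata)) newdata$mass_g
  else as.numeric(newdata)
  stopifnot(all(m > 0))
  pmin(exp(object$log_a + object$b * log(m)), 1)
}

#' @export
residuals.power_law_fit <- function(object, ...) {
  object$log_p - (object$log_a + object$b * object$log_m)
}

#' Log-log plot of the empty-piece probability and its power-law fit
#'
#' @param x a `power_law_fit`.
#' @param ... passed to [plot()].
#' @export
plot.power_law_fit <- function(x, ...) {
  plot(exp(x$log_m), exp(x$log_p), log = "xy",
       xlab = "piece mass m (g)", ylab = "P(empty | m)",
       main = sprintf("Uniformity exponent b = %.2f", x$b), ...)
  mm <- exp(seq(min(x$log_m), max(x$log_m), length.out = 100))
  graphics::lines(mm, exp(x$log_a + x$b * log(mm)), col = "red3")
  invisible(x)
}
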