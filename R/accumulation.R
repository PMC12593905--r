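#' Fit a count-versus-mass accumulation power law, N = c * m^beta
#'
#' Models the number of arthropod inclusions recovered from a resin
#' collection as a power law of the inspected resin mass, with the exponent
#' box-constrained to `[2/3, 1]`: `beta = 2/3` corresponds to trapping that
#' scales with the surface of a lump (area ~ mass^(2/3)), `beta = 1` to
#' volume scaling. The fit is least squares of `log N` on `log m`
#' (clip-and-refit: if the unconstrained slope falls outside the bounds,
#' `beta` is fixed at the violated bound and the prefactor refitted alone).
#' Zero-count samples cannot enter a log-space fit and are excluded (their
#' number is recorded); a Poisson-regression mode (`method = "poisson"`,
#' log link) is available for zero-heavy data.
#'
#' @param mass_g positive numeric vector of collection masses (grams), or a
#'   data.frame with columns `mass_g`/`total_mass_g` and
#'   `n_inclusions`/`total_inclusions` (e.g. rows of
#'   [load_locality_table()]).
#' @param n_inclusions non-negative counts (ignored if `mass_g` is a
#'   data.frame).
#' @param bounds length-2 numeric, the allowed exponent range.
#' @param method `"loglog"` (default) or `"poisson"` (GLM, log link,
#'   zero counts retained).
#' @param bootstrap case-resampling bootstrap replicates for `se_beta`
#'   (default 1000; 0 disables, falling back to the OLS/GLM slope se).
#' @param seed RNG seed for the bootstrap.
#' @param group optional group label stored on the fit.
#' @return object of class `accumulation_fit`: list with `c`, `beta`,
#'   `se_beta`, `active_bound` (`"none"`, `"lower"` or `"upper"`),
#'   `n_samples` (points used), `n_zero_excluded`, `bounds`, `method`,
#'   `group` and the points used.
#' @examples
#' fit_accumulation(c(10, 100, 1000), 2 * c(10, 100, 1000)^0.8)
#' @export
fit_accumulation <- function(mass_g, n_inclusions = NULL,
                             bounds = c(2 / 3, 1),
                             method = c("loglog", "poisson"),
                             bootstrap = 1000, seed = NULL, group = NULL) {
  method <- match.arg(method)
  if (is.data.frame(mass_g)) {
    df <- mass_g
    m <- if (!is.null(df$total_mass_g)) df$total_mass_g else df$mass_g
    n <- if (!is.null(df$total_inclusions)) df$total_inclusions else df$n_inclusions
  } else {
    m <- as.numeric(mass_g); n <- as.numeric(n_inclusions)
  }
  stopifnot(length(m) == length(n), all(m > 0), all(n >= 0),
            length(bounds) == 2L, bounds[1] < bounds[2])

  core <- function(m, n) {
    if (method == "loglog") {
      keep <- n > 0
      m2 <- m[keep]; n2 <- n[keep]
      if (length(m2) < 3L)
        stop("insufficient data: need at least 3 positive-count points, have ",
             length(m2))
      if (stats::var(log(m2)) == 0) stop("singular fit: identical masses")
      fit <- stats::lm(log(n2) ~ log(m2))
      beta_hat <- unname(stats::coef(fit)[2L])
      se_slope <- suppressWarnings(summary(fit))$coefficients[2L, 2L]
      if (beta_hat < bounds[1] || beta_hat > bounds[2]) {
        beta <- if (beta_hat < bounds[1]) bounds[1] else bounds[2]
        log_c <- mean(log(n2) - beta * log(m2))
      } else {
        beta <- beta_hat
        log_c <- unname(stats::coef(fit)[1L])
      }
      list(beta = beta, log_c = log_c, se_slope = se_slope,
           n_used = length(m2), n_zero = sum(!keep))
    } else {
      if (length(m) < 3L) stop("insufficient data: need at least 3 points")
      if (stats::var(log(m)) == 0) stop("singular fit: identical masses")
      lm_ <- log(m)
      fit <- stats::glm(n ~ lm_, family = stats::poisson())
      beta_hat <- unname(stats::coef(fit)[2L])
      se_slope <- summary(fit)$coefficients[2L, 2L]
      if (beta_hat < bounds[1] || beta_hat > bounds[2]) {
        beta <- if (beta_hat < bounds[1]) bounds[1] else bounds[2]
        fit0 <- stats::glm(n ~ 1 + offset(beta * lm_), family = stats::poisson())
        log_c <- unname(stats::coef(fit0)[1L])
      } else {
        beta <- beta_hat
        log_c <- unname(stats::coef(fit)[1L])
      }
      list(beta = beta, log_c = log_c, se_slope = se_slope,
           n_used = length(m), n_zero = 0L)
    }
  }

  est <- core(m, n)
  se_beta <- est$se_slope
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- vapply(seq_len(bootstrap), function(i) {
      idx <- sample.int(length(m), replace = TRUE)
      tryCatch(core(m[idx], n[idx])$beta, error = function(e) NA_real_)
    }, numeric(1))
    se_beta <- stats::sd(bs, na.rm = TRUE)
  }
  tol <- 1e-9
  active <- if (abs(est$beta - bounds[1]) <= tol) "lower"
  else if (abs(est$beta - bounds[2]) <= tol) "upper" else "none"
  structure(list(c = exp(est$log_c), beta = est$beta, se_beta = se_beta,
                 active_bound = active, n_samples = est$n_used,
                 n_zero_excluded = est$n_zero, bounds = bounds,
                 method = method, group = group,
                 mass_g = m, n_inclusions = n),
            class = "accumulation_fit")
}

#' Fit accumulation power laws per source-tree group
#'
#' Splits locality summaries into groups and fits one constrained
#' accumulation power law per group. The default grouping pools
#' `agathis`, `agathis_like` and `cheirolepidiaceae` sources into an
#' `agathis_family` group (these resins are chemically alike and plot as
#' one trend), against `hymenaea`. Groups with too few usable points are
#' reported as errors in place of a fit, without aborting the others.
#'
#' @param summaries a `locality_summary` data.frame (see
#'   [load_locality_table()]).
#' @param grouping named character vector mapping `tree_group` values to
#'   output groups; localities whose `tree_group` is unmapped raise an
#'   error.
#' @param ... passed to [fit_accumulation()].
#' @return named list of `accumulation_fit` objects (or `try-error`
#'   conditions for groups that could not be fitted).
#' @examples
#' fits <- fit_groups(load_locality_table(), bootstrap = 0)
#' sapply(fits, function(f) f$beta)
#' @export
fit_groups <- function(summaries,
                       grouping = c(agathis = "agathis_family",
                                    agathis_like = "agathis_family",
                                    cheirolepidiaceae = "agathis_family",
                                    hymenaea = "hymenaea"),
                       ...) {
  tg <- summaries$tree_group
  unmapped <- setdiff(unique(tg), names(grouping))
  if (length(unmapped))
    stop("unmapped tree group(s): ", paste(unmapped, collapse = ", "))
  groups <- unname(grouping[tg])
  out <- lapply(unique(groups), function(g) {
    rows <- summaries[groups == g, , drop = FALSE]
    tryCatch(fit_accumulation(rows, group = g, ...),
             error = function(e) {
               warning("group '", g, "' not fitted: ", conditionMessage(e),
                       call. = FALSE)
               e
             })
  })
  stats::setNames(out, unique(groups))
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat("Accumulation power law: N = c * m^beta, beta constrained to [",
      sprintf("%.4g, %.4g", x$bounds[1], x$bounds[2]), "]\n", sep = "")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  cat(sprintf("  c = %.4g,  beta = %.4f (se = %.4f), bound active: %s\n",
              x$c, x$beta, x$se_beta, x$active_bound))
  cat(sprintf("  %d points used (%d zero-count excluded), method %s\n",
              x$n_samples, x$n_zero_excluded, x$method))
  invisible(x)
}

#' @export
summary.accumulation_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.accumulation_fit <- function(object, ...) {
  c(c = object$c, beta = object$beta)
}

#' Predicted inclusion counts from an accumulation fit
#'
#' @param object an `accumulation_fit`.
#' @param newdata data.frame with column `mass_g`, or a numeric mass vector;
#'   defaults to the fitted masses.
#' @param ... unused.
#' @return expected inclusion counts `c * m^beta`.
#' @export
predict.accumulation_fit <- function(object, newdata = NULL, ...) {
  m <- if (is.null(newdata)) object$mass_g
  else if (is.data.frame(newdata)) newdata$mass_g
  else as.numeric(newdata)
  stopifnot(all(m > 0))
  object$c * m^object$beta
}

#' Log-log plot of counts vs mass with the fitted accumulation curve
#'
#' @param x an `accumulation_fit`.
#' @param ... passed to [plot()].
#' @export
plot.accumulation_fit <- function(x, ...) {
  keep <- x$n_inclusions > 0
  plot(x$mass_g[keep], x$n_inclusions[keep], log = "xy",
       xlab = "resin mass (g)", ylab = "arthropod inclusions",
       main = sprintf("N = %.3g m^%.2f%s", x$c, x$beta,
                      if (!is.null(x$group)) paste0(" (", x$group, ")") else ""),
       ...)
  mm <- exp(seq(log(min(x$mass_g)), log(max(x$mass_g)), length.out = 100))
  graphics::lines(mm, x$c * mm^x$beta, col = "red3")
  invisible(x)
}
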