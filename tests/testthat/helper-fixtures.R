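# Build an empty_mass_pdf by hand, for fits on exactly known curves
make_empty_pdf <- function(mid_g, p_empty, n_total = 100L) {
  n_total <- rep_len(n_total, length(mid_g))
  bins <- data.frame(lower_g = mid_g * 0.99, upper_g = mid_g * 1.01,
                     mid_g = mid_g, n_total = n_total,
                     n_empty = round(p_empty * n_total),
                     p_empty = p_empty)
  structure(list(bins = bins,
                 p_empty_marginal = sum(bins$n_empty) / sum(n_total),
                 n_pieces = sum(n_total), n_excluded = 0L,
                 settings = list(bin_width_g = NA, min_mass_g = NULL,
                                 log_bins = NULL, midpoint = "arithmetic")),
            class = "empty_mass_pdf")
}

# Brute-force oracle for the box-constrained log-log accumulation fit:
# dense beta grid, closed-form prefactor per beta, minimise log-space SSE
grid_fit_oracle <- function(mass_g, n, betas = seq(2 / 3, 1, by = 5e-4)) {
  keep <- n > 0
  m <- mass_g[keep]; n <- n[keep]
  sse <- vapply(betas, function(b) {
    # at fixed beta the OLS intercept is the mean residual
    lc <- mean(log(n) - b * log(m))
    sum((log(n) - lc - b * log(m))^2)
  }, numeric(1))
  b <- betas[which.min(sse)]
  c(beta = b, c = exp(mean(log(n) - b * log(m))))
}

# Mean silhouette width of a 1-d embedding under known group labels
mean_silhouette <- function(x, groups) {
  sil <- cluster::silhouette(as.integer(factor(groups)), stats::dist(x))
  mean(sil[, "sil_width"])
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
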