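test_that("simulation is reproducible, byte-identical through CSV", {
  cfg <- trap_sim_config(500, model = "negative_binomial", lambda_per_g = 1.5,
                         dispersion_k = 0.5, seed = 99)
  a <- simulate_pieces(cfg)
  b <- simulate_pieces(cfg)
  expect_identical(a$mass_g, b$mass_g)
  expect_identical(a$n_inclusions, b$n_inclusions)
  fa <- tempfile(); fb <- tempfile()
  write_piece_table(a, fa); write_piece_table(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("model parameter validation catches invalid combinations", {
  expect_error(trap_sim_config(10, model = "negative_binomial", seed = 1),
               "dispersion_k")
  expect_error(trap_sim_config(10, model = "episodic", seed = 1,
                               sticky_fraction_p = 0), "sticky_fraction_p")
  expect_error(trap_sim_config(10, model = "poisson"), "seed")
  expect_error(trap_sim_config(10, model = "poisson", beta = 0.5, seed = 1))
})

test_that("zero intensity traps nothing; concentrated loads exactly one piece", {
  for (mod in c("poisson", "negative_binomial", "episodic")) {
    cfg <- trap_sim_config(200, model = mod, lambda_per_g = 0, seed = 3,
                           dispersion_k = 1, sticky_fraction_p = 0.5)
    expect_true(all(simulate_pieces(cfg)$n_inclusions == 0L))
  }
  pc <- simulate_pieces(trap_sim_config(1000, model = "concentrated",
                                        lambda_per_g = 1, seed = 4))
  expect_equal(sum(pc$n_inclusions > 0L), 1L)
})

test_that("Poisson regime matches its moments and closed-form empty fraction", {
  # masses pinned to 1 g: empty fraction within 3 binomial SE of exp(-1)
  cfg <- trap_sim_config(10000, mass_log_mean = 0, mass_log_sd = 1e-9,
                         lambda_per_g = 1, beta = 1, model = "poisson",
                         seed = 17)
  pc <- simulate_pieces(cfg)
  expect_true(all(pc$mass_g == 1))
  p <- exp(-1)
  expect_lt(abs(mean(pc$n_inclusions == 0L) - p), 3 * sqrt(p * (1 - p) / 10000))

  # mean count matches lambda * E[m^beta] within 3 empirical SE
  cfg2 <- trap_sim_config(20000, lambda_per_g = 2, beta = 0.8,
                          model = "poisson", seed = 23)
  pc2 <- simulate_pieces(cfg2)
  target <- 2 * mean(pc2$mass_g^0.8)
  se <- stats::sd(pc2$n_inclusions) / sqrt(20000)
  expect_lt(abs(mean(pc2$n_inclusions) - target), 3 * se)
})

test_that("episodic regime keeps at least 1 - p of pieces empty", {
  for (s in 1:5) {
    p <- 0.3
    pc <- simulate_pieces(trap_sim_config(2000, model = "episodic",
                                          lambda_per_g = 50,
                                          sticky_fraction_p = p, seed = s))
    expect_gte(mean(pc$n_inclusions == 0L), 1 - p - 3 * sqrt(p * (1 - p) / 2000))
    # with huge lambda nearly every sticky piece traps: empty fraction ~ 1 - p
    expect_lt(abs(mean(pc$n_inclusions == 0L) - (1 - p)), 0.05)
  }
})

test_that("taxon count simulation honours totals, degenerate profiles and seeds", {
  cfg <- composition_sim_config(
    profiles = list(resin = c(A = 1, B = 0, C = 0),
                    malaise = c(A = 0.2, B = 0.3, C = 0.5)),
    totals = c(resin = 100, malaise = 0),
    n_samples = c(resin = 2, malaise = 1), seed = 6)
  tc <- simulate_taxon_counts(cfg)
  expect_equal(unname(tc["resin_1", ]), c(100L, 0L, 0L))
  expect_equal(unname(rowSums(tc)), c(100, 100, 0))
  expect_identical(simulate_taxon_counts(cfg), tc)

  expect_error(composition_sim_config(
    profiles = list(a = c(0.5, 0.5), b = c(1, 0, 0)),
    totals = c(a = 1, b = 1), n_samples = c(a = 1, b = 1), seed = 1),
    "same taxon set")
  expect_error(composition_sim_config(
    profiles = list(a = c(0.5, 0.4)), totals = c(a = 1),
    n_samples = c(a = 1), seed = 1), "sum to 1")
})

test_that("between-type distances exceed within-type distances for distinct profiles", {
  p1 <- c(A = 0.45, B = 0.3, C = 0.15, D = 0.1)
  p2 <- c(A = 0.2, B = 0.2, C = 0.3, D = 0.3)
  wins <- vapply(1:100, function(s) {
    cfg <- composition_sim_config(list(resin = p1, sticky = p2),
                                  totals = c(resin = 500, sticky = 500),
                                  n_samples = c(resin = 3, sticky = 3),
                                  seed = 1000 + s)
    tc <- simulate_taxon_counts(cfg)
    d <- as.matrix(taxon_distance(tc, "bhattacharyya"))
    grp <- rep(c(1, 2), each = 3)
    between <- mean(d[grp == 1, grp == 2])
    within <- mean(d[outer(grp, grp, "==") & upper.tri(d)])
    between > within
  }, logical(1))
  expect_gt(mean(wins), 0.95)
})

test_that("the uniformity sweep reports one row per grid point and propagates failures", {
  base <- trap_sim_config(3000, model = "episodic", lambda_per_g = 3,
                          sticky_fraction_p = 0.5, seed = 11)
  one <- uniformity_sweep(base, 0.5)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$error))

  dead <- trap_sim_config(50, model = "episodic", lambda_per_g = 0,
                          sticky_fraction_p = 0.5, seed = 11)
  res <- uniformity_sweep(dead, c(0.2, 0.8), log_bins = 3)
  expect_equal(nrow(res), 2L)
  # lambda = 0 means every piece is empty: the flat all-one curve still fits (b = 0)
  expect_true(all(res$b == 0 | !is.na(res$error)))
})
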