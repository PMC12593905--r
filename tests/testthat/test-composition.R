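test_that("profile normalisation applies the pseudocount and sums to one", {
  expect_equal(unname(normalize_profiles(matrix(c(3, 1), 1), 0)[1, ]),
               c(0.75, 0.25))
  expect_equal(unname(normalize_profiles(matrix(c(0, 0), 1), 0.5)[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(normalize_profiles(matrix(c(9, 1), 1), 0.5)[1, ]),
               c(9.5 / 11, 1.5 / 11))
  expect_error(normalize_profiles(matrix(numeric(0), 1, 0)), "empty taxon")
  expect_error(normalize_profiles(matrix(c(0, 0), 1), 0), "zero total")
})

test_that("Bhattacharyya distance matches hand values and its metric properties", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(bhattacharyya_distance(p, p), 0)
  expect_equal(bhattacharyya_distance(p, q),
               -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_lt(abs(bhattacharyya_distance(p, q) - 0.111572), 1e-6)
  expect_equal(bhattacharyya_distance(c(1, 0), c(0, 1)), 50)  # disjoint -> cap
  expect_error(bhattacharyya_distance(c(1, 0), c(0.5, 0.3, 0.2)), "different")

  set.seed(12)
  for (i in 1:20) {
    a <- as.vector(rmultinom(1, 100, runif(5))) + 0.5
    b <- as.vector(rmultinom(1, 100, runif(5))) + 0.5
    a <- a / sum(a); b <- b / sum(b)
    expect_equal(bhattacharyya_distance(a, b), bhattacharyya_distance(b, a))
    expect_gte(bhattacharyya_distance(a, b), 0)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and metric-consistent", {
  tc <- taxon_counts(rbind(s1 = c(5L, 5L), s2 = c(5L, 5L)), level = "order")
  d <- taxon_distance(tc, "bhattacharyya")
  expect_equal(as.vector(d), 0)

  tc3 <- taxon_counts(rbind(a = c(10L, 0L, 5L), b = c(2L, 8L, 5L),
                            c = c(0L, 0L, 15L)), level = "order")
  d3 <- as.matrix(taxon_distance(tc3, "bhattacharyya", pseudocount = 0.5))
  prof <- normalize_profiles(unclass(tc3), 0.5)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d3[i, j], bhattacharyya_distance(prof[i, ], prof[j, ]))

  # reversed ranks give 1 - rho = 2
  rev2 <- taxon_counts(rbind(u = c(1L, 2L, 3L, 4L), v = c(4L, 3L, 2L, 1L)),
                       level = "order")
  expect_equal(as.vector(taxon_distance(rev2, "one_minus_spearman")), 2)

  # rank distance of a sample with a positive rescaling of itself is 0
  sc <- taxon_counts(rbind(w = c(1L, 5L, 2L, 9L), x = c(3L, 15L, 6L, 27L)),
                     level = "order")
  expect_equal(as.vector(taxon_distance(sc, "one_minus_spearman")), 0)
})

test_that("classical MDS reproduces known geometries with variance split", {
  # equilateral triangle, side 1
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  mds <- classical_mds(stats::as.dist(tri), k = 2)
  emb <- as.matrix(stats::dist(mds$points))
  expect_lt(max(abs(emb - tri)), 1e-9)
  expect_equal(mds$variance_explained, c(0.5, 0.5), tolerance = 1e-9)

  # 4 collinear points: one positive eigenvalue carries all the variance
  lin <- as.matrix(stats::dist(1:4))
  expect_warning(m1 <- classical_mds(stats::as.dist(lin), k = 2), "positive")
  expect_equal(m1$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(ncol(m1$points), 1L)

  # all-zero distances
  z <- suppressWarnings(classical_mds(stats::as.dist(matrix(0, 3, 3)), k = 1))
  expect_true(all(abs(z$points) < 1e-12) || ncol(z$points) == 0)

  # random 3-d configuration: all pairwise distances reproduced
  set.seed(5)
  pts <- matrix(rnorm(24), 8, 3)
  d <- stats::dist(pts)
  m3 <- classical_mds(d, k = 3)
  expect_lt(max(abs(as.matrix(stats::dist(m3$points)) - as.matrix(d))), 1e-9)
  expect_equal(sum(m3$variance_explained), 1, tolerance = 1e-9)
})

test_that("complete-linkage clustering follows the hand agglomeration", {
  dm <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(dm)
  expect_equal(hc$height, c(1, 5))
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))

  two <- hierarchical_cluster(matrix(c(0, 3, 3, 0), 2,
                                     dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(two$height, 3)

  dup <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3)
  expect_equal(hierarchical_cluster(dup)$height[1], 0)

  # heights monotone on random dissimilarities
  set.seed(9)
  for (i in 1:10) {
    d <- stats::as.dist(matrix(runif(49), 7, 7))
    expect_true(!is.unsorted(hierarchical_cluster(d)$height))
  }
  expect_error(hierarchical_cluster(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("dendrograms export to parseable Newick", {
  tc <- taxon_counts(rbind(r = c(9L, 1L, 0L), st = c(8L, 2L, 1L),
                           mal = c(1L, 5L, 9L)), level = "order")
  hc <- hierarchical_cluster(taxon_distance(tc, "one_minus_spearman"))
  nwk <- as_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("r", "st", "mal"))
})

test_that("flying contingency matches the direct chi-square formula", {
  tc <- taxon_counts(rbind(res1 = c(10L, 20L), res2 = c(20L, 10L)),
                     level = "order")
  colnames(tc) <- c("Diptera", "Collembola")
  ct <- flying_contingency(tc)
  expect_equal(ct$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(ct$df, 1L)
  expect_equal(ct$std_residuals,
               (ct$table - outer(rowSums(ct$table), colSums(ct$table)) / 60) /
                 sqrt(outer(rowSums(ct$table), colSums(ct$table)) / 60))

  # identical rows: no departure
  same <- taxon_counts(rbind(a = c(10L, 5L), b = c(10L, 5L)), level = "order")
  colnames(same) <- c("Diptera", "Collembola")
  ct0 <- flying_contingency(same)
  expect_equal(ct0$chi2, 0)
  expect_equal(ct0$p_value, 1)

  # chi2 invariant under swapping rows
  swapped <- taxon_counts(rbind(res2 = c(20L, 10L), res1 = c(10L, 20L)),
                          level = "order")
  colnames(swapped) <- c("Diptera", "Collembola")
  expect_equal(flying_contingency(swapped)$chi2, ct$chi2)

  # unclassified taxon is a configuration error; excluded taxa are dropped
  bad <- taxon_counts(rbind(a = c(1L, 1L)), level = "order")
  colnames(bad) <- c("Diptera", "NotATaxon")
  expect_error(flying_contingency(bad), "missing from")

  with_acari <- taxon_counts(rbind(r1 = c(10L, 20L, 99L), r2 = c(20L, 10L, 1L)),
                             level = "order")
  colnames(with_acari) <- c("Diptera", "Collembola", "Acari")
  expect_equal(flying_contingency(with_acari)$chi2, 20 / 3, tolerance = 1e-12)
})
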