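#' Convert taxon counts to probability profiles
#'
#' Adds a pseudocount to every cell (Jeffreys-style 0.5 by default, so that
#' absent taxa do not force a Bhattacharyya coefficient of zero) and
#' normalises each sample row to sum to 1.
#'
#' @param counts a `taxon_counts` matrix (or any non-negative matrix with
#'   samples in rows).
#' @param pseudocount non-negative value added to every cell before
#'   normalisation; 0 gives the plain relative frequencies.
#' @return numeric matrix of row profiles, each row summing to 1.
#' @examples
#' normalize_profiles(rbind(a = c(3, 1), b = c(0, 0)), pseudocount = 0)
#' @export
normalize_profiles <- function(counts, pseudocount = 0.5) {
  m <- as.matrix(counts)
  if (ncol(m) == 0L) stop("empty taxon set")
  stopifnot(pseudocount >= 0, all(m >= 0))
  m <- m + pseudocount
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("sample(s) with zero total and zero pseudocount cannot be normalised: ",
         paste(rownames(m)[rs <= 0], collapse = ", "))
  sweep(m, 1L, rs, "/")
}

#' Bhattacharyya distance between two probability profiles
#'
#' `D = -ln(BC)` with the Bhattacharyya coefficient
#' `BC = sum_i sqrt(p_i * q_i)`. The coefficient is clipped into `(0, 1]`
#' before the log: rounding excursions above 1 map to distance 0, and
#' disjoint supports (BC = 0) map to the finite cap `max_distance` so that
#' downstream ordination stays finite.
#'
#' @param p,q non-negative numeric vectors over the same taxon set, each
#'   summing to 1 (within 1e-6).
#' @param max_distance distance assigned when BC underflows to 0.
#' @return the Bhattacharyya distance (non-negative scalar; 0 iff `p == q`).
#' @examples
#' bhattacharyya_distance(c(0.5, 0.5), c(0.9, 0.1))  # ~0.111572
#' @export
bhattacharyya_distance <- function(p, q, max_distance = 50) {
  if (length(p) != length(q))
    stop("profiles are over different taxon sets (lengths differ)")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("profiles are over different taxon sets (names differ)")
  stopifnot(all(p >= 0), all(q >= 0),
            abs(sum(p) - 1) < 1e-6, abs(sum(q) - 1) < 1e-6)
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(max_distance)
  min(-log(min(bc, 1)), max_distance)
}

#' Pairwise distance matrix between samples of a taxon count matrix
#'
#' Two metrics are offered, matching the two assemblage comparisons this
#' package performs: `"bhattacharyya"` (on pseudocounted probability
#' profiles; used for ordination) and `"one_minus_spearman"`
#' (1 - Spearman rank correlation between raw count rows, average ranks for
#' ties; used for clustering).
#'
#' @param counts a `taxon_counts` matrix (samples in rows).
#' @param metric `"bhattacharyya"` or `"one_minus_spearman"`.
#' @param pseudocount passed to [normalize_profiles()] (Bhattacharyya only).
#' @param max_distance cap for degenerate Bhattacharyya pairs.
#' @return a [stats::dist] object with attribute `metric`.
#' @export
taxon_distance <- function(counts,
                           metric = c("bhattacharyya", "one_minus_spearman"),
                           pseudocount = 0.5, max_distance = 50) {
  metric <- match.arg(metric)
  m <- as.matrix(counts)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (metric == "bhattacharyya") {
    prof <- normalize_profiles(m, pseudocount = pseudocount)
    n <- nrow(prof)
    d <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bhattacharyya_distance(prof[i, ], prof[j, ],
                                                   max_distance = max_distance)
    }
  } else {
    rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    rho[!is.finite(rho)] <- 0  # constant rows have undefined rank correlation
    d <- 1 - rho
    diag(d) <- 0
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- metric
  out
}

#' Classical (Torgerson) multidimensional scaling with variance explained
#'
#' Double-centres the squared distance matrix and eigendecomposes it
#' (via [stats::cmdscale]); coordinates are eigenvectors scaled by the
#' square root of the positive eigenvalues. The proportion of variance
#' explained per axis is its eigenvalue over the sum of positive
#' eigenvalues; negative eigenvalues (the Bhattacharyya distance is not
#' Euclidean) are truncated and their total magnitude reported.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @param k number of axes to retain (default 2; must be < number of
#'   samples). If fewer positive eigenvalues exist, the available axes are
#'   returned with a warning.
#' @return object of class `mds_result`: list with `points` (samples x k),
#'   `eigenvalues` (all, decreasing), `variance_explained` (per retained
#'   axis), `negative_magnitude` (sum of |negative eigenvalues|).
#' @examples
#' d <- stats::dist(rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2)))
#' classical_mds(d)$variance_explained  # 0.5 0.5
#' @export
classical_mds <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(k >= 1, k < n)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  n_pos <- length(pos)
  if (n_pos < k)
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " axis/axes instead of ", k)
  k_eff <- min(k, max(n_pos, 0L))
  pts <- if (k_eff > 0L) fit$points[, seq_len(k_eff), drop = FALSE]
  else matrix(0, n, 0, dimnames = list(rownames(dm), NULL))
  ve <- if (n_pos > 0L) pos[seq_len(k_eff)] / sum(pos) else numeric(0)
  structure(list(points = pts,
                 eigenvalues = eig,
                 variance_explained = ve,
                 negative_magnitude = sum(abs(eig[eig < 0]))),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("Classical MDS: %d samples, %d axes retained\n",
              nrow(x$points), ncol(x$points)))
  if (length(x$variance_explained))
    cat("  variance explained per axis:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
        "\n")
  if (x$negative_magnitude > 0)
    cat(sprintf("  truncated negative-eigenvalue magnitude: %.4g\n",
                x$negative_magnitude))
  invisible(x)
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering under the supplied distance (typically
#' `one_minus_spearman` from [taxon_distance()]) with complete linkage, so
#' merge heights are monotone non-decreasing.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @param linkage linkage method; only `"complete"` is used by the analyses
#'   here but any [stats::hclust] method is accepted.
#' @return a [stats::hclust] object.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  d <- stats::as.dist(as.matrix(d))
  if (any(!is.finite(d))) stop("non-finite distances")
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc a [stats::hclust] object.
#' @param file optional path; if given the tree is written there.
#' @return the Newick string (invisibly if written to file).
#' @export
as_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = file); invisible(ape::write.tree(phy)) }
}

#' Flying versus non-flying contingency analysis
#'
#' Aggregates each sample's counts into flying and non-flying insect totals
#' under a taxon classification (non-insect arthropods are excluded) and
#' tests homogeneity of the flying fraction across samples with a Pearson
#' chi-square (no continuity correction). Standardised residuals
#' `(O - E) / sqrt(E)` flag the cells driving any departure.
#'
#' @param counts a `taxon_counts` matrix (samples in rows).
#' @param classification named character vector mapping every taxon to
#'   `"flying"`, `"non_flying"` or `"excluded"`; defaults to
#'   [default_flying_classes()]. Taxa absent from the map raise an error.
#' @param simulate_p if `TRUE`, the p-value is obtained by Monte-Carlo
#'   permutation (for small expected counts).
#' @param B permutation replicates when `simulate_p` is `TRUE`.
#' @param seed RNG seed for the permutation p-value.
#' @return object of class `contingency_result`: list with `table`
#'   (samples x 2), `chi2`, `df`, `p_value`, `std_residuals`.
#' @examples
#' tc <- taxon_counts(rbind(r1 = c(10, 20), r2 = c(20, 10)),
#'                    level = "order")
#' colnames(tc) <- c("Diptera", "Collembola")
#' flying_contingency(tc)$chi2  # 20/3
#' @export
flying_contingency <- function(counts, classification = default_flying_classes(),
                               simulate_p = FALSE, B = 2000, seed = NULL) {
  m <- as.matrix(counts)
  taxa <- colnames(m)
  missing_taxa <- setdiff(taxa, names(classification))
  if (length(missing_taxa))
    stop("taxa missing from the flying classification: ",
         paste(missing_taxa, collapse = ", "))
  cls <- classification[taxa]
  tab <- cbind(
    flying = rowSums(m[, cls == "flying", drop = FALSE]),
    non_flying = rowSums(m[, cls == "non_flying", drop = FALSE])
  )
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("degenerate table: expected count of 0 in at least one cell")
  if (!is.null(seed)) set.seed(seed)
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE,
                      simulate.p.value = simulate_p, B = B))
  structure(list(table = tab,
                 chi2 = unname(ct$statistic),
                 df = if (simulate_p) (nrow(tab) - 1L) * (ncol(tab) - 1L)
                 else unname(ct$parameter),
                 p_value = ct$p.value,
                 std_residuals = (tab - exp_counts) / sqrt(exp_counts)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Flying vs non-flying contingency: chi2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  print(x$table)
  invisible(x)
}
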