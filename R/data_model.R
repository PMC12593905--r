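#' @keywords internal
"_PACKAGE"

TREE_GROUPS <- c("agathis", "agathis_like", "hymenaea", "cheirolepidiaceae", "other")
RESIN_CLASSES <- c("amber", "copal", "defaunation")

#' Round a mass to the 0.01 g recording resolution
#'
#' Piece masses are recorded with a balance error of 0.01 g, so every mass
#' entering the package is snapped to that grid. Ties at 0.005 g round half-up.
#'
#' @param mass_g numeric vector of masses in grams.
#' @return numeric vector, exact multiples of 0.01.
#' @keywords internal
round_mass <- function(mass_g) {
  # round() would round half-to-even; the recording convention is half-up
  floor(mass_g * 100 + 0.5) / 100
}

#' Construct a collection of resin pieces
#'
#' A piece collection is the unit of the uniformity analysis: one row per
#' collected (or simulated) resin piece or lump, with its mass in grams at
#' 0.01 g resolution and the number of arthropod inclusions it contains.
#'
#' @param mass_g positive numeric vector of piece masses (grams); rounded to
#'   0.01 g on construction, minimum 0.01 g.
#' @param n_inclusions non-negative integer vector, same length as `mass_g`.
#' @param piece_id optional character vector of unique piece identifiers.
#' @param label collection label (e.g. locality or simulation name).
#' @param tree_group one of `"agathis"`, `"agathis_like"`, `"hymenaea"`,
#'   `"cheirolepidiaceae"`, `"other"`.
#' @param resin_class one of `"amber"` (older than 2.58 Ma), `"copal"`
#'   (2.58 Ma to 1760 AD) or `"defaunation"` (after 1760 AD). Metadata only.
#' @return an object of class `piece_collection`: a data.frame with columns
#'   `piece_id`, `mass_g`, `n_inclusions` and attributes `label`,
#'   `tree_group`, `resin_class`.
#' @examples
#' pc <- piece_collection(c(1.005, 2, 0.014), c(0L, 1L, 0L))
#' pc$mass_g  # 1.00 2.00 0.01
#' @export
piece_collection <- function(mass_g, n_inclusions,
                             piece_id = NULL,
                             label = "collection",
                             tree_group = "other",
                             resin_class = "defaunation") {
  tree_group <- match.arg(tree_group, TREE_GROUPS)
  resin_class <- match.arg(resin_class, RESIN_CLASSES)
  mass_g <- as.numeric(mass_g)
  n_inclusions <- n_inclusions
  if (length(mass_g) != length(n_inclusions))
    stop("mass_g and n_inclusions must have the same length")
  bad_mass <- which(!is.finite(mass_g) | mass_g <= 0)
  if (length(bad_mass))
    stop("non-positive or non-finite mass in row(s): ",
         paste(utils::head(bad_mass, 5L), collapse = ", "))
  bad_n <- which(!is.finite(n_inclusions) | n_inclusions < 0 |
                   n_inclusions != floor(n_inclusions))
  if (length(bad_n))
    stop("negative or non-integer inclusion count in row(s): ",
         paste(utils::head(bad_n, 5L), collapse = ", "))
  mass_g <- pmax(round_mass(mass_g), 0.01)
  if (is.null(piece_id)) piece_id <- sprintf("p%04d", seq_along(mass_g))
  if (anyDuplicated(piece_id)) stop("piece_id values must be unique")
  out <- data.frame(piece_id = as.character(piece_id),
                    mass_g = mass_g,
                    n_inclusions = as.integer(n_inclusions),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- as.character(label)
  attr(out, "tree_group") <- tree_group
  attr(out, "resin_class") <- resin_class
  class(out) <- c("piece_collection", "data.frame")
  out
}

#' @export
print.piece_collection <- function(x, ...) {
  cat(sprintf("Piece collection '%s' (%s, %s): %d pieces, %.2f g, %d inclusions\n",
              attr(x, "label"), attr(x, "tree_group"), attr(x, "resin_class"),
              nrow(x), sum(x$mass_g), sum(x$n_inclusions)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a piece-level table from CSV
#'
#' The canonical piece table has columns `piece_id`, `mass_g`,
#' `n_inclusions` (comma-separated, UTF-8, header required). Masses are
#' rounded to the 0.01 g recording resolution on ingest; row order is
#' preserved.
#'
#' @param path path to a CSV file.
#' @inheritParams piece_collection
#' @return a [piece_collection].
#' @export
read_piece_table <- function(path, label = basename(path),
                             tree_group = "other",
                             resin_class = "defaunation") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("piece_id", "mass_g", "n_inclusions")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("piece table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(piece_collection(numeric(0), integer(0), character(0),
                            label = label, tree_group = tree_group,
                            resin_class = resin_class))
  piece_collection(df$mass_g, df$n_inclusions, piece_id = df$piece_id,
                   label = label, tree_group = tree_group,
                   resin_class = resin_class)
}

#' Write a piece collection to CSV
#'
#' Masses are written with two decimals so a write/read round trip is exact
#' at the 0.01 g resolution.
#'
#' @param collection a [piece_collection].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_piece_table <- function(collection, path) {
  stopifnot(inherits(collection, "piece_collection"))
  df <- data.frame(piece_id = collection$piece_id,
                   mass_g = sprintf("%.2f", collection$mass_g),
                   n_inclusions = collection$n_inclusions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locality summaries: inclusions per mass of inspected resin
#'
#' Returns the packaged summary of unbiased amber, copal and Defaunation
#' resin collections: one row per locality with the inspected resin mass and
#' the number of arthropod inclusions found. Localities whose inspected mass
#' is only known as a range carry both bounds; `total_mass_g` is the
#' midpoint, the convention used by all analyses in this package. Rows whose
#' mass is only approximate ("ca.") are flagged `approximate`.
#'
#' @return a data.frame of class `locality_summary` with columns `locality`,
#'   `age`, `tree_taxon`, `tree_group`, `resin_class`, `mass_min_g`,
#'   `mass_max_g`, `total_mass_g`, `approximate`, `total_inclusions`,
#'   `citation`.
#' @examples
#' tab <- load_locality_table()
#' subset(tab, tree_group == "agathis" & resin_class == "defaunation")
#' @export
load_locality_table <- function() {
  path <- system.file("extdata", "table1_localities.csv", package = "resintrap")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$total_mass_g <- (df$mass_min_g + df$mass_max_g) / 2
  df <- df[, c("locality", "age", "tree_taxon", "tree_group", "resin_class",
               "mass_min_g", "mass_max_g", "total_mass_g", "approximate",
               "total_inclusions", "citation")]
  class(df) <- c("locality_summary", "data.frame")
  df
}

#' Inclusion density (arthropod inclusions per gram of resin)
#'
#' @param x a [piece_collection], a `locality_summary` data.frame (density of
#'   the pooled rows), or a list/data.frame with elements `total_inclusions`
#'   and `total_mass_g`.
#' @return inclusions per gram (numeric scalar).
#' @examples
#' inclusion_density(piece_collection(c(5, 5), c(6L, 4L)))  # 1.0
#' @export
inclusion_density <- function(x) {
  if (inherits(x, "piece_collection")) {
    mass <- sum(x$mass_g); incl <- sum(x$n_inclusions)
  } else if (!is.null(x$total_mass_g)) {
    mass <- sum(x$total_mass_g); incl <- sum(x$total_inclusions)
  } else {
    stop("cannot extract mass and inclusion totals from 'x'")
  }
  if (!isTRUE(mass > 0)) stop("total mass must be positive")
  incl / mass
}

#' Read a samples-by-taxa count matrix from CSV
#'
#' First column is the sample id; every remaining column is one taxon.
#' Zeros are preserved; all-zero rows are retained (a trap that caught
#' nothing is a valid sample).
#'
#' @param path path to a CSV file.
#' @param level `"order"` or `"diptera_family"`; recorded as an attribute.
#' @return an integer matrix with sample ids as rownames, taxa as colnames,
#'   class `taxon_counts`, attribute `level`.
#' @export
read_taxon_counts <- function(path, level = c("order", "diptera_family")) {
  level <- match.arg(level)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("taxon count file needs a sample column plus taxa")
  taxa <- names(df)[-1L]
  if (anyDuplicated(taxa))
    stop("duplicated taxon column(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  samples <- as.character(df[[1L]])
  if (anyDuplicated(samples)) stop("duplicated sample id(s)")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(samples, taxa)
  taxon_counts(m, level = level)
}

#' Construct a taxon count matrix
#'
#' @param counts non-negative integer matrix, samples in rows (rownames),
#'   taxa in columns (colnames).
#' @param level `"order"` or `"diptera_family"`.
#' @return the matrix with class `taxon_counts` and attribute `level`.
#' @export
taxon_counts <- function(counts, level = c("order", "diptera_family")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and taxon ids must be unique")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(counts, level = level, class = c("taxon_counts", class(counts)))
}

#' Default flying / non-flying classification of arthropod taxa
#'
#' Winged insect orders are classed as flying; Collembola, Zygentoma and the
#' ants (Formicidae, treated separately from other Hymenoptera when family
#' data allow) as non-flying; non-insect arthropods (Acari, Araneae,
#' Pseudoscorpiones, Isopoda, Myriapoda) are excluded. Shipped as an
#' editable CSV under `extdata/flying_classes.csv`.
#'
#' @return named character vector mapping taxon to
#'   `"flying"` / `"non_flying"` / `"excluded"`.
#' @export
default_flying_classes <- function() {
  path <- system.file("extdata", "flying_classes.csv", package = "resintrap")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$class, df$taxon)
}
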