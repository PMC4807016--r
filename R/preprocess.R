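#' Construct a strains-by-features trait matrix
#'
#' Thin S3 wrapper over a numeric matrix with strain ids as row names and
#' feature ids as column names. Missing values are `NA`; a `standardized`
#' attribute records whether columns are per-feature z-scores.
#'
#' @param values Numeric matrix (strains in rows, features in columns) or an
#'   object coercible to one; row and column names required.
#' @param standardized Logical flag.
#' @return A `"trait_matrix"` (a numeric matrix subclass).
#' @export
trait_matrix <- function(values, standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("trait_matrix needs strain row names and feature column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate strain ids", call. = FALSE)
  structure(values, standardized = standardized,
            class = c("trait_matrix", class(values)))
}

is_standardized <- function(m) isTRUE(attr(m, "standardized"))

as_trait_matrix <- function(values, standardized = FALSE) {
  if (inherits(values, "trait_matrix")) return(values)
  trait_matrix(values, standardized = standardized)
}

#' Read a trait matrix from TSV/CSV
#'
#' Expects strains in rows with the strain id in the first column and
#' features in the remaining columns (header row of feature ids).
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.csv` means comma, anything else tab).
#' @return A `"trait_matrix"`.
#' @export
read_trait_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  trait_matrix(as.matrix(df))
}

#' Write a trait matrix as TSV
#'
#' @param m A `"trait_matrix"` (or plain matrix).
#' @param path Output path.
#' @export
write_trait_matrix <- function(m, path) {
  utils::write.table(cbind(strain = rownames(m), as.data.frame(unclass(m))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature standardization (z-scores)
#'
#' Centers and scales every feature column to mean 0 and sample (n - 1)
#' standard deviation 1 across strains, using observed values only; missing
#' entries stay missing. Constant features (zero variance) cannot be scaled
#' and are dropped with a warning; their ids are recorded in the
#' `dropped_features` attribute.
#'
#' @param m A `"trait_matrix"` or strains-by-features matrix.
#' @return A standardized `"trait_matrix"`.
#' @examples
#' m <- trait_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3,
#'                   dimnames = list(c("a", "b", "c"), c("f1", "f2"))))
#' standardize(m)
#' @export
standardize <- function(m) {
  m <- as_trait_matrix(m)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2L)) {
    stop("feature(s) with fewer than 2 observed values: ",
         paste(colnames(m)[n_obs < 2L], collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
  constant <- sd_ == 0 | is.na(sd_)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant feature(s): ",
            paste(utils::head(colnames(m)[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "", call. = FALSE)
  }
  keep <- !constant
  z <- sweep(sweep(unclass(m)[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sd_[keep], "/")
  out <- trait_matrix(z, standardized = TRUE)
  attr(out, "dropped_features") <- colnames(m)[constant]
  out
}

#' Metabolite missing-value filter
#'
#' Drops features (metabolites) with missing values in more than one strain,
#' where missingness in one designated strain (the strain lacking the whole
#' metabolite panel) is not counted. Features missing in exactly one other
#' strain are retained for imputation.
#'
#' @param m A `"trait_matrix"`.
#' @param excluded_strain Strain id whose missing values are ignored by the
#'   filter (default `"378604X"`); may be absent from the matrix.
#' @return A filtered `"trait_matrix"`; dropped feature ids are in the
#'   `dropped_features` attribute.
#' @export
filter_metabolites <- function(m, excluded_strain = "378604X") {
  m <- as_trait_matrix(m)
  rows <- setdiff(rownames(m), excluded_strain)
  n_missing <- colSums(is.na(unclass(m)[rows, , drop = FALSE]))
  keep <- n_missing <= 1L
  out <- trait_matrix(unclass(m)[, keep, drop = FALSE],
                      standardized = is_standardized(m))
  attr(out, "dropped_features") <- colnames(m)[!keep]
  out
}

#' k-nearest-neighbour imputation of missing values
#'
#' For each strain row with missing entries, the k nearest complete strain
#' rows are found by Euclidean distance over the features observed in the
#' target row; each missing entry is filled with the `exp(-d)`-weighted mean
#' of the neighbours' values. Observed entries are never altered. This
#' mirrors the behaviour of the classic case-wise kNN imputation routine for
#' omics matrices.
#'
#' @param m A `"trait_matrix"` with missing values.
#' @param k Number of neighbours (default 10); clamped with a warning when
#'   fewer complete rows exist.
#' @return A complete `"trait_matrix"`.
#' @examples
#' m <- trait_matrix(matrix(c(0, 1, 2, 0, NA, 2), 3,
#'                   dimnames = list(c("A", "B", "C"), c("f1", "f2"))))
#' knn_impute(m, k = 2)
#' @export
knn_impute <- function(m, k = 10) {
  m <- as_trait_matrix(m)
  vals <- unclass(m)
  complete <- rowSums(is.na(vals)) == 0L
  targets <- which(!complete)
  if (!length(targets)) return(m)
  if (!any(complete)) {
    stop("no complete strain rows available as neighbours", call. = FALSE)
  }
  n_cand <- sum(complete)
  k_eff <- k
  if (k > n_cand) {
    warning("k = ", k, " exceeds the ", n_cand,
            " complete neighbour row(s); using k = ", n_cand, call. = FALSE)
    k_eff <- n_cand
  }
  cand <- vals[complete, , drop = FALSE]
  for (i in targets) {
    obs <- !is.na(vals[i, ])
    if (!any(obs)) {
      stop("strain '", rownames(m)[i],
           "' has no observed values to compute neighbour distances",
           call. = FALSE)
    }
    d <- sqrt(colSums((t(cand[, obs, drop = FALSE]) - vals[i, obs])^2))
    nb <- order(d)[seq_len(k_eff)]
    w <- exp(-d[nb])
    if (sum(w) == 0) w <- rep(1, length(nb))  # all neighbours very distant
    fill <- which(!obs)
    vals[i, fill] <- colSums(cand[nb, fill, drop = FALSE] * w) / sum(w)
  }
  trait_matrix(vals, standardized = is_standardized(m))
}

#' Aggregate peptide-level rows to gene level
#'
#' For genes represented by several peptides, the gene profile is the mean of
#' the standardized peptide values per strain; single-peptide genes pass
#' through unchanged. Peptides absent from the map are excluded with a
#' warning and counted in the `n_unmapped` attribute.
#'
#' @param m A standardized `"trait_matrix"` with peptide columns.
#' @param gene_map Data frame (or 2-column TSV path) with columns
#'   `peptide_id`, `gene_id`.
#' @return A `"trait_matrix"` keyed by gene.
#' @export
aggregate_peptides <- function(m, gene_map) {
  m <- as_trait_matrix(m)
  if (!is_standardized(m)) {
    stop("aggregate_peptides expects a standardized matrix; call standardize() first",
         call. = FALSE)
  }
  if (is.character(gene_map) && length(gene_map) == 1L) {
    gene_map <- utils::read.table(gene_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  stopifnot(all(c("peptide_id", "gene_id") %in% names(gene_map)))
  idx <- match(colnames(m), gene_map$peptide_id)
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    warning(sum(unmapped), " peptide(s) absent from gene_map were excluded",
            call. = FALSE)
  }
  genes <- gene_map$gene_id[idx[!unmapped]]
  sub <- unclass(m)[, !unmapped, drop = FALSE]
  out <- vapply(split(seq_along(genes), genes), function(cols) {
    rowMeans(sub[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(sub)))
  res <- trait_matrix(out, standardized = TRUE)
  attr(res, "n_unmapped") <- sum(unmapped)
  res
}

#' Principal component analysis of a complete standardized matrix
#'
#' Centered PCA (no re-scaling; the input is already standardized) with up to
#' `min(strains - 1, features)` components.
#'
#' @param m A complete (no missing values) `"trait_matrix"`.
#' @return An object of class `"pca_result"`: `loadings` (features x
#'   components, orthonormal columns), `scores` (strains x components), and
#'   `variance_fraction` (non-increasing, summing to 1 over the returned
#'   components).
#' @export
run_pca <- function(m) {
  m <- as_trait_matrix(m)
  if (anyNA(m)) {
    stop("matrix has missing values; impute first (see knn_impute)", call. = FALSE)
  }
  rank_max <- min(nrow(m) - 1L, ncol(m))
  p <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE, rank. = rank_max)
  v <- p$sdev[seq_len(rank_max)]^2
  structure(
    list(loadings = p$rotation, scores = p$x, variance_fraction = v / sum(v),
         center = p$center),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "strains,", nrow(x$loadings), "features,",
      ncol(x$loadings), "components\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)), collapse = " "),
      if (length(x$variance_fraction) > 5) "..." else "", "\n")
  invisible(x)
}

#' Top contributors to a principal component
#'
#' Ranks features by contribution (absolute loading by default) on one
#' component and returns the top `floor(fraction * F)` feature ids, for
#' export as a plain gene list to external enrichment tools. Ties at the
#' cutoff are broken by feature id.
#'
#' @param p A `"pca_result"`.
#' @param component Component index (1-based).
#' @param fraction Fraction of features to keep, in (0, 1\]; default 0.10.
#' @param contribution `"abs"` (absolute loading, default) or `"squared"`.
#' @return Character vector of feature ids, ranked by decreasing
#'   contribution.
#' @export
top_contributors <- function(p, component, fraction = 0.10,
                             contribution = c("abs", "squared")) {
  contribution <- match.arg(contribution)
  stopifnot(inherits(p, "pca_result"))
  if (component < 1L || component > ncol(p$loadings)) {
    stop("component out of range (1..", ncol(p$loadings), ")", call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  load <- p$loadings[, component]
  score <- if (contribution == "abs") abs(load) else load^2
  n_top <- floor(fraction * length(score))
  ord <- order(-score, names(score))
  names(score)[ord][seq_len(n_top)]
}

#' Pearson or Spearman correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("constant input", call. = FALSE)
  }
  stats::cor(x[ok], y[ok], method = method)
}

#' Combine standardized omics blocks by strain
#'
#' Column-binds standardized blocks over their common strains for a combined
#' PCA. Blocks missing any of the common strains are dropped with a message
#' (the classic case: the metabolite panel absent for one strain excludes
#' metabolites from the combined data).
#'
#' @param blocks Named list of standardized `"trait_matrix"` objects.
#' @param strains Optional character vector of strains to use; defaults to
#'   strains present in at least one block.
#' @return A `"trait_matrix"` over the common strains, with feature ids
#'   prefixed by block name.
#' @export
combine_blocks <- function(blocks, strains = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L, !is.null(names(blocks)))
  if (is.null(strains)) {
    strains <- Reduce(union, lapply(blocks, rownames))
  }
  keep <- vapply(blocks, function(b) all(strains %in% rownames(b)), logical(1))
  if (!all(keep)) {
    message("excluding block(s) lacking some strains: ",
            paste(names(blocks)[!keep], collapse = ", "))
  }
  blocks <- blocks[keep]
  if (!length(blocks)) stop("no block covers the requested strains", call. = FALSE)
  parts <- lapply(names(blocks), function(nm) {
    b <- unclass(blocks[[nm]])[strains, , drop = FALSE]
    colnames(b) <- paste(nm, colnames(b), sep = ":")
    b
  })
  trait_matrix(do.call(cbind, parts),
               standardized = all(vapply(blocks, is_standardized, logical(1))))
}
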