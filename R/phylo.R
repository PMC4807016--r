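#' Parse a Newick string into a validated phylogeny
#'
#' Reads a rooted tree with branch lengths and validates it for use in
#' phylogenetic regression: at least two tips, unique tip labels, and
#' non-negative branch lengths on every edge. Unlabeled internal nodes and
#' polytomies are accepted. A root edge, if present, is ignored downstream
#' (it adds the same constant to every covariance entry and is confounded
#' with the regression intercept).
#'
#' @param text A Newick string, e.g. `"((A:1,B:1):1,C:2);"`. Branch lengths
#'   are required on all non-root edges.
#' @return An object of class `"phylo"` (from \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree) || is.null(tree$tip.label) || is.na(tree$Nnode)) {
    stop("Newick parse error: unparseable string (need at least 2 tips)",
         call. = FALSE)
  }
  validate_tree(tree)
  tree
}

# Cheap positional pre-check so malformed input fails with the offending
# character position rather than an opaque downstream error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of string (position ",
         nchar(text), ")", call. = FALSE)
  }
  if (!grepl("(", text, fixed = TRUE)) {
    stop("Newick parse error: no '(' found; a tree needs at least 2 tips",
         call. = FALSE)
  }
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L) {
    stop("Newick parse error: missing ';' terminator at position ",
         nchar(text), call. = FALSE)
  }
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2L) {
    stop("tree must have at least 2 tips", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on one or more edges", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s): ",
         paste(signif(tree$edge.length[tree$edge.length < 0], 4), collapse = ", "),
         call. = FALSE)
  }
  invisible(tree)
}

#' Tree geometry: MRCA-depth and patristic-distance matrices
#'
#' Computes the two matrices every trait-evolution covariance model consumes:
#' `mrca_depth` (entry i,j is the root-to-MRCA path length of tips i and j;
#' the diagonal holds tip depths) and `patristic` (tip-to-tip path lengths).
#' They satisfy `D[i,j] = C[i,i] + C[j,j] - 2 C[i,j]`. Trees need not be
#' ultrametric. A root edge is ignored.
#'
#' @param tree A `"phylo"` object (see [parse_newick()]).
#' @param tip_order Optional character vector, a permutation of the tip
#'   labels, giving the row/column order of the matrices. Defaults to the
#'   tree's tip order.
#' @return An object of class `"tree_geometry"`: a list with `tip_order`,
#'   `mrca_depth`, and `patristic`.
#' @examples
#' g <- geometry(parse_newick("((A:1,B:1):1,C:2);"), c("A", "B", "C"))
#' g$mrca_depth
#' @export
geometry <- function(tree, tip_order = NULL) {
  validate_tree(tree)
  labs <- tree$tip.label
  if (is.null(tip_order)) tip_order <- labs
  missing <- setdiff(tip_order, labs)
  if (length(missing)) {
    stop("tip_order contains label(s) not in the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(tip_order) != length(labs) || anyDuplicated(tip_order)) {
    stop("tip_order must be a permutation of the tree's tip labels", call. = FALSE)
  }
  tree$root.edge <- NULL
  C <- ape::vcv.phylo(tree)[tip_order, tip_order, drop = FALSE]
  D <- stats::cophenetic(tree)[tip_order, tip_order, drop = FALSE]
  structure(
    list(tip_order = tip_order, mrca_depth = C, patristic = D),
    class = "tree_geometry"
  )
}

#' @export
print.tree_geometry <- function(x, ...) {
  cat("tree_geometry:", length(x$tip_order), "tips\n")
  cat("tips:", paste(utils::head(x$tip_order, 8), collapse = ", "),
      if (length(x$tip_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Restrict a tree geometry to a subset of tips
#'
#' Dropping a tip does not change the MRCA depth or patristic distance of any
#' remaining tip pair, so pruning reduces to subsetting the matrices. Used by
#' the leave-one-out robustness check.
#'
#' @param geom A `"tree_geometry"`.
#' @param keep Character vector of tip labels to retain (order preserved).
#' @return A `"tree_geometry"` over `keep`.
#' @export
prune_geometry <- function(geom, keep) {
  stopifnot(inherits(geom, "tree_geometry"))
  missing <- setdiff(keep, geom$tip_order)
  if (length(missing)) {
    stop("unknown tip label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(tip_order = keep,
         mrca_depth = geom$mrca_depth[keep, keep, drop = FALSE],
         patristic = geom$patristic[keep, keep, drop = FALSE]),
    class = "tree_geometry"
  )
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  # full double precision so geometry round-trips bit-true
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Export geometry matrices as TSV
#'
#' Writes `mrca_depth` and `patristic` as tab-separated matrices with a
#' header row of tip labels.
#'
#' @param geom A `"tree_geometry"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_geometry <- function(geom, dir) {
  stopifnot(inherits(geom, "tree_geometry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mrca_depth.tsv", "patristic.tsv"))
  utils::write.table(geom$mrca_depth, paths[1], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(geom$patristic, paths[2], sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(paths)
}
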