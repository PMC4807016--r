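#' Per-base depth profile
#'
#' Holds per-base sequencing depth for each chromosome plus the name of the
#' mitochondrial sequence. Coordinates are 1-based (position p of chromosome
#' c is `depths[[c]][p]`).
#'
#' @param depths Named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param mito Name of the mitochondrial sequence (must be in `depths`).
#' @return An object of class `"depth_profile"`.
#' @export
depth_profile <- function(depths, mito) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  if (!mito %in% names(depths)) {
    stop("mitochondrial sequence '", mito, "' not in depth profile", call. = FALSE)
  }
  if (length(depths) < 2L) {
    stop("need the mitochondrial sequence and at least one nuclear chromosome",
         call. = FALSE)
  }
  for (nm in names(depths)) {
    d <- depths[[nm]]
    if (!length(d)) stop("chromosome '", nm, "' has zero length", call. = FALSE)
    if (any(d < 0)) stop("negative depth on '", nm, "'", call. = FALSE)
  }
  structure(list(depths = depths, mito = mito), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile:", length(x$depths), "sequences (mito:", x$mito, ")\n")
  invisible(x)
}

#' Default excluded region: the rDNA repeat window
#'
#' The yeast rDNA tandem repeat on chromosome XII collapses onto a single
#' reference copy and inflates depth there, so positions 45,000-50,000 of
#' chromosome XII (1-based, inclusive) are excluded from the nuclear mean by
#' default.
#'
#' @param chrom Chromosome name to match (default `"chrXII"`).
#' @return A one-row data frame with columns `chrom`, `start`, `end`.
#' @export
default_exclusion <- function(chrom = "chrXII") {
  data.frame(chrom = chrom, start = 45000L, end = 50000L,
             stringsAsFactors = FALSE)
}

#' Relative mitochondrial DNA coverage
#'
#' Mean per-base depth over the mitochondrial sequence divided by the mean
#' per-base depth over all nuclear positions outside the excluded regions.
#' Any per-library depth normalization applied to both tracks cancels in the
#' ratio. Used as a proxy for mitochondrial genome copy number.
#'
#' @param d A `"depth_profile"`.
#' @param exclude Data frame of regions (`chrom`, `start`, `end`; 1-based,
#'   inclusive) excluded from the nuclear mean. Defaults to the rDNA window
#'   [default_exclusion()]; regions on chromosomes absent from the profile
#'   are ignored.
#' @return The dimensionless coverage ratio (>= 0).
#' @examples
#' d <- depth_profile(list(chrI = rep(10, 1000), chrM = rep(40, 200)), "chrM")
#' relative_mtdna_coverage(d, exclude = NULL)
#' @export
relative_mtdna_coverage <- function(d, exclude = default_exclusion()) {
  stopifnot(inherits(d, "depth_profile"))
  mito_mean <- mean(d$depths[[d$mito]])
  nuc <- d$depths[names(d$depths) != d$mito]
  total <- 0
  n_pos <- 0
  for (nm in names(nuc)) {
    dep <- nuc[[nm]]
    keep <- rep(TRUE, length(dep))
    if (!is.null(exclude)) {
      rows <- which(exclude$chrom == nm)
      for (r in rows) {
        s <- max(1L, as.integer(exclude$start[r]))
        e <- min(length(dep), as.integer(exclude$end[r]))
        if (as.integer(exclude$start[r]) > length(dep)) {
          stop("excluded region beyond end of '", nm, "'", call. = FALSE)
        }
        if (s <= e) keep[s:e] <- FALSE
      }
    }
    if (!any(keep)) {
      warning("exclusion covers all of '", nm, "'", call. = FALSE)
      next
    }
    total <- total + sum(dep[keep])
    n_pos <- n_pos + sum(keep)
  }
  if (n_pos == 0L || total == 0) {
    stop("nuclear mean depth is zero; cannot form coverage ratio", call. = FALSE)
  }
  mito_mean / (total / n_pos)
}

#' Read a bedGraph-style depth track into a per-base profile
#'
#' Expects four tab-separated columns (`chrom`, `start`, `end`, `depth`) with
#' 0-based half-open intervals, the UCSC bedGraph convention; intervals are
#' expanded to per-base depth. Positions not covered by any interval get
#' depth 0 (chromosome length is taken as the largest end seen, unless given).
#'
#' @param path bedGraph file path.
#' @param mito Mitochondrial sequence name.
#' @param lengths Optional named vector of chromosome lengths.
#' @return A `"depth_profile"`.
#' @export
read_bedgraph <- function(path, mito, lengths = NULL) {
  bg <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "depth"),
                          stringsAsFactors = FALSE)
  chroms <- unique(bg$chrom)
  depths <- lapply(chroms, function(cm) {
    sub <- bg[bg$chrom == cm, , drop = FALSE]
    len <- if (!is.null(lengths) && cm %in% names(lengths)) {
      as.integer(lengths[[cm]])
    } else {
      max(sub$end)
    }
    d <- numeric(len)
    for (r in seq_len(nrow(sub))) {
      # 0-based half-open -> 1-based inclusive
      d[(sub$start[r] + 1L):sub$end[r]] <- sub$depth[r]
    }
    d
  })
  names(depths) <- chroms
  depth_profile(depths, mito)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns: `chrom`, `pos` (1-based), `depth`. Positions
#' absent from the table get depth 0 up to the largest position seen (or the
#' given length).
#'
#' @inheritParams read_bedgraph
#' @return A `"depth_profile"`.
#' @export
read_perbase_depth <- function(path, mito, lengths = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "pos", "depth"),
                           stringsAsFactors = FALSE)
  chroms <- unique(tab$chrom)
  depths <- lapply(chroms, function(cm) {
    sub <- tab[tab$chrom == cm, , drop = FALSE]
    len <- if (!is.null(lengths) && cm %in% names(lengths)) {
      as.integer(lengths[[cm]])
    } else {
      max(sub$pos)
    }
    d <- numeric(len)
    d[sub$pos] <- sub$depth
    d
  })
  names(depths) <- chroms
  depth_profile(depths, mito)
}

#' Convert BED regions to 1-based inclusive coordinates
#'
#' BED files are 0-based half-open; internal exclusion regions are 1-based
#' inclusive.
#'
#' @param path BED file path (first three columns used).
#' @return Data frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
bed_to_regions <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
             stringsAsFactors = FALSE)
}
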