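#' Bundled strain lifespan table
#'
#' Returns the per-strain phenotype table for the 22 natural isolates plus
#' the laboratory reference BY4743: strain type and source, maximum and mean
#' replicative lifespan (cell divisions) with standard error, doubling times
#' in glucose and glycerol media (minutes, mean and s.e.), relative
#' mitochondrial DNA coverage, and cell size (micrometres; not available for
#' BY4743).
#'
#' @return A data frame of class `"lifespan_table"` with 23 rows.
#' @examples
#' t1 <- table1_fixture()
#' subset(t1, strain == "BC187", c(mean_rls, max_rls))
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_strains.tsv", package = "pglscan",
                      mustWork = TRUE)
  t1 <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(t1$mean_rls <= t1$max_rls),
            all(t1$doubling_glucose_mean > 0),
            all(t1$doubling_glycerol_mean > 0))
  class(t1) <- c("lifespan_table", "data.frame")
  t1
}

#' Natural isolates of the bundled table (reference strain removed)
#'
#' @param reference Strain id of the laboratory reference (default
#'   `"BY4743"`).
#' @return The [table1_fixture()] rows without the reference strain.
#' @export
table1_isolates <- function(reference = "BY4743") {
  t1 <- table1_fixture()
  t1[t1$strain != reference, , drop = FALSE]
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Simulate a pure-birth phylogeny
#'
#' Random binary tree from a pure-birth (Yule) process, so branch lengths
#' come from exponential waiting times. Deterministic for a given seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed (required for reproducibility).
#' @param birth Birth rate (default 1; sets the time unit only).
#' @return A `"phylo"` tree with uniquely labeled tips.
#' @export
simulate_tree <- function(n_tips, seed, birth = 1) {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = 0)
    tree$tip.label <- sprintf("s%03d", seq_len(n_tips))
    tree
  })
}

#' Simulate one continuous trait on a phylogeny
#'
#' Draws a single realization from the multivariate normal with mean 0 and
#' covariance `sigma2 * covariance_matrix(geom, model)` over the tips — i.e.
#' a trait evolving under the chosen model (BM, lambda-scaled BM, fixed-root
#' OU, or iid noise for the Null model).
#'
#' @param tree A `"phylo"` tree (or a `"tree_geometry"`).
#' @param model An `"evolution_model"`.
#' @param sigma2 Evolutionary rate (variance scale), > 0.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named numeric vector over the tips.
#' @export
simulate_trait <- function(tree, model, sigma2 = 1, seed = NULL) {
  stopifnot(sigma2 > 0)
  geom <- if (inherits(tree, "tree_geometry")) tree else geometry(tree)
  V <- sigma2 * covariance_matrix(geom, model)
  R <- chol_with_jitter(V, "trait simulation covariance")
  with_seed(seed, {
    z <- stats::rnorm(nrow(V))
    stats::setNames(drop(crossprod(R, z)), geom$tip_order)
  })
}

#' Simulate a feature matrix with planted lifespan effects
#'
#' Builds strains-by-features data `x_j = beta_j * y + eps_j`, where `y` is a
#' lifespan-like trait over the tips and the noise `eps_j` is either
#' phylogenetic (BM on the tree, the default) or iid Gaussian. The first
#' `n_planted` features carry slope `beta` on y; the remainder are null
#' (beta = 0). Optional missingness is sprinkled uniformly at random to
#' exercise the filter/imputation rules.
#'
#' Note the planted slope is expressed on the x-on-y scale; the association
#' scan regresses y on x, which detects the same features.
#'
#' @param tree A `"phylo"` tree (or `"tree_geometry"`).
#' @param y Lifespan-like trait, named by tip or in tip order.
#' @param n_features Total number of feature columns.
#' @param n_planted Number of features with a real effect.
#' @param beta Planted slope (scalar or length `n_planted`).
#' @param noise `"bm"` (phylogenetic) or `"iid"`.
#' @param noise_sigma2 Noise variance scale.
#' @param missing_rate Fraction of entries set missing, in \[0, 1).
#' @param seed Integer seed.
#' @return List with `matrix` (a `"trait_matrix"`) and `truth` (data frame
#'   `feature_id`, `beta`).
#' @export
simulate_feature_set <- function(tree, y, n_features, n_planted = 0,
                                 beta = 1, noise = c("bm", "iid"),
                                 noise_sigma2 = 1, missing_rate = 0,
                                 seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_features >= 1L, n_planted >= 0L, n_planted <= n_features,
            missing_rate >= 0, missing_rate < 1)
  geom <- if (inherits(tree, "tree_geometry")) tree else geometry(tree)
  tips <- geom$tip_order
  if (!is.null(names(y))) y <- y[tips]
  stopifnot(length(y) == length(tips), !anyNA(y))
  betas <- numeric(n_features)
  if (n_planted > 0L) betas[seq_len(n_planted)] <- rep_len(beta, n_planted)
  n <- length(tips)
  with_seed(seed, {
    if (noise == "bm") {
      V <- noise_sigma2 * covariance_matrix(geom, evolution_model("BM"))
      R <- chol_with_jitter(V, "noise covariance")
      eps <- crossprod(R, matrix(stats::rnorm(n * n_features), n, n_features))
    } else {
      eps <- matrix(stats::rnorm(n * n_features, sd = sqrt(noise_sigma2)),
                    n, n_features)
    }
    vals <- outer(as.numeric(y), betas) + eps
    dimnames(vals) <- list(tips, sprintf("f%04d", seq_len(n_features)))
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n * n_features) < missing_rate, n, n_features)
      # keep at least 2 observed values per feature so standardization works
      for (j in which(colSums(!mask) < 2L)) {
        mask[sample.int(n, 2L), j] <- FALSE
      }
      vals[mask] <- NA_real_
      n_miss <- colSums(is.na(vals))
      if (all(n_miss > 1L)) {
        stop("missing_rate leaves no feature surviving the missing-value filter",
             call. = FALSE)
      }
    }
    list(matrix = trait_matrix(vals),
         truth = data.frame(feature_id = colnames(vals), beta = betas,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-base depth profiles
#'
#' Poisson per-base depths with a common nuclear mean, a mitochondrial mean
#' of `mito_factor` times the nuclear mean, and an optional high-coverage
#' spike (emulating the collapsed rDNA repeat) inside a designated window.
#'
#' @param lengths Named integer vector of sequence lengths, including the
#'   mitochondrial sequence.
#' @param nuclear_mean Mean nuclear depth, > 0.
#' @param mito_factor Ratio of mitochondrial to nuclear mean depth, > 0.
#' @param mito Name of the mitochondrial sequence in `lengths`.
#' @param spike_region Optional one-row data frame (`chrom`, `start`, `end`,
#'   1-based inclusive) whose Poisson mean is `spike_mean`.
#' @param spike_mean Depth mean inside the spike window.
#' @param seed Integer seed.
#' @return A `"depth_profile"`.
#' @export
simulate_depth <- function(lengths, nuclear_mean, mito_factor,
                           mito = "chrM", spike_region = NULL,
                           spike_mean = 20 * nuclear_mean, seed = NULL) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0),
            nuclear_mean > 0, mito_factor > 0)
  if (!mito %in% names(lengths)) {
    stop("mitochondrial sequence '", mito, "' not in lengths", call. = FALSE)
  }
  with_seed(seed, {
    depths <- lapply(names(lengths), function(nm) {
      len <- as.integer(lengths[[nm]])
      mu <- rep(if (nm == mito) mito_factor * nuclear_mean else nuclear_mean, len)
      if (!is.null(spike_region)) {
        for (r in seq_len(nrow(spike_region))) {
          if (spike_region$chrom[r] != nm) next
          s <- as.integer(spike_region$start[r])
          e <- as.integer(spike_region$end[r])
          if (s < 1L || e > len || s > e) {
            stop("invalid spike region for '", nm, "'", call. = FALSE)
          }
          mu[s:e] <- spike_mean
        }
      }
      stats::rpois(len, mu)
    })
    names(depths) <- names(lengths)
    depth_profile(depths, mito)
  })
}
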