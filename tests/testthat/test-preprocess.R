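mk <- function(vals, strains = NULL, feats = NULL) {
  vals <- as.matrix(vals)
  rownames(vals) <- strains %||% rownames(vals) %||%
    sprintf("s%d", seq_len(nrow(vals)))
  colnames(vals) <- feats %||% colnames(vals) %||%
    sprintf("f%d", seq_len(ncol(vals)))
  trait_matrix(vals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("standardize gives n-1 z-scores, drops constants, keeps NA", {
  m <- mk(cbind(c(1, 2, 3), c(5, 5, 5), c(2, NA, 4)))
  expect_warning(z <- standardize(m), "constant")
  expect_equal(unname(z[, "f1"]), c(-1, 0, 1))
  expect_equal(attr(z, "dropped_features"), "f2")
  expect_true(is.na(z["s2", "f3"]))
  obs <- z[!is.na(z[, "f3"]), "f3"]
  expect_equal(mean(obs), 0, tolerance = 1e-9)
  expect_equal(sd(obs), 1, tolerance = 1e-9)
  # idempotence on complete data
  zz <- standardize(z[, "f1", drop = FALSE])
  expect_equal(unname(unclass(zz)), unname(unclass(z[, "f1", drop = FALSE])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize(mk(cbind(c(1, NA, NA)))), "fewer than 2")
})

test_that("filter_metabolites applies the more-than-one-strain rule with exclusion", {
  vals <- cbind(a = c(1, NA, NA, 2),  # missing in 2 non-excluded -> drop
                b = c(NA, 1, 2, 3),   # missing only in excluded -> keep
                c = c(1, NA, 2, 3),   # missing in exactly 1 other -> keep
                d = c(NA, NA, NA, 1)) # missing everywhere -> drop
  m <- mk(vals, strains = c("X378604X", "s2", "s3", "s4"))
  out <- filter_metabolites(m, excluded_strain = "X378604X")
  expect_setequal(colnames(out), c("b", "c"))
  expect_setequal(attr(out, "dropped_features"), c("a", "d"))
  # excluded strain absent from the matrix: plain <=1 missing rule
  out2 <- filter_metabolites(m, excluded_strain = "nonexistent")
  expect_setequal(colnames(out2), c("b", "c"))
})

test_that("knn_impute matches the worked neighbour examples", {
  m1 <- mk(rbind(c(1, 1), c(1, NA), c(5, 5)), strains = c("A", "B", "C"))
  out1 <- knn_impute(m1, k = 1)
  expect_equal(unname(out1["B", "f2"]), 1)

  m2 <- mk(rbind(c(0, 0), c(2, 2), c(1, NA)), strains = c("A", "C", "B"))
  out2 <- knn_impute(m2, k = 2)
  expect_equal(unname(out2["B", "f2"]), 1)  # equidistant -> equal weights

  expect_warning(out3 <- knn_impute(m2, k = 10), "using k = 2")
  expect_equal(unname(out3["B", "f2"]), 1)

  all_na <- mk(rbind(c(1, NA), c(NA, 1)), strains = c("A", "B"))
  expect_error(knn_impute(all_na, k = 1), "no complete")
})

test_that("knn_impute never alters observed values; imputations stay in neighbour range", {
  g <- rand_geom(12, seed = 44)
  y <- simulate_trait(g, evolution_model("BM"), seed = 45)
  sim <- simulate_feature_set(g, y, n_features = 20, missing_rate = 0.08,
                              seed = 46)
  m <- sim$matrix
  out <- suppressWarnings(knn_impute(m, k = 5))
  expect_false(anyNA(out))
  obs <- !is.na(unclass(m))
  expect_equal(unclass(out)[obs], unclass(m)[obs])
  was_na <- which(!obs, arr.ind = TRUE)
  complete_rows <- rowSums(obs) == ncol(m)
  for (r in seq_len(nrow(was_na))) {
    j <- was_na[r, 2]
    rng <- range(unclass(m)[complete_rows, j])
    expect_gte(out[was_na[r, 1], j], rng[1] - 1e-12)
    expect_lte(out[was_na[r, 1], j], rng[2] + 1e-12)
  }
})

test_that("aggregate_peptides averages standardized peptides per gene", {
  vals <- cbind(p1 = c(-1, 0, 1), p2 = c(1, 0, -1), p3 = c(-1, 0, 1),
                p4 = c(0, 1, -1), p5 = c(1, -1, 0), p6 = c(0.5, 0, -0.5))
  m <- trait_matrix(`rownames<-`(vals, c("s1", "s2", "s3")), standardized = TRUE)
  map <- data.frame(peptide_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_id = c("g1", "g1", "g2", "g2", "g2"))
  expect_warning(out <- aggregate_peptides(m, map), "1 peptide")
  expect_setequal(colnames(out), c("g1", "g2"))
  expect_equal(unname(out[, "g1"]), c(0, 0, 0))
  expect_equal(unname(out[, "g2"]),
               rowMeans(vals[, c("p3", "p4", "p5")]))
  expect_equal(attr(out, "n_unmapped"), 1L)
  # single-peptide gene passes through unchanged
  map1 <- data.frame(peptide_id = "p1", gene_id = "solo")
  expect_warning(one <- aggregate_peptides(m, map1))
  expect_equal(unname(one[, "solo"]), unname(vals[, "p1"]))
  raw <- trait_matrix(`rownames<-`(vals[, 1:2], c("s1", "s2", "s3")),
                      standardized = FALSE)
  expect_error(aggregate_peptides(raw, map), "standardize")
})

test_that("run_pca returns orthonormal loadings and reconstructs the data", {
  set.seed(50)
  vals <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(sprintf("s%d", 1:10), sprintf("f%d", 1:6)))
  suppressWarnings(m <- standardize(trait_matrix(vals)))
  p <- run_pca(m)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  centered <- sweep(unclass(m), 2, colMeans(unclass(m)))
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 data: two perfectly correlated features
  r1 <- mk(cbind(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  p1 <- run_pca(r1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)

  na_m <- mk(cbind(c(1, NA, 3), c(1, 2, 3)))
  expect_error(run_pca(na_m), "impute")
})

test_that("top_contributors applies the floor rule and ranks by |loading|", {
  set.seed(51)
  vals <- matrix(rnorm(30 * 392), 30, 392,
                 dimnames = list(sprintf("s%d", 1:30), sprintf("f%04d", 1:392)))
  p <- run_pca(standardize(trait_matrix(vals)))
  top <- top_contributors(p, 1, fraction = 0.10)
  expect_length(top, 39)
  expect_equal(top[1], names(which.max(abs(p$loadings[, 1]))))
  # fraction = 1 returns every feature ranked by contribution
  all_ranked <- top_contributors(p, 1, fraction = 1)
  expect_length(all_ranked, 392)
  expect_equal(order(-abs(p$loadings[all_ranked, 1])), seq_len(392))
  # small panel with distinct magnitudes: the single largest
  small <- run_pca(standardize(trait_matrix(
    matrix(rnorm(8 * 10), 8, 10,
           dimnames = list(sprintf("s%d", 1:8), sprintf("f%02d", 1:10))))))
  expect_equal(top_contributors(small, 1, fraction = 0.10),
               names(which.max(abs(small$loadings[, 1]))))
  expect_error(top_contributors(p, 1, fraction = 0), "fraction")
  expect_error(top_contributors(p, 99), "out of range")
})

test_that("correlate computes Pearson/Spearman and rejects bad input", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlate(x, x), 1)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(correlate(x, y, "spearman"),
               correlate(exp(x), y^3, "spearman"))
  expect_error(correlate(x, rep(1, 5)), "constant")
  expect_error(correlate(x, y[1:4]), "length")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("combine_blocks joins by strain and excludes incomplete blocks", {
  a <- trait_matrix(matrix(rnorm(6), 3, 2,
        dimnames = list(c("s1", "s2", "s3"), c("x", "y"))), standardized = TRUE)
  b <- trait_matrix(matrix(rnorm(4), 2, 2,
        dimnames = list(c("s1", "s2"), c("u", "v"))), standardized = TRUE)
  expect_message(cmb <- combine_blocks(list(tr = a, met = b)), "met")
  expect_equal(colnames(cmb), c("tr:x", "tr:y"))
  expect_equal(nrow(cmb), 3)
})
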