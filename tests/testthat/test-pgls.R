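test_that("covariance_matrix matches the model formulas on the 3-tip tree", {
  g <- geom3()
  C <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  dimnames(C) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(covariance_matrix(g, evolution_model("BM")), C)
  expect_equal(unname(covariance_matrix(g, evolution_model("Null"))), diag(3))
  L <- covariance_matrix(g, evolution_model("Lambda", lambda = 0.5))
  expect_equal(unname(L), rbind(c(2, 0.5, 0), c(0.5, 2, 0), c(0, 0, 2)))
  L0 <- covariance_matrix(g, evolution_model("Lambda", lambda = 0))
  expect_equal(unname(L0), diag(c(2, 2, 2)))
  ou <- covariance_matrix(g, evolution_model("OU", alpha = 1e-6))
  expect_equal(ou, C, tolerance = 1e-4)
})

test_that("OU covariance limit and parameter validation hold on non-ultrametric trees", {
  g <- geometry(tree_nonultra())
  ou <- covariance_matrix(g, evolution_model("OU", alpha = 1e-7))
  expect_equal(ou, g$mrca_depth, tolerance = 1e-5)
  # explicit OU entry check against the closed form for one pair
  a <- 0.7
  V <- covariance_matrix(g, evolution_model("OU", alpha = a))
  i <- "A"; j <- "B"
  expect_equal(V[i, j],
               exp(-a * g$patristic[i, j]) *
                 (1 - exp(-2 * a * g$mrca_depth[i, j])) / (2 * a))
  expect_error(evolution_model("Lambda", lambda = 1.2), "\\[0, 1\\]")
  expect_error(evolution_model("OU", alpha = -1), "> 0")
  expect_error(evolution_model("Lambda"), "requires")
})

test_that("gls_fit reproduces hand-computed OLS and flags perfect fits", {
  f <- gls_fit(c(1, 2, 2), c(1, 2, 3), diag(3))
  expect_equal(unname(f$beta), c(2 / 3, 0.5), tolerance = 1e-12)
  expect_false(f$degenerate)

  x <- c(1, 2, 3, 4)
  fp <- gls_fit(2 + 3 * x, x, diag(4))
  expect_true(fp$degenerate)
  expect_equal(unname(fp$beta[2]), 3, tolerance = 1e-10)
  expect_equal(fp$p_slope, 0)
  expect_false(is.finite(fp$loglik))

  expect_error(gls_fit(c(1, 2, 3), c(1, 1, 1), diag(3)), "collinear")
})

test_that("gls_fit with V = I matches lm() exactly", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n, 1 + 0.5 * x)
    f <- gls_fit(y, x, diag(n))
    s <- summary(lm(y ~ x))$coefficients
    expect_equal(unname(f$beta), unname(s[, 1]), tolerance = 1e-10)
    expect_equal(f$t_slope, s[2, 3], tolerance = 1e-10)
    expect_equal(f$p_slope, s[2, 4], tolerance = 1e-10)
  }
})

test_that("gls_fit log-likelihood equals the direct MVN log-density", {
  set.seed(21)
  for (rep in 1:10) {
    g <- rand_geom(sample(3:6, 1), seed = 100 + rep)
    n <- length(g$tip_order)
    V <- covariance_matrix(g, evolution_model("BM"))
    x <- rnorm(n)
    y <- rnorm(n, x)
    f <- gls_fit(y, x, V)
    mu <- drop(cbind(1, x) %*% f$beta)
    expect_equal(f$loglik, mvn_logdensity(y, mu, f$sigma2_ml * V),
                 tolerance = 1e-8)
  }
})

test_that("whitening equivalence: GLS equals OLS on decorrelated data", {
  set.seed(31)
  for (rep in 1:5) {
    g <- rand_geom(15, seed = 200 + rep)
    V <- covariance_matrix(g, evolution_model("BM"))
    x <- rnorm(15); y <- rnorm(15, 2 * x)
    f <- gls_fit(y, x, V)
    R <- chol(V)
    yw <- backsolve(R, y, transpose = TRUE)
    Xw <- backsolve(R, cbind(1, x), transpose = TRUE)
    beta_w <- qr.solve(Xw, yw)
    expect_equal(unname(f$beta), unname(beta_w), tolerance = 1e-8)
  }
})

test_that("fit_pgls profile optimum dominates the interval endpoints", {
  g <- rand_geom(25, seed = 5)
  y <- simulate_trait(g, evolution_model("Lambda", lambda = 0.6), seed = 6)
  x <- simulate_trait(g, evolution_model("BM"), seed = 7)
  f <- fit_pgls(y, x, g, "Lambda")
  for (lam in c(0, 1)) {
    end <- gls_fit(y, x, covariance_matrix(g, evolution_model("Lambda", lambda = lam)))
    expect_gte(f$loglik, end$loglik - 1e-9)
  }
  expect_true(f$converged)
  fo <- fit_pgls(y, x, g, "OU")
  h <- max(diag(g$mrca_depth))
  for (a in c(1e-4 / h, 100 / h)) {
    end <- gls_fit(y, x, covariance_matrix(g, evolution_model("OU", alpha = a)))
    expect_gte(fo$loglik, end$loglik - 1e-9)
  }
})

test_that("lambda estimates separate phylogenetic from iid data (small panel)", {
  lam_bm <- lam_iid <- numeric(20)
  for (r in 1:20) {
    g <- rand_geom(60, seed = 300 + r)
    y <- simulate_trait(g, evolution_model("BM"), seed = 400 + r)
    x <- simulate_trait(g, evolution_model("BM"), seed = 500 + r)
    lam_bm[r] <- fit_pgls(y, x, g, "Lambda", optimize_tol = 1e-4)$model$lambda
    set.seed(600 + r)
    lam_iid[r] <- fit_pgls(rnorm(60), rnorm(60), g, "Lambda",
                           optimize_tol = 1e-4)$model$lambda
  }
  expect_gte(median(lam_bm), 0.8)
  expect_lte(median(lam_iid), 0.2)
})

test_that("select_best_model maximizes loglik with simplicity tie-breaks", {
  fits <- list(make_fake_fit("Null", -12), make_fake_fit("BM", -9),
               make_fake_fit("Lambda", -8.5), make_fake_fit("OU", -9.5))
  expect_equal(select_best_model(fits)$model$kind, "Lambda")

  tied <- list(make_fake_fit("Null", -9), make_fake_fit("BM", -9),
               make_fake_fit("Lambda", -9), make_fake_fit("OU", -9))
  expect_equal(select_best_model(tied)$model$kind, "Null")

  excl <- list(make_fake_fit("Null", -9), make_fake_fit("BM", -9),
               make_fake_fit("Lambda", -9, converged = FALSE),
               make_fake_fit("OU", -9))
  expect_equal(select_best_model(excl)$model$kind, "Null")

  none <- list(make_fake_fit("BM", -9, converged = FALSE))
  expect_error(select_best_model(none), "no converged")
})

test_that("loo_pvalues returns one entry per strain and detects outlier-driven fits", {
  g <- rand_geom(10, seed = 8)
  tips <- g$tip_order
  set.seed(9)
  # strong planted effect: every LOO p small
  x <- simulate_trait(g, evolution_model("BM"), seed = 10)
  y <- 3 * x + rnorm(10, sd = 0.3)
  lo <- loo_pvalues(y, x, g, "Lambda")
  expect_length(lo$p, 10)
  expect_named(lo$p, tips)
  expect_true(all(lo$p < 0.05, na.rm = TRUE))
  expect_equal(lo$max_p, max(lo$p, na.rm = TRUE))

  # association carried by one constructed outlier strain
  set.seed(12)
  x2 <- c(10, rnorm(9, sd = 0.5))
  y2 <- c(10, rnorm(9, sd = 0.5))
  lo2 <- loo_pvalues(y2, x2, g, "Null")
  expect_gt(lo2$max_p, 0.05)
  expect_error(loo_pvalues(y2[1:3], x2[1:3], prune_geometry(g, tips[1:3]), "Null"),
               "at least 4")
})
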