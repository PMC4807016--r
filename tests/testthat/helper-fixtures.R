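# Shared fixtures built in code. tree3 is the canonical 3-tip example;
# tree_nonultra has unequal tip depths to exercise non-ultrametric formulas.

tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
geom3 <- function() geometry(tree3())

tree_nonultra <- function() parse_newick("((A:0.5,B:2):1,(C:3,D:0.2):0.4);")

rand_geom <- function(n, seed) geometry(simulate_tree(n, seed = seed))

# direct multivariate-normal log-density, the independent likelihood oracle
mvn_logdensity <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(Sigma) %*% r))
}

make_fake_fit <- function(kind, loglik, converged = TRUE, lambda = 0.5,
                          alpha = 1) {
  model <- switch(kind,
    Lambda = evolution_model("Lambda", lambda = lambda),
    OU = evolution_model("OU", alpha = alpha),
    evolution_model(kind))
  structure(list(beta = c(0, 0), sigma2_ml = 1, loglik = loglik,
                 t_slope = 0, p_slope = 1, df = 1L, n = 3L,
                 degenerate = FALSE, model = model, converged = converged),
            class = c("pgls_fit", "gls_fit"))
}
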