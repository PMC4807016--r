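#' Trait-evolution model specification
#'
#' Four error-covariance models for continuous traits on a phylogeny:
#' \describe{
#'   \item{Null}{no phylogenetic structure, V = I;}
#'   \item{BM}{Brownian motion, V = C, the MRCA-depth matrix;}
#'   \item{Lambda}{Pagel's lambda, off-diagonal entries of C multiplied by
#'     lambda in \[0, 1\];}
#'   \item{OU}{fixed-root Ornstein-Uhlenbeck with reversion strength alpha
#'     (per unit branch length), valid on non-ultrametric trees, with the
#'     BM limit as alpha tends to 0.}
#' }
#' The overall rate sigma^2 scales V and is profiled out analytically during
#' fitting, so it is not a free parameter here.
#'
#' @param kind One of `"Null"`, `"BM"`, `"Lambda"`, `"OU"`.
#' @param lambda Pagel's lambda in \[0, 1\] (Lambda model only).
#' @param alpha OU reversion strength, > 0 (OU model only).
#' @return An object of class `"evolution_model"`.
#' @examples
#' evolution_model("Lambda", lambda = 0.5)
#' @export
evolution_model <- function(kind = c("Null", "BM", "Lambda", "OU"),
                            lambda = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "Lambda") {
    if (is.null(lambda)) stop("Lambda model requires 'lambda'", call. = FALSE)
    if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must lie in [0, 1]", call. = FALSE)
    }
  }
  if (kind == "OU") {
    if (is.null(alpha)) stop("OU model requires 'alpha'", call. = FALSE)
    if (!is.finite(alpha) || alpha <= 0) {
      stop("alpha must be > 0", call. = FALSE)
    }
  }
  structure(list(kind = kind, lambda = lambda, alpha = alpha),
            class = "evolution_model")
}

#' @export
print.evolution_model <- function(x, ...) {
  par <- switch(x$kind,
    Lambda = sprintf(" (lambda = %.4g)", x$lambda),
    OU = sprintf(" (alpha = %.4g)", x$alpha),
    "")
  cat("evolution_model: ", x$kind, par, "\n", sep = "")
  invisible(x)
}

#' Phylogenetic covariance matrix under a trait-evolution model
#'
#' Builds the among-tip covariance matrix V (up to the rate sigma^2) from
#' tree geometry. With C the MRCA-depth matrix and D the patristic-distance
#' matrix:
#' Null gives I; BM gives C; Lambda keeps the diagonal of C and multiplies
#' off-diagonals by lambda; fixed-root OU gives
#' `V[i,j] = exp(-alpha * D[i,j]) * (1 - exp(-2 * alpha * C[i,j])) / (2 * alpha)`,
#' which tends entrywise to C as alpha tends to 0.
#'
#' @param geom A `"tree_geometry"` from [geometry()].
#' @param model An `"evolution_model"`.
#' @return A symmetric positive-definite matrix with tip labels as dimnames.
#' @examples
#' g <- geometry(parse_newick("((A:1,B:1):1,C:2);"))
#' covariance_matrix(g, evolution_model("Lambda", lambda = 0.5))
#' @export
covariance_matrix <- function(geom, model) {
  stopifnot(inherits(geom, "tree_geometry"), inherits(model, "evolution_model"))
  C <- geom$mrca_depth
  V <- switch(model$kind,
    Null = diag(nrow(C)),
    BM = C,
    Lambda = {
      V <- model$lambda * C
      diag(V) <- diag(C)
      V
    },
    OU = {
      a <- model$alpha
      # -expm1 is the stable form of (1 - exp(.)) for small alpha
      exp(-a * geom$patristic) * (-expm1(-2 * a * C)) / (2 * a)
    }
  )
  dimnames(V) <- dimnames(C)
  V
}

# Cholesky with a single-jitter fallback: on failure add 1e-10 * trace/n to
# the diagonal once, then give up with an informative error.
chol_with_jitter <- function(V, context = "covariance matrix") {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * sum(diag(V)) / nrow(V)
    R <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (is.null(R)) {
      stop(context, " is not positive definite (even after jitter)", call. = FALSE)
    }
  }
  R
}

#' Generalized least squares fit of a simple regression
#'
#' Fits `y = b0 + b1 * x + e`, `e ~ N(0, sigma^2 V)`, by GLS. The ML variance
#' estimate `sigma2_ml` uses n in the denominator (it enters the maximized
#' log-likelihood); the slope standard error uses the unbiased estimate with
#' n - 2, and the slope is tested two-sided against Student's t with n - 2
#' degrees of freedom.
#'
#' A perfect fit (residual quadratic form numerically zero) is flagged
#' `degenerate`: the log-likelihood diverges and is reported as `Inf`, and
#' `p_slope` is set to 0 by convention.
#'
#' @param y Numeric response vector.
#' @param x Numeric predictor vector.
#' @param V Covariance matrix (positive definite, same dimension).
#' @return An object of class `"gls_fit"`: list with `beta` (intercept,
#'   slope), `sigma2_ml`, `loglik`, `t_slope`, `p_slope`, `df`, `n`,
#'   `degenerate`.
#' @examples
#' f <- gls_fit(c(1, 2, 2), c(1, 2, 3), diag(3))
#' f$beta
#' @export
gls_fit <- function(y, x, V) {
  n <- length(y)
  stopifnot(length(x) == n, is.matrix(V), nrow(V) == n, ncol(V) == n)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  R <- chol_with_jitter(V)
  # whiten: L^{-1} y with V = L L', L = t(R)
  yw <- backsolve(R, y, transpose = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  Xw <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (!is.finite(rcond(XtX)) || rcond(XtX) < 1e-12) {
    stop("design is collinear (constant predictor?)", call. = FALSE)
  }
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  resw <- yw - drop(Xw %*% beta)
  q <- sum(resw^2)
  logdetV <- 2 * sum(log(diag(R)))
  scale_ref <- max(sum(yw^2), .Machine$double.eps)
  degenerate <- (q / scale_ref) < 1e-12
  df <- n - 2L
  if (degenerate) {
    t_slope <- sign(beta[2]) * Inf
    p_slope <- 0
    loglik <- Inf
    sigma2_ml <- 0
  } else {
    sigma2_ml <- q / n
    loglik <- -n / 2 * log(2 * pi * sigma2_ml) - logdetV / 2 - n / 2
    sigma2_unb <- q / df
    se_slope <- sqrt(sigma2_unb * XtXi[2, 2])
    t_slope <- beta[2] / se_slope
    p_slope <- 2 * stats::pt(-abs(t_slope), df = df)
  }
  structure(
    list(beta = beta, sigma2_ml = sigma2_ml, loglik = loglik,
         t_slope = unname(t_slope), p_slope = unname(p_slope),
         df = df, n = n, degenerate = degenerate),
    class = "gls_fit"
  )
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("gls_fit: n = %d, slope = %.4g (t = %.3g, p = %.3g), loglik = %.4g%s\n",
              x$n, x$beta[2], x$t_slope, x$p_slope, x$loglik,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Profile log-likelihood of a model parameter: sigma^2 and beta are profiled
# inside gls_fit, leaving a 1-d function of lambda or log(alpha).
profile_loglik <- function(par, kind, y, x, geom) {
  model <- switch(kind,
    Lambda = evolution_model("Lambda", lambda = par),
    OU = evolution_model("OU", alpha = exp(par))
  )
  fit <- tryCatch(gls_fit(y, x, covariance_matrix(geom, model)),
                  error = function(e) NULL)
  # large finite sentinels keep optimize() quiet on degenerate (+Inf)
  # or failed (-Inf) evaluations
  if (is.null(fit)) return(-1e300)
  if (!is.finite(fit$loglik)) return(if (fit$degenerate) 1e300 else -1e300)
  fit$loglik
}

#' Fit PGLS under one trait-evolution model
#'
#' Null and BM have no free covariance parameter and reduce to a single GLS
#' fit. For Lambda and OU the parameter is estimated by maximizing the
#' profile log-likelihood (sigma^2 and the coefficients are profiled out
#' analytically): lambda by bounded search on \[0, 1\], alpha by search on
#' log(alpha) in `[log(1e-4 / h), log(100 / h)]` where h is the maximum tip
#' depth. Both interval endpoints are also evaluated so the returned optimum
#' never falls below them.
#'
#' @param y Response vector (one lifespan measure), named or ordered as
#'   `geom$tip_order`.
#' @param x Predictor vector (one feature), same order.
#' @param geom A `"tree_geometry"`.
#' @param kind Model kind: `"Null"`, `"BM"`, `"Lambda"` or `"OU"`.
#' @param optimize_tol Convergence tolerance passed to [stats::optimize()].
#' @return An object of class `"pgls_fit"`: the `"gls_fit"` fields plus
#'   `model` (with the estimated parameter) and `converged`.
#' @export
fit_pgls <- function(y, x, geom, kind = c("Null", "BM", "Lambda", "OU"),
                     optimize_tol = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(inherits(geom, "tree_geometry"))
  n <- length(geom$tip_order)
  stopifnot(length(y) == n, length(x) == n)

  if (kind %in% c("Null", "BM")) {
    model <- evolution_model(kind)
    fit <- gls_fit(y, x, covariance_matrix(geom, model))
    return(as_pgls_fit(fit, model, converged = TRUE))
  }

  if (kind == "Lambda") {
    bounds <- c(0, 1)
    to_model <- function(p) evolution_model("Lambda", lambda = p)
  } else {
    h <- max(diag(geom$mrca_depth))
    bounds <- log(c(1e-4 / h, 100 / h))
    to_model <- function(p) evolution_model("OU", alpha = exp(p))
  }

  f <- function(p) profile_loglik(p, kind, y, x, geom)
  opt <- tryCatch(
    stats::optimize(f, interval = bounds, maximum = TRUE, tol = optimize_tol),
    error = function(e) NULL
  )
  cand_par <- c(if (!is.null(opt)) opt$maximum, bounds)
  cand_ll <- c(if (!is.null(opt)) opt$objective, f(bounds[1]), f(bounds[2]))
  if (all(cand_ll <= -1e300)) {
    # every evaluation failed: report a non-converged shell fit
    fit <- structure(
      list(beta = c(NA_real_, NA_real_), sigma2_ml = NA_real_, loglik = -Inf,
           t_slope = NA_real_, p_slope = NA_real_, df = n - 2L, n = n,
           degenerate = FALSE),
      class = "gls_fit")
    return(as_pgls_fit(fit, to_model(mean(bounds)), converged = FALSE))
  }
  model <- to_model(cand_par[which.max(cand_ll)])
  fit <- gls_fit(y, x, covariance_matrix(geom, model))
  as_pgls_fit(fit, model, converged = !is.null(opt))
}

as_pgls_fit <- function(fit, model, converged) {
  fit$model <- model
  fit$converged <- converged
  class(fit) <- c("pgls_fit", "gls_fit")
  fit
}

#' @export
print.pgls_fit <- function(x, ...) {
  par <- switch(x$model$kind,
    Lambda = sprintf(", lambda = %.3g", x$model$lambda),
    OU = sprintf(", alpha = %.3g", x$model$alpha),
    "")
  cat(sprintf("pgls_fit [%s%s]: n = %d, slope = %.4g (p = %.3g), loglik = %.4g%s%s\n",
              x$model$kind, par, x$n, x$beta[2], x$p_slope, x$loglik,
              if (!x$converged) " [not converged]" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Select the best-fitting trait-evolution model
#'
#' Among converged fits, returns the one with the highest maximized
#' log-likelihood (raw ML, not AIC, by default). Exact ties are broken toward
#' fewer parameters in the order Null, BM, Lambda, OU.
#'
#' @param fits A list of `"pgls_fit"` objects (typically one per model kind).
#' @param criterion `"loglik"` (default) or `"aic"`.
#' @return The selected `"pgls_fit"`.
#' @export
select_best_model <- function(fits, criterion = c("loglik", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 1L)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits to select from", call. = FALSE)
  order_pref <- c(Null = 1L, BM = 2L, Lambda = 3L, OU = 4L)
  n_par <- c(Null = 3, BM = 3, Lambda = 4, OU = 4)  # b0, b1, sigma2 (+ par)
  score <- vapply(conv, function(f) {
    if (criterion == "loglik") f$loglik else -(2 * n_par[[f$model$kind]] - 2 * f$loglik)
  }, numeric(1))
  best_score <- max(score)
  tied <- which(score == best_score)
  pref <- vapply(conv[tied], function(f) order_pref[[f$model$kind]], integer(1))
  conv[[tied[which.min(pref)]]]
}

#' Leave-one-out slope p-values
#'
#' Refits the PGLS regression n times, each time with one strain removed
#' (the tree is pruned by subsetting the geometry; MRCA depths and patristic
#' distances of the remaining pairs are unchanged), and collects the slope
#' p-value of each subfit. An association driven by a single strain shows a
#' large p-value when that strain is left out. Degenerate subfits are flagged
#' `NA` and excluded from `max_p`.
#'
#' @param y,x,geom,kind As in [fit_pgls()].
#' @param optimize_tol Tolerance for the per-subfit parameter search.
#' @return A list with `p` (named vector, one entry per left-out strain) and
#'   `max_p` (maximum over non-degenerate entries).
#' @export
loo_pvalues <- function(y, x, geom, kind = c("Null", "BM", "Lambda", "OU"),
                        optimize_tol = 1e-4) {
  kind <- match.arg(kind)
  tips <- geom$tip_order
  n <- length(tips)
  if (n < 4L) stop("leave-one-out needs at least 4 strains", call. = FALSE)
  stopifnot(length(y) == n, length(x) == n)
  p <- stats::setNames(rep(NA_real_, n), tips)
  for (i in seq_len(n)) {
    keep <- tips[-i]
    sub <- prune_geometry(geom, keep)
    fit <- tryCatch(
      fit_pgls(y[-i], x[-i], sub, kind, optimize_tol = optimize_tol),
      error = function(e) NULL
    )
    if (!is.null(fit) && !fit$degenerate && is.finite(fit$p_slope)) {
      p[i] <- fit$p_slope
    }
  }
  list(p = p, max_p = if (all(is.na(p))) NA_real_ else max(p, na.rm = TRUE))
}
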