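#' Regularized canonical correlation analysis (first pair)
#'
#' Finds weight vectors u, v maximizing the correlation between Xu and Yv
#' with ridge-regularized covariance matrices Cxx + lambda_x I and
#' Cyy + lambda_y I, which keeps the problem well posed when variables
#' outnumber subjects. Solved through the symmetric p x p eigenproblem on
#' the X side; the Y-side inverse uses the Woodbury identity so the cost is
#' O(n^2 q) even for many thousands of vertex columns. Columns are
#' standardized internally; the sign convention makes the X weight of
#' largest magnitude positive. Only the first canonical pair is modeled.
#'
#' @param X subjects x p behavioral matrix (no missing values)
#' @param Y subjects x q AFD matrix (no missing values)
#' @param lambda_x,lambda_y ridge regularizers >= 0
#' @return object of class `rcca`: `canonical_corr`, `u_weights`,
#'   `v_weights`, `U`, `V` (unit-variance canonical variates), `loadings_x`,
#'   `loadings_y` (correlations of each column with its variate), `lambda_x`,
#'   `lambda_y`; confidence intervals are NULL until
#'   [permutation_loading_cis()]
#' @export
fit_rcca <- function(X, Y, lambda_x = 0, lambda_y = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values: impute or drop before fitting")
  if (lambda_x < 0 || lambda_y < 0) stop("regularizers must be nonnegative")
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n >= 4)
  p <- ncol(X); q <- ncol(Y)
  if (lambda_y == 0 && q >= n)
    stop("Cyy is singular with q >= n; use lambda_y > 0")
  if (lambda_x == 0 && p >= n)
    stop("Cxx is singular with p >= n; use lambda_x > 0")
  Xs <- scale(X); Ys <- scale(Y)
  if (any(!is.finite(Xs)) || any(!is.finite(Ys)))
    stop("zero-variance columns: drop them before fitting")
  m <- n - 1
  Cxx <- crossprod(Xs) / m + lambda_x * diag(p)
  ex <- eigen(Cxx, symmetric = TRUE)
  Cxx_ih <- ex$vectors %*% (t(ex$vectors) / sqrt(pmax(ex$values, 1e-300)))
  ## K = Cxx^{-1/2} Cxy Cyy^{-1} Cyx Cxx^{-1/2}, symmetric PSD. For q <= n
  ## (or lambda_y = 0) invert the q x q Cyy directly; for q > n use the
  ## Woodbury identity (Y'Y/m + l I)^{-1} Y' = Y' (YY'/m + l I_n)^{-1}.
  if (q <= n || lambda_y == 0) {
    Cyy <- crossprod(Ys) / m + lambda_y * diag(q)
    Cyx <- crossprod(Ys, Xs) / m           # q x p
    M <- crossprod(Cyx, solve(Cyy, Cyx))   # p x p
    vfun <- function(u) as.vector(solve(Cyy, Cyx %*% u))
  } else {
    G <- tcrossprod(Ys) / m
    A <- G + lambda_y * diag(n)
    AinvX <- solve(A, Xs)                  # n x p
    M <- crossprod(Xs, G %*% AinvX) / m    # Cxy Cyy^{-1} Cyx, p x p
    vfun <- function(u) as.vector(crossprod(Ys, solve(A, Xs %*% u))) / m
  }
  K <- Cxx_ih %*% M %*% Cxx_ih
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  u <- as.vector(Cxx_ih %*% ek$vectors[, 1])
  v <- vfun(u)                             # proportional to Cyy^{-1} Cyx u
  ## deterministic sign: largest-|u| behavioral weight positive
  s <- sign(u[which.max(abs(u))])
  if (s < 0) { u <- -u; v <- -v }
  U <- as.vector(Xs %*% u)
  V <- as.vector(Ys %*% v)
  if (stats::sd(U) > 0) { u <- u / stats::sd(U); U <- U / stats::sd(U) }
  if (stats::sd(V) > 0) { v <- v / stats::sd(V); V <- V / stats::sd(V) }
  rho <- if (stats::sd(U) > 0 && stats::sd(V) > 0) stats::cor(U, V) else NA_real_
  structure(list(canonical_corr = rho, u_weights = u, v_weights = v,
                 U = U, V = V,
                 loadings_x = as.vector(stats::cor(Xs, U)),
                 loadings_y = as.vector(stats::cor(Ys, V)),
                 lambda_x = lambda_x, lambda_y = lambda_y,
                 ci99 = NULL, n_perm = 0L, n = n, p = p, q = q),
            class = "rcca")
}

#' @export
print.rcca <- function(x, ...) {
  cat(sprintf("rCCA (first pair): n = %d, p = %d, q = %d\n", x$n, x$p, x$q))
  cat(sprintf("  lambda_x = %.3g, lambda_y = %.3g, canonical correlation = %.3f\n",
              x$lambda_x, x$lambda_y, x$canonical_corr))
  if (!is.null(x$ci99))
    cat(sprintf("  permutation CIs from %d permutations: %d/%d X and %d/%d Y variables flagged\n",
                x$n_perm, sum(x$ci99$x$significant), x$p,
                sum(x$ci99$y$significant), x$q))
  invisible(x)
}

#' @export
summary.rcca <- function(object, ...) {
  print(object)
  if (!is.null(object$ci99)) {
    cat("\nFlagged behavioral variables:\n")
    fx <- object$ci99$x
    print(fx[fx$significant, c("variable", "loading", "lower", "upper")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.rcca <- function(object, side = c("x", "y"), ...) {
  side <- match.arg(side)
  if (side == "x") object$u_weights else object$v_weights
}

#' Grid search of the regularizers by cross-validated variate correlation
#'
#' For every lambda pair, fits on training folds and correlates the
#' held-out canonical variates computed with the training weights; the pair
#' maximizing the mean out-of-fold correlation wins and the model is refit
#' on all data. (The in-sample canonical correlation is degenerate when
#' q >= n at lambda_y = 0, so cross-validation is the operative reading of
#' "maximize the correlation of the variates".)
#'
#' @param X,Y as in [fit_rcca()]
#' @param grid data frame / matrix with columns lambda_x, lambda_y; default
#'   6 log-spaced values per side spanning 1e-3 to 1e2 times the mean
#'   covariance diagonal (i.e. 1e-3 ... 1e2 after standardization)
#' @param k_folds folds (every fold must keep >= 3 subjects)
#' @param seed integer fold-assignment seed
#' @return list with `lambda` (the winning pair), `cv_corr` (its mean
#'   out-of-fold correlation), `fit` (the refit `rcca`), `cv_table`
#' @export
grid_search_lambdas <- function(X, Y, grid = NULL, k_folds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(grid)) {
    lv <- 10^seq(-3, 2, length.out = 6)
    grid <- expand.grid(lambda_x = lv, lambda_y = lv)
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) == 1) {
    fit <- fit_rcca(X, Y, grid$lambda_x[1], grid$lambda_y[1])
    return(list(lambda = grid[1, ], cv_corr = NA_real_, fit = fit,
                cv_table = cbind(grid, cv_corr = NA_real_)))
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  if (min(table(fold)) < 3) stop("folds with fewer than 3 subjects; reduce k_folds")
  cv <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    rs <- vapply(seq_len(k_folds), function(k) {
      tr <- fold != k; te <- !tr
      f <- tryCatch(fit_rcca(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                             grid$lambda_x[gidx], grid$lambda_y[gidx]),
                    error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      mx <- colMeans(X[tr, , drop = FALSE]); sx <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      my <- colMeans(Y[tr, , drop = FALSE]); sy <- apply(Y[tr, , drop = FALSE], 2, stats::sd)
      sx[sx == 0] <- 1; sy[sy == 0] <- 1
      Ute <- scale(X[te, , drop = FALSE], mx, sx) %*% f$u_weights
      Vte <- scale(Y[te, , drop = FALSE], my, sy) %*% f$v_weights
      if (stats::sd(Ute) == 0 || stats::sd(Vte) == 0) return(NA_real_)
      stats::cor(Ute, Vte)[1, 1]
    }, numeric(1))
    cv[gidx] <- mean(rs, na.rm = TRUE)
  }
  best <- which.max(cv)
  fit <- fit_rcca(X, Y, grid$lambda_x[best], grid$lambda_y[best])
  list(lambda = grid[best, ], cv_corr = cv[best], fit = fit,
       cv_table = cbind(grid, cv_corr = cv))
}

#' Permutation confidence intervals for rCCA loadings
#'
#' Builds null distributions of the loadings by refitting the model at the
#' chosen regularizers after randomly permuting the rows of Y, and returns
#' the central `level` interval per variable; a variable is flagged
#' significant when its observed loading falls outside its own null
#' interval. `n_perm = 0` is a no-op (point estimates unchanged, no CIs).
#'
#' @param fit an [fit_rcca()] result
#' @param X,Y the matrices the model was fit on
#' @param n_perm number of permutations (default 10000; a warning below
#'   100 as intervals become unstable)
#' @param level central coverage (default 0.99)
#' @param seed integer
#' @return the `rcca` object with `ci99` filled: data frames `x` and `y`
#'   with columns variable, loading, lower, upper, significant
#' @export
permutation_loading_cis <- function(fit, X, Y, n_perm = 10000, level = 0.99,
                                    seed = 1) {
  if (n_perm == 0) return(fit)
  if (n_perm < 100) warning("fewer than 100 permutations: unstable intervals")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  lx <- matrix(NA_real_, n_perm, ncol(X))
  ly <- matrix(NA_real_, n_perm, ncol(Y))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      f <- tryCatch(fit_rcca(X, Y[sample.int(n), , drop = FALSE],
                             fit$lambda_x, fit$lambda_y),
                    error = function(e) NULL)
      if (is.null(f)) next
      lx[i, ] <- f$loadings_x
      ly[i, ] <- f$loadings_y
    }
  })
  a <- (1 - level) / 2
  mk <- function(obs, nulls, names) {
    lo <- apply(nulls, 2, stats::quantile, probs = a, na.rm = TRUE)
    hi <- apply(nulls, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
    data.frame(variable = names, loading = obs, lower = lo, upper = hi,
               significant = obs < lo | obs > hi, row.names = NULL)
  }
  nx <- colnames(X); if (is.null(nx)) nx <- paste0("x", seq_len(ncol(X)))
  ny <- colnames(Y); if (is.null(ny)) ny <- paste0("y", seq_len(ncol(Y)))
  fit$ci99 <- list(x = mk(fit$loadings_x, lx, nx),
                   y = mk(fit$loadings_y, ly, ny), level = level)
  fit$n_perm <- n_perm
  fit
}
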