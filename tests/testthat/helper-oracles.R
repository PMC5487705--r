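# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: Cox-de Boor recursion instead of splineDesign,
# dense textbook REML instead of the MME determinant identities, explicit
# summation instead of matrix products.

# single B-spline value by the Cox-de Boor recursion
cdb_one <- function(x, i, k, t) {
  if (k == 0) return(as.numeric(t[i] <= x && x < t[i + 1]))
  a <- if (t[i + k] > t[i])
    (x - t[i]) / (t[i + k] - t[i]) * cdb_one(x, i, k - 1, t) else 0
  b <- if (t[i + k + 1] > t[i + 1])
    (t[i + k + 1] - x) / (t[i + k + 1] - t[i + 1]) *
      cdb_one(x, i + 1, k - 1, t) else 0
  a + b
}

cdb_row <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1
  vapply(seq_len(nb), function(i) cdb_one(x, i, degree, knots), 0)
}

# dense textbook REML deviance: -2 l_R = (n-p) log 2pi + log|V| +
# log|X' V^-1 X| + y' P y
dense_reml_deviance <- function(spec, vc) {
  vc <- unlist(vc)
  y <- spec$y; X <- spec$X
  n <- length(y); p <- ncol(X)
  V <- diag(vc[["sigma2_e"]], n)
  for (k in names(spec$random)) {
    b <- spec$random[[k]]
    V <- V + vc[[k]] * b$Z %*% (t(b$Z) / b$prec)
  }
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, crossprod(X, Vi %*% y))
  (n - p) * log(2 * pi) +
    as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
    drop(crossprod(y, Py)) -
    as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
}

# profiled dense deviance at fixed variance RATIOS lambda_k = sigma2_e /
# sigma2_k, minimized over sigma2_e in closed form; returns the deviance
# and the implied components
profiled_dense_deviance <- function(spec, lambda) {
  y <- spec$y; X <- spec$X
  n <- length(y); p <- ncol(X)
  V0 <- diag(n)
  for (k in names(spec$random)) {
    b <- spec$random[[k]]
    V0 <- V0 + (1 / lambda[[k]]) * b$Z %*% (t(b$Z) / b$prec)
  }
  Vi <- solve(V0)
  XtViX <- crossprod(X, Vi %*% X)
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, crossprod(X, Vi %*% y))
  s2 <- drop(crossprod(y, Py)) / (n - p)
  dev <- (n - p) * log(2 * pi) + (n - p) * log(s2) +
    as.numeric(determinant(V0, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + (n - p) -
    as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  list(deviance = dev, sigma2_e = s2,
       sigma2 = s2 / unlist(lambda[names(spec$random)]))
}

# small mm_spec with genotype + row + column random blocks and no spatial
# surface: few enough components for brute-force likelihood work
small_rcg_spec <- function(seed, nr = 6, nc = 6, n_geno = 12,
                           sigma2_g = 1, sigma2_r = 0.5, sigma2_c = 0.5,
                           sigma2_e = 0.5) {
  set.seed(seed)
  grid <- expand.grid(row = 1:nr, col = 1:nc)
  geno <- sample(rep(sprintf("G%02d", 1:n_geno),
                     length.out = nrow(grid)))
  g <- rnorm(n_geno, 0, sqrt(sigma2_g))
  r <- rnorm(nr, 0, sqrt(sigma2_r))
  cc <- rnorm(nc, 0, sqrt(sigma2_c))
  y <- 5 + g[as.integer(factor(geno))] + r[grid$row] + cc[grid$col] +
    rnorm(nrow(grid), 0, sqrt(sigma2_e))
  ind <- function(v) {
    lv <- sort(unique(v))
    Z <- outer(v, lv, `==`) * 1
    colnames(Z) <- as.character(lv)
    Z
  }
  new_mm_spec(y, cbind("(Intercept)" = rep(1, nrow(grid))),
              list(geno = list(Z = ind(geno)),
                   row = list(Z = ind(grid$row)),
                   col = list(Z = ind(grid$col))))
}

# quick simulated trial for fit-level tests
quick_trial <- function(seed, nr = 20, nc = 10, n_geno = 120, n_checks = 4,
                        amplitude = sqrt(0.2), missing_rate = 0.05, ...) {
  simulate_trial(sim_params(
    n_rows = nr, n_cols = nc, n_geno = n_geno, n_checks = n_checks,
    p_rep = 0.3, missing_rate = missing_rate,
    surface = list(type = "smooth", amplitude = amplitude,
                   shape_seed = seed),
    seed = seed, ...))
}
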