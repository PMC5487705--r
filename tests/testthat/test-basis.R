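test_that("basis size, partition of unity and non-negativity hold across settings", {
  set.seed(42)
  for (cfg in list(c(11, 3), c(31, 3), c(5, 2), c(8, 1), c(2, 3))) {
    nk <- cfg[1]; dg <- cfg[2]
    x <- runif(50, 1, 20)
    b <- bspline_basis(x, nk, degree = dg, domain = c(1, 20))
    expect_equal(b$n_basis, nk - 1 + dg)
    expect_equal(ncol(b$B), nk - 1 + dg)
    expect_true(all(b$B >= 0))
    expect_equal(rowSums(b$B), rep(1, 50), tolerance = 1e-10)
  }
  # the reference settings: 31 knots, cubic -> 33 columns
  expect_equal(ncol(bspline_basis(1:31, 31, 3)$B), 33)
})

test_that("basis rows match an independent Cox-de Boor recursion", {
  b <- bspline_basis(1:10, n_knots = 6, degree = 3, domain = c(1, 10))
  set.seed(7)
  for (x in runif(8, 1.01, 9.99)) {
    row <- evaluate_basis(b, x)
    expect_equal(unname(drop(row)), cdb_row(x, b$knots, 3),
                 tolerance = 1e-12)
  }
})

test_that("evaluation outside the domain is rejected", {
  b <- bspline_basis(1:10, 5)
  expect_error(evaluate_basis(b, 10.5), "outside")
  expect_error(evaluate_basis(b, 0.5), "outside")
  expect_silent(evaluate_basis(b, c(1, 10)))  # endpoints are in range
})

test_that("difference penalty: smallest case, null space, summation oracle", {
  p <- difference_penalty(3, 2)
  expect_equal(p$D, matrix(c(1, -2, 1), 1), ignore_attr = TRUE)
  expect_equal(p$P, matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3),
               ignore_attr = TRUE)

  for (nb in c(5, 12, 33)) {
    p <- difference_penalty(nb, 2)
    expect_equal(p$null_dim, 2)
    expect_true(all(p$values >= 0))
    # the null space reproduces constants and linear trends
    N <- p$vectors[, 1:2]
    for (v in list(rep(1, nb), seq_len(nb))) {
      proj <- N %*% crossprod(N, v)
      expect_equal(drop(proj), v, tolerance = 1e-8)
    }
    # P %*% v equals explicit double differencing: second difference of v,
    # then the adjoint sum
    set.seed(nb)
    v <- rnorm(nb)
    d2 <- diff(v, differences = 2)
    adj <- numeric(nb)
    for (i in seq_along(d2)) {
      adj[i] <- adj[i] + d2[i]
      adj[i + 1] <- adj[i + 1] - 2 * d2[i]
      adj[i + 2] <- adj[i + 2] + d2[i]
    }
    expect_equal(drop(p$P %*% v), adj, tolerance = 1e-10)
  }
  expect_error(difference_penalty(2, 2), "greater than")
})

test_that("mixed-model transform splits dimensions and absorbs straight lines", {
  b33 <- bspline_basis(1:31, 31)
  tr33 <- mixed_model_transform(b33, difference_penalty(33, 2))
  expect_equal(ncol(tr33$Z), 31)
  b13 <- bspline_basis(1:11, 11)
  tr13 <- mixed_model_transform(b13, difference_penalty(13, 2))
  expect_equal(ncol(tr13$Z), 11)
  expect_error(mixed_model_transform(b33, difference_penalty(13, 2)),
               "columns")

  # noiseless straight line: all signal lands in the unpenalized part
  x <- 1:31
  y <- 2 + 0.3 * x
  W <- cbind(tr33$X, tr33$Z)
  pen <- c(rep(0, ncol(tr33$X)), 10 * tr33$lambda)
  coefs <- solve(crossprod(W) + diag(pen), crossprod(W, y))
  u <- coefs[-(1:ncol(tr33$X))]
  expect_lt(max(abs(u)), 1e-8)
  expect_equal(drop(W %*% coefs), y, tolerance = 1e-8)
})

test_that("transformed penalized regression equals the untransformed P-spline ridge", {
  set.seed(11)
  x <- sort(runif(40, 1, 15))
  y <- sin(x / 2) + rnorm(40, 0, 0.2)
  b <- bspline_basis(x, 9, domain = c(1, 15))
  p <- difference_penalty(b$n_basis, 2)
  lam <- 2.7
  theta <- solve(crossprod(b$B) + lam * p$P, crossprod(b$B, y))
  fit_ridge <- drop(b$B %*% theta)

  tr <- mixed_model_transform(b, p)
  W <- cbind(tr$X, tr$Z)
  pen <- c(rep(0, ncol(tr$X)), lam * tr$lambda)
  fit_tr <- drop(W %*% solve(crossprod(W) + diag(pen), crossprod(W, y)))
  expect_equal(fit_tr, fit_ridge, tolerance = 1e-8)
})

test_that("PS-ANOVA block dimensions: reference settings give 425 and bookkeeping closes", {
  rows <- rep(1:60, each = 20); cols <- rep(1:20, 60)
  d <- build_psanova(rows, cols, 31, 11)
  expect_equal(unname(d$q), c(31, 11, 31, 11, 341))
  expect_equal(sum(d$q), 425)
  # sum(q) + 3 fixed spatial columns + intercept = full tensor dimension
  expect_equal(sum(d$q) + 3 + 1, 33 * 13)
  expect_true(all(vapply(d$prec, function(p) all(p > 0), TRUE)))
  expect_equal(vapply(d$Z, ncol, 0L), d$q, ignore_attr = TRUE)

  # smallest legal design: 2 knots per dimension
  g <- expand.grid(r = 1:4, c = 1:4)
  d2 <- build_psanova(g$r, g$c, 2, 2)
  expect_equal(unname(d2$q), c(2, 2, 2, 2, 4))
})

test_that("PS-ANOVA plus intercept spans the full tensor-product basis", {
  g <- expand.grid(r = 1:6, c = 1:6)
  d <- build_psanova(g$r, g$c, 3, 3)
  br <- bspline_basis(g$r, 3, domain = c(1, 6))
  bc <- bspline_basis(g$c, 3, domain = c(1, 6))
  # row-wise tensor product basis evaluated at the plots
  TP <- br$B[, rep(seq_len(ncol(br$B)), each = ncol(bc$B))] *
    bc$B[, rep(seq_len(ncol(bc$B)), times = ncol(br$B))]
  PS <- cbind(1, d$X_s, do.call(cbind, d$Z))
  expect_equal(ncol(PS), ncol(TP))
  expect_equal(qr(TP)$rank, qr(PS)$rank)
  expect_equal(qr(cbind(TP, PS))$rank, qr(TP)$rank)  # same column space
})

test_that("off-grid or malformed coordinates are rejected", {
  expect_error(build_psanova(c(1, 2, 7), c(1, 1, 1), 3, 3,
                             n_rows = 6, n_cols = 3), "outside")
  expect_error(build_psanova(c(1.5, 2), c(1, 2), 3, 3), "integer")
  expect_error(build_psanova(1:4, 1:3, 3, 3), "same length")
  # non-rectangular (missing plots) is fine
  expect_silent(build_psanova(c(1, 2, 5), c(1, 3, 2), 3, 3,
                              n_rows = 5, n_cols = 3))
})

test_that("psanova_matrices agrees at build coordinates and rejects extrapolation", {
  g <- expand.grid(r = 1:8, c = 1:5)
  d <- build_psanova(g$r, g$c, 4, 3)
  m <- psanova_matrices(d, g$r, g$c)
  expect_equal(m$X_s, d$X_s)
  for (k in names(d$Z)) expect_equal(m$Z[[k]], d$Z[[k]])
  # fractional in-range coordinates are allowed (fine prediction grids)
  expect_silent(psanova_matrices(d, c(1.25, 7.75), c(2.5, 4.1)))
  expect_error(psanova_matrices(d, 8.5, 3), "outside")
})
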