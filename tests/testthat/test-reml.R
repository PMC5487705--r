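test_that("production deviance matches the dense textbook formula", {
  spec <- small_rcg_spec(seed = 5, nr = 4, nc = 5, n_geno = 6)  # n = 20
  for (s in 1:3) {
    set.seed(100 + s)
    vc <- c(geno = runif(1, 0.2, 2), row = runif(1, 0.2, 2),
            col = runif(1, 0.2, 2), sigma2_e = runif(1, 0.2, 2))
    expect_equal(reml_deviance(spec, vc), dense_reml_deviance(spec, vc),
                 tolerance = 1e-8)
  }
})

test_that("deviance is invariant to affine rescaling of fixed columns", {
  tr <- quick_trial(3, nr = 10, nc = 6, n_geno = 24, n_checks = 2)
  spec <- build_spats_model(tr)
  vc <- c(f_r = 0.1, f_c = 0.1, h_r_c = 0.1, r_h_c = 0.1, f_r_c = 0.1,
          row = 0.05, col = 0.05, geno = 0.2, sigma2_e = 0.2)
  d1 <- reml_deviance(spec, vc)
  spec2 <- spec
  sf <- spec$meta$spatial_fixed
  spec2$X[, sf] <- sweep(spec2$X[, sf], 2, c(3, 0.2, 7), `*`)
  expect_equal(reml_deviance(spec2, vc), d1, tolerance = 1e-8)
})

test_that("converged deviance is a local optimum under component perturbations", {
  spec <- small_rcg_spec(seed = 9, nr = 6, nc = 6, n_geno = 12)
  fit <- fit_reml(spec)
  expect_true(fit$converged)
  vc0 <- fit$vc
  set.seed(21)
  for (i in 1:10) {
    vc <- vc0 * runif(length(vc0), 0.8, 1.2)
    names(vc) <- names(vc0)
    expect_lte(fit$deviance, reml_deviance(spec, vc) + 1e-6)
  }
})

test_that("EDs equal the trace of the dense hat matrix per component", {
  spec <- small_rcg_spec(seed = 13, nr = 5, nc = 5, n_geno = 8)
  vc <- c(geno = 0.8, row = 0.4, col = 0.3, sigma2_e = 0.6)
  sol <- mme_solution(spec, vc)
  X <- spec$X
  Zs <- lapply(spec$random, `[[`, "Z")
  W <- cbind(X, do.call(cbind, Zs))
  lam <- vc[["sigma2_e"]] / vc[names(spec$random)]
  pen <- c(rep(0, ncol(X)),
           unlist(mapply(function(b, l) l * b$prec, spec$random,
                         lam[names(spec$random)], SIMPLIFY = FALSE)))
  Cinv <- solve(crossprod(W) + diag(pen))
  Hfull <- W %*% Cinv %*% t(W)
  off <- ncol(X)
  for (k in names(spec$random)) {
    idx <- off + seq_len(ncol(Zs[[k]]))
    Hk <- Zs[[k]] %*% Cinv[idx, , drop = FALSE] %*% t(W)
    expect_equal(sol$ed[[k]], sum(diag(Hk)), tolerance = 1e-8)
    off <- off + ncol(Zs[[k]])
  }
  # trace bookkeeping: fixed part + all EDs + residual df = n
  ed_resid <- length(spec$y) - ncol(X) - sum(sol$ed)
  expect_equal(ncol(X) + sum(sol$ed) + ed_resid, length(spec$y))
})

test_that("ED limits: lambda -> Inf gives 0, lambda -> 0 gives q", {
  spec <- small_rcg_spec(seed = 17, nr = 5, nc = 5, n_geno = 8)
  base <- c(geno = 1, row = 1, col = 1, sigma2_e = 1)
  tiny <- base; tiny[["row"]] <- 1e-10      # lambda_row -> Inf
  expect_lt(mme_solution(spec, tiny)$ed[["row"]], 1e-6)
  huge <- base; huge[["row"]] <- 1e10       # lambda_row -> 0
  # unpenalized limit: the block behaves like fixed effects, so its ED
  # tends to rank([X Z_row]) - rank(X) (one row level aliases the intercept)
  ub <- qr(cbind(spec$X, spec$random$row$Z))$rank - qr(spec$X)$rank
  expect_equal(mme_solution(spec, huge)$ed[["row"]], ub, tolerance = 1e-4)
})

test_that("fit reconstructs y exactly and respects ED bounds", {
  tr <- quick_trial(4, nr = 16, nc = 8, n_geno = 70, n_checks = 3)
  fit <- fit_reml(build_spats_model(tr), reml_control(tolerance = 1e-7))
  spec <- fit$spec
  yhat <- drop(spec$X %*% fit$beta)
  for (k in names(spec$random))
    yhat <- yhat + drop(spec$random[[k]]$Z %*% fit$blups[[k]])
  expect_equal(yhat + fit$residuals, spec$y, tolerance = 1e-8)
  expect_true(all(fit$ed > -1e-8))
  expect_true(all(fit$ed <= fit$q + 1e-8))
  # partial-to-total spatial additivity is exact
  ed <- effective_dimensions(fit)
  expect_equal(attr(ed, "ed_spatial"),
               sum(ed[c("f_r", "f_c", "h_r_c", "r_h_c", "f_r_c")]))
})

test_that("a perfect fixed-effect fit floors the variances and zeroes the BLUPs", {
  spec <- small_rcg_spec(seed = 23, nr = 5, nc = 5, n_geno = 8)
  beta <- 2.5
  spec$y <- rep(beta, length(spec$y)) + 0.3 * spec$X[, 1] * 0  # constant y
  spec$y <- spec$y + seq_along(spec$y) * 0                      # keep exact
  # add a tiny fixed structure so var(y) > 0 via a covariate
  spec$X <- cbind(spec$X, x2 = seq_along(spec$y))
  spec$y <- drop(spec$X %*% c(2.5, 0.01))
  fit <- suppressWarnings(fit_reml(spec))
  expect_lt(fit$vc[["sigma2_e"]] / var(spec$y), 1e-6)
  expect_lt(max(abs(unlist(fit$blups))), 1e-4)
})

test_that("aliased fixed columns are dropped with a report", {
  spec <- small_rcg_spec(seed = 29, nr = 4, nc = 4, n_geno = 4)
  X <- cbind(spec$X, dupe = spec$X[, 1])
  spec2 <- new_mm_spec(spec$y, X, spec$random)
  expect_equal(spec2$aliased, "dupe")
  expect_equal(ncol(spec2$X), ncol(spec$X))
})

test_that("heritability: ED and PEV forms agree; floored genetics gives 0", {
  tr <- quick_trial(6, nr = 14, nc = 8, n_geno = 50, n_checks = 2)
  fit <- fit_reml(build_spats_model(tr))
  h <- heritability(fit)
  expect_equal(h$H2_ED, h$H2_PEV, tolerance = 1e-6)
  expect_gte(h$H2_ED, 0); expect_lte(h$H2_ED, 1)
  expect_equal(h$n_g, length(unique(tr$genotype[!tr$check & !is.na(tr$y)])))

  # degenerate data with no variation at all: sigma2_g floors and H2 = 0
  # by convention
  p0 <- sim_params(n_rows = 10, n_cols = 6, n_geno = 24, n_checks = 2,
                   sigma2_g = 0, sigma2_r = 0, sigma2_c = 0, sigma2_e = 0,
                   block_shift = 0, surface = list(type = "none"),
                   missing_rate = 0, seed = 31)
  f0 <- suppressWarnings(fit_reml(build_nonspatial_model(simulate_trial(p0))))
  expect_warning(h0 <- heritability(f0), "floor")
  expect_equal(h0$H2_ED, 0)
})

test_that("balanced 2-rep no-trend trial approaches entry-mean heritability", {
  # every genotype replicated once per block, no spatial signal
  p <- sim_params(n_rows = 20, n_cols = 10, n_geno = 100, p_rep = 1,
                  n_checks = 0, sigma2_g = 0.2, sigma2_r = 0, sigma2_c = 0,
                  sigma2_e = 0.2, surface = list(type = "none"),
                  missing_rate = 0, seed = 37)
  fit <- fit_reml(build_nonspatial_model(simulate_trial(p)))
  h <- heritability(fit, compute_l = FALSE)
  s2g <- fit$vc[["geno"]]; s2e <- fit$vc[["sigma2_e"]]
  expect_equal(h$H2_ED, 2 * s2g / (2 * s2g + s2e), tolerance = 0.03)
})

test_that("predict_surface reproduces the per-plot trend and refuses extrapolation", {
  tr <- quick_trial(8, nr = 12, nc = 8, n_geno = 40, n_checks = 2,
                    missing_rate = 0)
  fit <- fit_reml(build_spats_model(tr))
  obs <- tr[!is.na(tr$y), ]
  pred <- predict_surface(fit, rows = sort(unique(obs$row)),
                          cols = sort(unique(obs$col)))
  key <- paste(obs$row, obs$col)
  m <- match(key, paste(pred$row, pred$col))
  expect_equal(pred$trend[m], fit$spatial_trend, tolerance = 1e-8)
  expect_error(predict_surface(fit, rows = 13, cols = 1), "extrapolation")
  # default grid: 4x plot density in each direction
  s <- predict_surface(fit)
  expect_equal(length(unique(s$row)), (12 - 1) * 4 + 1)
  expect_equal(length(unique(s$col)), (8 - 1) * 4 + 1)
})

test_that("fitted surface is insensitive to doubling the knot counts", {
  tr <- quick_trial(10, nr = 24, nc = 12, n_geno = 100, n_checks = 3,
                    amplitude = 1, missing_rate = 0)
  f1 <- fit_reml(build_spats_model(tr))            # 13 / 7 knots
  f2 <- fit_reml(build_spats_model(tr, 25, 12))    # roughly doubled
  rms <- sqrt(mean((f1$spatial_trend - f2$spatial_trend)^2))
  expect_lt(rms / diff(range(f1$spatial_trend)), 0.05)
})

test_that("variogram: constant residuals give 0, white noise is flat", {
  g <- expand.grid(r = 1:8, c = 1:6)
  v0 <- nugget_variogram(rep(2, nrow(g)), g$r, g$c)
  expect_true(all(v0$semivariance == 0))
  expect_false(any(v0$row_disp == 0 & v0$col_disp == 0))
  expect_equal(sum(v0$n_pairs), choose(nrow(g), 2))

  # iid noise of variance v: mean semivariance ~ v at every displacement
  set.seed(41)
  sv <- replicate(40, {
    e <- rnorm(nrow(g), 0, sqrt(0.5))
    v <- nugget_variogram(e, g$r, g$c)
    weighted.mean(v$semivariance, v$n_pairs)
  })
  expect_equal(mean(sv), 0.5, tolerance = 0.05)
  expect_error(nugget_variogram(1.5, 1, 1), "at least 2")
})

test_that("post-fit residual variogram shows no displacement trend", {
  slopes <- vapply(1:5, function(s) {
    tr <- quick_trial(50 + s, nr = 15, nc = 8, n_geno = 55, n_checks = 2,
                      amplitude = 1, missing_rate = 0)
    fit <- fit_reml(build_spats_model(tr))
    v <- nugget_variogram(fit)
    d <- sqrt(v$row_disp^2 + v$col_disp^2)
    unname(coef(lm(v$semivariance ~ d, weights = v$n_pairs))[2])
  }, 0)
  # mean slope across seeds not significantly positive
  expect_lt(mean(slopes), 2 * sd(slopes) / sqrt(length(slopes)) + 1e-3)
})

test_that("non-convergence is flagged, not thrown", {
  spec <- small_rcg_spec(seed = 43, nr = 5, nc = 5, n_geno = 8)
  expect_warning(fit <- fit_reml(spec, reml_control(max_iter = 2)),
                 "did not converge")
  expect_false(fit$converged)
  expect_true(is.finite(fit$deviance))
})
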