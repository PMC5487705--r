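#' Simulation settings for a partially replicated field trial
#'
#' Defaults emulate the layout of a large early-generation breeding trial:
#' a 55 x 28 grid (1540 plots), 1136 test genotypes of which 30% are
#' duplicated once in each of two resolvable blocks, ten replicated check
#' varieties filling the remaining plots, a smooth field trend with range
#' equal to the nugget standard deviation, random row/column effects, and
#' 10% of plots missing completely at random (real trials ranged from 3 to
#' 29% missing).  Phenotype scale is grain-yield-like (t/ha, trial mean ~4).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_geno number of test genotypes.
#' @param p_rep fraction of test genotypes duplicated (default 0.30).
#' @param n_checks number of check varieties; check plots fill whatever the
#'   test entries do not occupy, cycling over the checks.
#' @param mu trial mean.
#' @param block_shift additive offset of the second resolvable block.
#' @param sigma2_g,sigma2_r,sigma2_c,sigma2_e variance components
#'   (genotype, random row, random column, nugget), trait units squared.
#' @param surface field-trend settings: a list with `type` one of
#'   `"none"`, `"plane"` (uses `slopes`, two numbers per unit scaled
#'   coordinate), `"smooth"` (uses `amplitude` = max - min of the trend and
#'   `shape_seed`), `"ar1field"` (uses `sigma2_xi`, `rho_r`, `rho_c`).
#' @param missing_rate fraction of plots with missing phenotype, in
#'   [0, 0.29].
#' @param block_orientation `"rows"` (two row-wise halves, default) or
#'   `"cols"`.
#' @param seed integer RNG seed; all layout and phenotype randomness flows
#'   from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_rows = 55, n_cols = 28, n_geno = 1136,
                       p_rep = 0.30, n_checks = 10,
                       mu = 4.0, block_shift = 0.2,
                       sigma2_g = 0.2, sigma2_r = 0.05, sigma2_c = 0.05,
                       sigma2_e = 0.2,
                       surface = list(type = "smooth",
                                      amplitude = sqrt(sigma2_e),
                                      shape_seed = seed),
                       missing_rate = 0.10,
                       block_orientation = c("rows", "cols"),
                       seed = 1L) {
  block_orientation <- match.arg(block_orientation)
  stopifnot(n_rows >= 2, n_cols >= 2, n_geno >= 1,
            p_rep >= 0, p_rep <= 1, n_checks >= 0,
            sigma2_g >= 0, sigma2_r >= 0, sigma2_c >= 0, sigma2_e >= 0,
            missing_rate >= 0, missing_rate <= 0.29)
  if (!is.list(surface) || is.null(surface$type) ||
      !surface$type %in% c("none", "plane", "smooth", "ar1field"))
    stop("surface$type must be one of none, plane, smooth, ar1field")
  if (surface$type == "ar1field") {
    if (is.null(surface$rho_r) || is.null(surface$rho_c) ||
        abs(surface$rho_r) >= 1 || abs(surface$rho_c) >= 1)
      stop("ar1field needs rho_r, rho_c in (-1, 1)")
    if (is.null(surface$sigma2_xi) || surface$sigma2_xi < 0)
      stop("ar1field needs sigma2_xi >= 0")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_geno = as.integer(n_geno), p_rep = p_rep,
                 n_checks = as.integer(n_checks), mu = mu,
                 block_shift = block_shift,
                 sigma2_g = sigma2_g, sigma2_r = sigma2_r,
                 sigma2_c = sigma2_c, sigma2_e = sigma2_e,
                 surface = surface, missing_rate = missing_rate,
                 block_orientation = block_orientation,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a p-rep trial layout (no phenotypes)
#'
#' The grid is split into two contiguous halves forming the resolvable
#' blocks.  Each duplicated test genotype appears exactly once per block;
#' unreplicated genotypes and check plots are randomized within blocks
#' under the seed, and every plot is assigned.  Real p-rep designs place
#' replicates by an optimal-design search; this generator uses constrained
#' randomization instead, which none of the analysis code depends on.
#'
#' @param params a [sim_params()] object.
#' @return a [trial_data()] skeleton with `y = NA`.
#' @export
generate_prep_layout <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nr <- params$n_rows; nc <- params$n_cols
  n_plots <- nr * nc
  geno <- sprintf("G%04d", seq_len(params$n_geno))
  n_dup <- round(params$p_rep * params$n_geno)
  leftover <- n_plots - params$n_geno - n_dup
  if (leftover < 0)
    stop(sprintf("infeasible budget: %d plots needed (%d genotypes + %d duplicates) but only %d available",
                 params$n_geno + n_dup, params$n_geno, n_dup, n_plots))
  if (params$n_checks == 0 && leftover > 0)
    stop(sprintf("infeasible budget: %d plots left unassigned and no checks to fill them",
                 leftover))
  checks <- if (params$n_checks > 0)
    sprintf("CHK%02d", seq_len(params$n_checks)) else character(0)

  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  half <- if (params$block_orientation == "rows")
    grid$row <= nr %/% 2 else grid$col <= nc %/% 2
  cap1 <- sum(half); cap2 <- n_plots - cap1
  if (n_dup > min(cap1, cap2))
    stop("infeasible budget: more duplicated genotypes than plots per block")

  dup <- sample(geno, n_dup)
  singles <- sample(setdiff(geno, dup))
  check_plots <- if (leftover > 0) sample(rep(checks, length.out = leftover))
    else character(0)
  ck1 <- round(leftover * cap1 / n_plots)
  s1 <- cap1 - n_dup - ck1
  if (s1 < 0 || s1 > length(singles)) {
    s1 <- min(max(cap1 - n_dup - leftover, 0), length(singles))
    ck1 <- cap1 - n_dup - s1
  }
  if (ck1 < 0 || ck1 > leftover)
    stop("infeasible budget: cannot balance entries across the two blocks")

  entries1 <- c(dup, singles[seq_len(s1)],
                if (ck1 > 0) check_plots[seq_len(ck1)])
  entries2 <- c(dup, singles[setdiff(seq_along(singles), seq_len(s1))],
                if (leftover - ck1 > 0) check_plots[-seq_len(ck1)])
  stopifnot(length(entries1) == cap1, length(entries2) == cap2)

  assign <- character(n_plots)
  assign[which(half)] <- sample(entries1)
  assign[which(!half)] <- sample(entries2)
  df <- data.frame(row = grid$row, col = grid$col,
                   genotype = assign,
                   check = assign %in% checks,
                   block = ifelse(half, "B1", "B2"),
                   y = NA_real_)
  out <- trial_data(df, n_rows = nr, n_cols = nc, trait = "sim")
  attr(out, "sim_params") <- params
  attr(out, "dup_genotypes") <- sort(dup)
  out
}

#' Reproducible smooth field-trend surface
#'
#' A tilted plane plus 2-4 Gaussian bumps whose centers, widths and signs
#' derive from `shape_seed`, rescaled so that max - min equals `amplitude`
#' and centered at zero.  Infinitely differentiable in both coordinates.
#' The global RNG state is left untouched.
#'
#' @param shape_seed integer seed controlling the shape.
#' @param amplitude non-negative range of the surface.
#' @param n_rows,n_cols grid dimensions.
#' @return `n_rows` x `n_cols` matrix of trend values.
#' @export
smooth_surface <- function(shape_seed, amplitude, n_rows, n_cols) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(matrix(0, n_rows, n_cols))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(shape_seed))
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c_ <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  rt <- (r - (1 + n_rows) / 2) / (n_rows - 1)
  ct <- (c_ - (1 + n_cols) / 2) / (n_cols - 1)
  z <- stats::runif(1, -1, 1) * rt + stats::runif(1, -1, 1) * ct
  for (i in seq_len(sample(2:4, 1))) {
    cr <- stats::runif(1, 1, n_rows); cc <- stats::runif(1, 1, n_cols)
    wr <- stats::runif(1, 0.15, 0.4) * n_rows
    wc <- stats::runif(1, 0.15, 0.4) * n_cols
    a <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
    z <- z + a * exp(-((r - cr)^2 / (2 * wr^2) + (c_ - cc)^2 / (2 * wc^2)))
  }
  rng <- max(z) - min(z)
  if (rng == 0) return(matrix(0, n_rows, n_cols))
  (z - min(z)) / rng * amplitude - amplitude / 2
}

#' Zero-mean Gaussian field with separable AR1 x AR1 correlation
#'
#' Built through the Kronecker structure: with `U_r`, `U_c` the Cholesky
#' factors of the one-dimensional AR1 correlation matrices, the field is
#' `sqrt(sigma2) * t(U_r) %*% Z %*% U_c` for an iid standard normal matrix
#' `Z`.  Draws from the current RNG stream.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param sigma2 marginal variance.
#' @param rho_r,rho_c lag-1 autocorrelations in (-1, 1).
#' @return `n_rows` x `n_cols` matrix.
#' @export
ar1_field <- function(n_rows, n_cols, sigma2, rho_r, rho_c) {
  stopifnot(abs(rho_r) < 1, abs(rho_c) < 1, sigma2 >= 0)
  Ur <- chol(stats::toeplitz(rho_r^(0:(n_rows - 1))))
  Uc <- chol(stats::toeplitz(rho_c^(0:(n_cols - 1))))
  Z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  sqrt(sigma2) * t(Ur) %*% Z %*% Uc
}

#' Simulate phenotypes on a p-rep layout
#'
#' y = mu + block shift + genotype effect + surface(r, c) + row effect +
#' column effect + nugget.  Test-genotype effects are Normal(0, sigma2_g);
#' check varieties get fixed offsets equally spaced across +-1 genetic SD.
#' Missingness is completely at random at `missing_rate`.  The generating
#' truth (per-plot trend, per-genotype effects, row/column effects,
#' realized variances) is attached as attribute `"truth"`; fitting code
#' never reads it.
#'
#' @param layout a [generate_prep_layout()] result.
#' @param params the same [sim_params()] object.
#' @return a [trial_data()] object with phenotypes and a `"truth"`
#'   attribute.
#' @export
simulate_phenotypes <- function(layout, params) {
  stopifnot(inherits(layout, "trial_data"), inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  nr <- params$n_rows; nc <- params$n_cols
  geno <- sprintf("G%04d", seq_len(params$n_geno))
  checks <- if (params$n_checks > 0)
    sprintf("CHK%02d", seq_len(params$n_checks)) else character(0)
  g_eff <- stats::setNames(stats::rnorm(params$n_geno, 0,
                                        sqrt(params$sigma2_g)), geno)
  ck_eff <- if (length(checks))
    stats::setNames(seq(-1, 1, length.out = max(length(checks), 2))[
      seq_along(checks)] * sqrt(params$sigma2_g), checks)
    else numeric(0)
  all_eff <- c(g_eff, ck_eff)

  surf <- switch(params$surface$type,
    none = matrix(0, nr, nc),
    plane = {
      sl <- params$surface$slopes
      if (is.null(sl) || length(sl) != 2)
        stop("plane surface needs 'slopes' of length 2")
      r <- matrix(seq_len(nr), nr, nc)
      c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      sl[1] * (r - (1 + nr) / 2) / ((nr - 1) / 2) +
        sl[2] * (c_ - (1 + nc) / 2) / ((nc - 1) / 2)
    },
    smooth = smooth_surface(
      if (is.null(params$surface$shape_seed)) params$seed
      else params$surface$shape_seed,
      params$surface$amplitude, nr, nc),
    ar1field = ar1_field(nr, nc, params$surface$sigma2_xi,
                         params$surface$rho_r, params$surface$rho_c))

  row_eff <- stats::rnorm(nr, 0, sqrt(params$sigma2_r))
  col_eff <- stats::rnorm(nc, 0, sqrt(params$sigma2_c))
  blk_eff <- c(B1 = 0, B2 = params$block_shift)
  nugget <- stats::rnorm(nrow(layout), 0, sqrt(params$sigma2_e))

  trend <- surf[cbind(layout$row, layout$col)]
  y <- params$mu + blk_eff[layout$block] + all_eff[layout$genotype] +
    trend + row_eff[layout$row] + col_eff[layout$col] + nugget
  y <- unname(y)
  miss <- stats::runif(length(y)) < params$missing_rate
  y[miss] <- NA_real_

  df <- as.data.frame(layout)
  df$y <- y
  out <- trial_data(df, n_rows = nr, n_cols = nc, trait = "sim")
  attr(out, "sim_params") <- params
  attr(out, "dup_genotypes") <- attr(layout, "dup_genotypes")
  attr(out, "truth") <- list(
    geno_effects = g_eff, check_effects = ck_eff,
    surface = surf, trend_per_plot = trend,
    row_effects = row_eff, col_effects = col_eff,
    nugget = nugget, missing = miss,
    realized = c(var_g = stats::var(g_eff),
                 var_e = stats::var(nugget),
                 trend_range = max(surf) - min(surf)))
  out
}

#' Simulate a complete trial (layout + phenotypes)
#'
#' @param params a [sim_params()] object.
#' @return a [trial_data()] object with a `"truth"` attribute.
#' @export
simulate_trial <- function(params) {
  simulate_phenotypes(generate_prep_layout(params), params)
}
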