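#' Construct a mixed-model specification
#'
#' Low-level container consumed by [fit_reml()].  Most users should build it
#' with [build_spats_model()] or [build_nonspatial_model()].
#'
#' @param y numeric response vector (no missing values; drop them upstream).
#' @param X fixed-effect design matrix with column names.  Aliased columns
#'   are detected by pivoted QR and removed with a report.
#' @param random named list of random blocks; each element is a list with
#'   `Z` (design matrix) and optionally `prec` (diagonal precision vector,
#'   default all ones = identity).
#' @param meta list of bookkeeping (PS-ANOVA design, genotype labels,
#'   coordinates, ...), carried through to the fit.
#' @return object of class `mm_spec`.
#' @export
new_mm_spec <- function(y, X, random, meta = list()) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("'y' must not contain missing values; drop them first")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrx <- qr(X)
  aliased <- character(0)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }
  if (length(random) == 0 || is.null(names(random)) || any(names(random) == ""))
    stop("'random' must be a non-empty named list")
  if (anyDuplicated(names(random))) stop("random-block names must be unique")
  random <- lapply(random, function(b) {
    b$Z <- as.matrix(b$Z)
    if (nrow(b$Z) != length(y)) stop("a random-block Z has wrong row count")
    if (is.null(b$prec)) b$prec <- rep(1, ncol(b$Z))
    if (length(b$prec) != ncol(b$Z)) stop("precision length != ncol(Z)")
    if (any(b$prec <= 0)) stop("diagonal precisions must be strictly positive")
    b
  })
  structure(list(y = y, X = X, random = random, aliased = aliased,
                 meta = meta),
            class = "mm_spec")
}

#' Convergence settings for the REML fixed-point fit
#'
#' @param tolerance relative tolerance applied to all effective dimensions
#'   and to the REML deviance (default 1e-8).
#' @param max_iter maximum fixed-point iterations (default 200).
#' @param floor_factor variance components are floored at
#'   `floor_factor * var(y)`; a floored component is reported with ED 0 and
#'   excluded from the smoothing-parameter ratios.
#' @param trace if TRUE, print deviance and EDs each iteration.
#' @export
reml_control <- function(tolerance = 1e-8, max_iter = 200,
                         floor_factor = 1e-10, trace = FALSE) {
  stopifnot(tolerance > 0, max_iter >= 1, floor_factor > 0)
  list(tolerance = tolerance, max_iter = as.integer(max_iter),
       floor_factor = floor_factor, trace = isTRUE(trace))
}

# Precompute crossproducts and absorption layout.  The "geno" block (if
# present, with one nonzero per row so Z'Z is diagonal) is absorbed via its
# Schur complement: trials carry ~1000 genotypes, so this turns the dominant
# cost from O((p+q)^3) into O(m_o^2 n_g) per iteration.
prepare_mme <- function(spec) {
  y <- spec$y; X <- spec$X
  n <- length(y); p <- ncol(X)
  bn <- names(spec$random)
  absorb <- "geno" %in% bn &&
    all(rowSums(spec$random$geno$Z != 0) <= 1)
  gname <- if (absorb) "geno" else character(0)
  onames <- setdiff(bn, gname)
  Zo <- do.call(cbind, lapply(spec$random[onames], `[[`, "Z"))
  q_o <- vapply(spec$random[onames], function(b) ncol(b$Z), 0L)
  idx <- list(); off <- p
  for (k in onames) { idx[[k]] <- off + seq_len(q_o[[k]]); off <- off + q_o[[k]] }
  Wo <- if (length(onames)) cbind(X, Zo) else X
  m_o <- ncol(Wo)
  prec_o <- numeric(m_o)   # positions of random entries get prec, fixed get 0
  for (k in onames) prec_o[idx[[k]]] <- spec$random[[k]]$prec
  out <- list(n = n, p = p, m_o = m_o, onames = onames, gname = gname,
              idx = idx, Wo = Wo, A0 = crossprod(Wo),
              rhs_o = drop(crossprod(Wo, y)), yty = sum(y^2),
              prec_o = prec_o, y = y,
              logdetXtX = as.numeric(determinant(crossprod(X),
                                                 logarithm = TRUE)$modulus))
  if (absorb) {
    Zg <- spec$random$geno$Z
    out$Zg <- Zg
    out$B <- crossprod(Wo, Zg)
    out$d0 <- colSums(Zg^2)
    out$prec_g <- spec$random$geno$prec
    out$rhs_g <- drop(crossprod(Zg, y))
    out$n_g <- ncol(Zg)
  } else {
    out$n_g <- 0L
  }
  out
}

# Solve the mixed-model equations at given variance components and return
# coefficients, per-block EDs, diagnostics and the REML deviance.
solve_mme <- function(pre, sig2, sig2e, spec) {
  lam <- sig2e / sig2
  diag_add <- pre$prec_o * 0
  for (k in pre$onames) diag_add[pre$idx[[k]]] <-
      lam[[k]] * spec$random[[k]]$prec
  A <- pre$A0
  dg <- seq_len(pre$m_o)
  A[cbind(dg, dg)] <- diag(pre$A0) + diag_add

  has_g <- length(pre$gname) == 1L
  if (has_g) {
    D <- pre$d0 + lam[["geno"]] * pre$prec_g
    Bd <- sweep(pre$B, 2, D, "/")
    S <- A - tcrossprod(Bd, pre$B)
    S <- (S + t(S)) / 2
    rhs_s <- pre$rhs_o - drop(Bd %*% pre$rhs_g)
  } else {
    D <- numeric(0)
    S <- A
    rhs_s <- pre$rhs_o
  }
  cholS <- tryCatch(chol(S), error = function(e) {
    k <- suppressWarnings(as.integer(sub(".*order ([0-9]+).*", "\\1",
                                         conditionMessage(e))))
    blk <- "fixed part"
    if (!is.na(k)) for (nm in pre$onames)
      if (k %in% pre$idx[[nm]]) blk <- nm
    stop("mixed-model coefficient matrix numerically singular near block '",
         blk, "'", call. = FALSE)
  })
  Sinv <- chol2inv(cholS)
  coef_o <- drop(Sinv %*% rhs_s)
  diagSinv <- diag(Sinv)

  ed <- numeric(0); uPu <- numeric(0); blups <- list()
  for (k in pre$onames) {
    i <- pre$idx[[k]]
    pk <- spec$random[[k]]$prec
    ed[[k]] <- length(i) - lam[[k]] * sum(pk * diagSinv[i])
    blups[[k]] <- coef_o[i]
    uPu[[k]] <- sum(pk * coef_o[i]^2)
  }
  if (has_g) {
    u_g <- (pre$rhs_g - drop(crossprod(pre$B, coef_o))) / D
    M <- backsolve(cholS, Bd, transpose = TRUE)
    diagCgg <- 1 / D + colSums(M^2)
    ed[["geno"]] <- pre$n_g - lam[["geno"]] * sum(pre$prec_g * diagCgg)
    blups[["geno"]] <- u_g
    uPu[["geno"]] <- sum(pre$prec_g * u_g^2)
  } else {
    u_g <- numeric(0); diagCgg <- NULL; Bd <- NULL; M <- NULL
  }

  fitted <- drop(pre$Wo %*% coef_o)
  if (has_g) fitted <- fitted + drop(pre$Zg %*% u_g)
  resid <- pre$y - fitted

  q_all <- vapply(spec$random, function(b) ncol(b$Z), 0L)
  ypy <- (pre$yty - sum(coef_o * pre$rhs_o) - sum(u_g * pre$rhs_g)) / sig2e
  logdetC <- 2 * sum(log(diag(cholS))) + sum(log(D))
  logdetG <- 0
  for (k in names(spec$random))
    logdetG <- logdetG + ncol(spec$random[[k]]$Z) * log(sig2[[k]]) -
      sum(log(spec$random[[k]]$prec))
  # normalized by -log|X'X| so the deviance is invariant to affine
  # reparameterizations of the fixed columns (the textbook form shifts by
  # the constant 2 log|det T| under X -> X T)
  dev <- (pre$n - pre$p) * log(2 * pi) + pre$n * log(sig2e) + logdetG +
    logdetC - (pre$p + sum(q_all)) * log(sig2e) + ypy - pre$logdetXtX

  list(beta = stats::setNames(coef_o[seq_len(pre$p)], colnames(spec$X)),
       coef_o = coef_o, blups = blups, uPu = uPu, ed = ed,
       fitted = fitted, resid = resid, deviance = dev,
       diagCgg = diagCgg, cholS = cholS, Sinv = Sinv, Bd = Bd, D = D)
}

#' Fit the spatial mixed model by REML
#'
#' Estimates all variance components by effective-dimension fixed-point
#' updates (Schall/Harville style): at each iteration the mixed-model
#' equations are solved at the current components, each component is updated
#' as \eqn{\sigma^2_k = u_k' P_k u_k / ED_k} and the nugget as
#' \eqn{\sigma^2_e = e'e / (n - ED_\beta - \sum_k ED_k)}, until the maximum
#' relative change over all effective dimensions and the deviance change
#' fall below the tolerance.  Smoothing parameters are the implied ratios
#' \eqn{\lambda_k = \sigma^2_e / \sigma^2_k}.
#'
#' @param spec an `mm_spec` from [build_spats_model()],
#'   [build_nonspatial_model()] or [new_mm_spec()].
#' @param control a [reml_control()] list.
#' @return object of class `spats_fit`: variance components (`vc`),
#'   smoothing ratios (`lambda`), fixed-effect BLUEs (`beta`), per-block
#'   BLUPs, per-block effective dimensions (`ed`, plus `ed_beta`),
#'   residuals, fitted values, per-plot fitted spatial trend
#'   (`spatial_trend`, when the spec carries a PS-ANOVA design), genotype
#'   PEVs (`pev`), REML `deviance`, `iterations`, `converged` flag and an
#'   iteration `trace`.  Non-convergence is flagged, not an error.
#' @export
fit_reml <- function(spec, control = reml_control()) {
  stopifnot(inherits(spec, "mm_spec"))
  pre <- prepare_mme(spec)
  if (pre$n <= pre$p)
    stop("more fixed-effect columns than observations")
  vy <- stats::var(spec$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  floor_val <- control$floor_factor * vy
  K <- length(spec$random)
  sig2 <- stats::setNames(rep(vy / (K + 1), K), names(spec$random))
  sig2e <- vy / (K + 1)

  ed_old <- NULL; dev_old <- NULL
  converged <- FALSE; it <- 0
  trace_rows <- list()
  low_count <- stats::setNames(integer(K), names(sig2))
  dev_flat <- 0L
  frozen <- stats::setNames(rep(FALSE, K), names(sig2))
  sol <- NULL
  while (it < control$max_iter) {
    it <- it + 1
    sol <- solve_mme(pre, sig2, sig2e, spec)
    ed <- unlist(sol$ed)
    ed_sum <- sum(ed)
    # updates; components whose ED decays geometrically toward zero are
    # snapped to the floor after three consecutive shrinking iterations
    # below ED 1e-3 (they contribute nothing but stall convergence)
    for (k in names(sig2)) {
      if (frozen[[k]]) { sig2[[k]] <- floor_val; next }
      if (sol$ed[[k]] > 1e-8) {
        new_val <- max(sol$uPu[[k]] / sol$ed[[k]], floor_val)
      } else {
        new_val <- floor_val
      }
      if (sol$ed[[k]] < 1e-3 && new_val <= sig2[[k]]) {
        low_count[[k]] <- low_count[[k]] + 1L
        if (low_count[[k]] >= 3L) { frozen[[k]] <- TRUE; new_val <- floor_val }
      } else low_count[[k]] <- 0L
      sig2[[k]] <- new_val
    }
    denom <- pre$n - pre$p - ed_sum
    if (denom <= 0) denom <- max(pre$n - pre$p - ed_sum, 1e-8)
    sig2e <- max(sum(sol$resid^2) / denom, floor_val)
    trace_rows[[it]] <- c(iter = it, deviance = sol$deviance, ed)
    if (control$trace)
      message(sprintf("it %3d  dev %.6f  ED %s", it, sol$deviance,
                      paste(sprintf("%.2f", ed), collapse = " ")))
    if (!is.null(ed_old)) {
      ed_change <- max(abs(ed - ed_old) / pmax(abs(ed_old), 1))
      dev_change <- abs(sol$deviance - dev_old) / max(abs(dev_old), 1)
      dev_flat <- if (dev_change < control$tolerance) dev_flat + 1L else 0L
      # converged when all EDs and the deviance are stable, or when the
      # deviance has plateaued (a flat likelihood ridge can leave the ED of
      # a vanishing component drifting indefinitely without changing the fit)
      if ((ed_change < control$tolerance && dev_change < control$tolerance) ||
          dev_flat >= 5L) {
        converged <- TRUE
        break
      }
    }
    ed_old <- ed; dev_old <- sol$deviance
  }
  # final solve at the converged components so everything is consistent
  sol <- solve_mme(pre, sig2, sig2e, spec)

  floored <- vapply(names(sig2), function(k) sig2[[k]] <= floor_val * 1.0001,
                    TRUE)
  lambda <- ifelse(floored, NA_real_, sig2e / unlist(sig2))
  names(lambda) <- names(sig2)
  ed <- unlist(sol$ed)
  ed[floored & ed < 1e-6] <- pmax(ed[floored & ed < 1e-6], 0)

  fit <- structure(list(
    vc = c(unlist(sig2), sigma2_e = sig2e),
    lambda = lambda,
    floored = floored,
    beta = sol$beta,
    blups = sol$blups,
    ed = ed,
    ed_beta = pre$p,
    q = vapply(spec$random, function(b) ncol(b$Z), 0L),
    fitted = sol$fitted,
    residuals = sol$resid,
    deviance = sol$deviance,
    iterations = it,
    converged = converged,
    trace = do.call(rbind, trace_rows),
    n = pre$n,
    spec = spec),
    class = "spats_fit")

  if (!is.null(sol$diagCgg)) {
    fit$pev <- sig2e * sol$diagCgg
    names(fit$pev) <- colnames(spec$random$geno$Z)
    names(fit$blups$geno) <- colnames(spec$random$geno$Z)
    fit$n_g <- pre$n_g
    # pieces needed to reconstruct the full genotype block of the inverse
    # coefficient matrix (for the zero-eigenvalue count in heritability())
    fit$internal <- list(D = sol$D, Bd = sol$Bd, cholS = sol$cholS)
  }

  if (!is.null(spec$meta$design)) {
    sb <- intersect(names(spec$random), names(spec$meta$design$q))
    trend <- numeric(pre$n)
    sf <- spec$meta$spatial_fixed
    sf <- sf[sf %in% names(fit$beta)]
    if (length(sf))
      trend <- trend + drop(spec$X[, sf, drop = FALSE] %*% fit$beta[sf])
    for (k in sb)
      trend <- trend + drop(spec$random[[k]]$Z %*% fit$blups[[k]])
    fit$spatial_trend <- trend
  }
  if (!converged)
    warning("REML fixed-point iteration did not converge in ",
            control$max_iter, " iterations")
  fit
}

#' @export
print.spats_fit <- function(x, ...) {
  cat("Spatial P-spline mixed model fit (REML, ED fixed-point)\n")
  cat(sprintf("  n = %d observations, deviance = %.4f, %d iterations (%s)\n",
              x$n, x$deviance, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  variance components:\n")
  print(signif(x$vc, 4))
  cat("  effective dimensions:\n")
  print(round(x$ed, 2))
  invisible(x)
}

#' Per-component effective dimensions of a fit
#'
#' ED_k = q_k - lambda_k trace(P_k C^kk), the trace of each component's hat
#' matrix; the spatial total is the sum over the five surface components.
#'
#' @param fit a `spats_fit`.
#' @return named numeric vector of per-block EDs with attributes
#'   `ed_beta` (fixed-part dimension) and `ed_spatial` (total over the five
#'   smooth-surface blocks, `NA` for non-spatial fits).
#' @export
effective_dimensions <- function(fit) {
  stopifnot(inherits(fit, "spats_fit"))
  ed <- fit$ed
  sp <- intersect(names(ed), c("f_r", "f_c", "h_r_c", "r_h_c", "f_r_c"))
  attr(ed, "ed_beta") <- fit$ed_beta
  attr(ed, "ed_spatial") <- if (length(sp)) sum(ed[sp]) else NA_real_
  ed
}

#' Total and percentage contributions of spatial ED components
#'
#' Utility shared by the report writer: given the five partial effective
#' dimensions of the smooth surface, returns their total and each
#' component's percentage share (rounded to integers, matching the printed
#' convention of trial reports).
#'
#' @param ed numeric vector of partial spatial EDs.
#' @return list with `total` (sum, rounded to 1 decimal) and `percent`
#'   (integer shares of the unrounded total).
#' @export
ed_contributions <- function(ed) {
  ed <- as.numeric(ed)
  if (any(ed < 0)) stop("effective dimensions must be non-negative")
  tot <- sum(ed)
  pct <- if (tot > 0) round(100 * ed / tot) else rep(0, length(ed))
  list(total = round(tot, 1), percent = pct)
}

#' Generalized heritability from a converged fit
#'
#' Two equivalent forms for independent genotype effects: the
#' effective-dimension form \eqn{H^2 = ED_g / (n_g - l)} and the
#' prediction-error-variance form \eqn{H^2 = 1 - \overline{PEV}/\sigma^2_g}.
#' The headline ED form uses l = 0 (zero eigenvalues of the genotype hat
#' matrix ignored), which makes the two forms agree exactly; the value with
#' the computed l is also reported when `compute_l = TRUE`.
#'
#' @param fit a `spats_fit` whose spec contains a `geno` random block.
#' @param mode `"both"` (default), `"ED"` or `"PEV"`.
#' @param compute_l count zero eigenvalues of the genotype hat matrix
#'   (eigendecomposition of an n_g x n_g matrix; set FALSE to skip).
#' @return object of class `heritability_result`: `H2_ED` (l = 0),
#'   `H2_PEV`, `H2_ED_l` (computed l, or NA), `n_g`, `l`, `ed_g`,
#'   `mean_pev`.
#' @export
heritability <- function(fit, mode = c("both", "ED", "PEV"),
                         compute_l = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "spats_fit"))
  if (!("geno" %in% names(fit$blups)))
    stop("fit has no 'geno' random block")
  n_g <- fit$n_g
  sig2g <- fit$vc[["geno"]]
  ed_g <- fit$ed[["geno"]]
  if (isTRUE(fit$floored[["geno"]])) {
    warning("genotypic variance at floor; heritability set to 0")
    return(structure(list(H2_ED = 0, H2_PEV = 0, H2_ED_l = 0, n_g = n_g,
                          l = NA_integer_, ed_g = 0, mean_pev = NA_real_),
                     class = "heritability_result"))
  }
  mean_pev <- mean(fit$pev)
  H2_ED <- min(max(ed_g / n_g, 0), 1)
  H2_PEV <- min(max(1 - mean_pev / sig2g, 0), 1)
  l <- NA_integer_; H2_ED_l <- NA_real_
  if (compute_l && !is.null(fit$internal)) {
    Cgg <- genotype_inverse_block(fit)
    Hg <- diag(n_g) - (fit$vc[["sigma2_e"]] / sig2g) * Cgg
    ev <- eigen((Hg + t(Hg)) / 2, symmetric = TRUE, only.values = TRUE)$values
    l <- sum(abs(ev) < 1e-10 * max(abs(ev), 1))
    H2_ED_l <- min(max(ed_g / (n_g - l), 0), 1)
  }
  out <- structure(list(H2_ED = H2_ED, H2_PEV = H2_PEV, H2_ED_l = H2_ED_l,
                        n_g = n_g, l = l, ed_g = ed_g, mean_pev = mean_pev),
                   class = "heritability_result")
  if (mode == "ED") out$H2_PEV <- NULL
  if (mode == "PEV") out$H2_ED <- NULL
  out
}

# Full genotype block of the inverse coefficient matrix:
# C^{gg} = D^{-1} + (U^{-T} Bd)' (U^{-T} Bd)  with S = U'U.
genotype_inverse_block <- function(fit) {
  int <- fit$internal
  M <- backsolve(int$cholS, int$Bd, transpose = TRUE)
  Cgg <- crossprod(M)
  diag(Cgg) <- diag(Cgg) + 1 / int$D
  Cgg
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("Generalized heritability\n")
  if (!is.null(x$H2_ED))
    cat(sprintf("  H2 (ED form, l = 0):   %.4f\n", x$H2_ED))
  if (!is.null(x$H2_PEV))
    cat(sprintf("  H2 (PEV / Cullis form): %.4f\n", x$H2_PEV))
  if (!is.na(x$H2_ED_l))
    cat(sprintf("  H2 (ED form, l = %d):   %.4f\n", x$l, x$H2_ED_l))
  cat(sprintf("  n_g = %d genotypes, ED_g = %.2f\n", x$n_g, x$ed_g))
  invisible(x)
}

#' Evaluate the fitted spatial trend on a grid
#'
#' Evaluates the fitted smooth surface (fixed linear spatial columns plus
#' the five penalized blocks) at arbitrary in-range coordinates.  The
#' default grid is 4x the plot density in each direction; at the observed
#' plot coordinates it reproduces the per-plot fitted trend.
#'
#' @param fit a `spats_fit` whose spec carries a PS-ANOVA design.
#' @param rows,cols optional coordinate vectors defining the grid (crossed);
#'   must lie within the observed coordinate range.
#' @param grid_mult grid density multiplier when `rows`/`cols` are not
#'   given.
#' @return data.frame with columns `row`, `col`, `trend`.
#' @export
predict_surface <- function(fit, rows = NULL, cols = NULL, grid_mult = 4) {
  stopifnot(inherits(fit, "spats_fit"))
  design <- fit$spec$meta$design
  if (is.null(design)) stop("fit has no spatial design to predict from")
  if (is.null(rows)) rows <- seq(1, design$n_rows, by = 1 / grid_mult)
  if (is.null(cols)) cols <- seq(1, design$n_cols, by = 1 / grid_mult)
  if (any(rows < 1 | rows > design$n_rows) ||
      any(cols < 1 | cols > design$n_cols))
    stop("extrapolation outside the observed coordinate range")
  g <- expand.grid(row = rows, col = cols)
  m <- psanova_matrices(design, g$row, g$col)
  sf <- fit$spec$meta$spatial_fixed
  sf <- sf[sf %in% names(fit$beta)]
  trend <- numeric(nrow(g))
  if (length(sf)) {
    sx <- m$X_s[, match(sf, fit$spec$meta$spatial_fixed), drop = FALSE]
    trend <- trend + drop(sx %*% fit$beta[sf])
  }
  for (k in names(m$Z))
    if (k %in% names(fit$blups))
      trend <- trend + drop(m$Z[[k]] %*% fit$blups[[k]])
  data.frame(row = g$row, col = g$col, trend = trend)
}

#' Variogram of the spatially independent residuals
#'
#' For every absolute displacement pair (|dr|, |dc|) other than (0, 0),
#' the mean semivariance 0.5 (e_i - e_j)^2 over all plot pairs at that
#' displacement, with pair counts.  Residuals from a well-fitting spatial
#' model should show a flat variogram (pure nugget).
#'
#' @param fit a `spats_fit` (with plot coordinates in its spec meta), or a
#'   numeric residual vector if `rows`/`cols` are supplied.
#' @param rows,cols plot coordinates, required when `fit` is a plain vector.
#' @return data.frame with `row_disp`, `col_disp`, `semivariance`,
#'   `n_pairs`, sorted by displacement.
#' @export
nugget_variogram <- function(fit, rows = NULL, cols = NULL) {
  if (inherits(fit, "spats_fit")) {
    e <- fit$residuals
    rows <- fit$spec$meta$rows
    cols <- fit$spec$meta$cols
    if (is.null(rows) || is.null(cols))
      stop("fit does not carry plot coordinates")
  } else {
    e <- as.numeric(fit)
    if (is.null(rows) || is.null(cols))
      stop("supply 'rows' and 'cols' with a residual vector")
  }
  n <- length(e)
  if (n < 2) stop("need at least 2 observed plots")
  if (length(rows) != n || length(cols) != n)
    stop("coordinate length mismatch")
  ut <- upper.tri(matrix(0, n, n))
  dr <- abs(outer(rows, rows, "-"))[ut]
  dc <- abs(outer(cols, cols, "-"))[ut]
  sv <- 0.5 * (outer(e, e, "-")^2)[ut]
  key <- paste(dr, dc, sep = ":")
  agg_sv <- rowsum(sv, key)
  agg_n <- rowsum(rep(1, length(sv)), key)
  parts <- do.call(rbind, strsplit(rownames(agg_sv), ":", fixed = TRUE))
  out <- data.frame(row_disp = as.numeric(parts[, 1]),
                    col_disp = as.numeric(parts[, 2]),
                    semivariance = agg_sv[, 1] / agg_n[, 1],
                    n_pairs = agg_n[, 1])
  out <- out[!(out$row_disp == 0 & out$col_disp == 0), ]
  out <- out[order(out$row_disp, out$col_disp), ]
  rownames(out) <- NULL
  out
}

#' Mixed-model solution at fixed variance components
#'
#' Solves the mixed-model equations once at the supplied components and
#' returns coefficients, per-block effective dimensions, fitted values,
#' residuals and the REML deviance — no iteration.  Useful for likelihood
#' probes and for studying the smoothing limits (ED -> 0 as lambda -> Inf,
#' ED -> q as lambda -> 0).
#'
#' @param spec an `mm_spec`.
#' @param vc named numeric vector: one `sigma2` per random block plus
#'   `sigma2_e`, all positive.
#' @return list with `beta`, `blups`, `ed`, `fitted`, `residuals`,
#'   `deviance`.
#' @export
mme_solution <- function(spec, vc) {
  stopifnot(inherits(spec, "mm_spec"))
  vc <- unlist(vc)
  need <- c(names(spec$random), "sigma2_e")
  if (!all(need %in% names(vc)))
    stop("vc must contain: ", paste(need, collapse = ", "))
  if (any(vc[need] <= 0)) stop("variance components must be positive")
  pre <- prepare_mme(spec)
  sol <- solve_mme(pre, vc[names(spec$random)], vc[["sigma2_e"]], spec)
  list(beta = sol$beta, blups = sol$blups, ed = unlist(sol$ed),
       fitted = sol$fitted, residuals = sol$resid, deviance = sol$deviance)
}

#' REML deviance at supplied variance components
#'
#' Minus twice the restricted log-likelihood of the model at the given
#' components, computed through the mixed-model-equation determinant
#' identities (profiled form).  Used for convergence monitoring and as the
#' production counterpart of the dense textbook formula.
#'
#' @param spec an `mm_spec`.
#' @param vc named numeric vector: one `sigma2` per random block (matching
#'   the block names) plus `sigma2_e`.  All must be strictly positive.
#' @return the deviance (-2 restricted log-likelihood), a single number.
#' @export
reml_deviance <- function(spec, vc) {
  stopifnot(inherits(spec, "mm_spec"))
  vc <- unlist(vc)
  need <- c(names(spec$random), "sigma2_e")
  if (!all(need %in% names(vc)))
    stop("vc must contain: ", paste(need, collapse = ", "))
  if (any(vc[need] <= 0)) stop("variance components must be positive")
  pre <- prepare_mme(spec)
  solve_mme(pre, vc[names(spec$random)], vc[["sigma2_e"]], spec)$deviance
}
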