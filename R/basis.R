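#' B-spline basis on equally spaced knots
#'
#' Builds a univariate B-spline basis over `domain` with `n_knots` equally
#' spaced knots (endpoints included, giving `n_knots - 1` segments) and the
#' standard equidistant boundary extension of `degree` extra knots on each
#' side.  The basis has `n_knots - 1 + degree` functions, every evaluation
#' row is non-negative and sums to one (partition of unity).
#'
#' @param x numeric vector of covariate values, all inside `domain`.
#' @param n_knots integer >= 2, number of equally spaced interior+boundary
#'   knots spanning the domain.
#' @param degree spline degree (default 3, cubic).
#' @param domain numeric length-2 vector, covariate range; defaults to
#'   `range(x)`.
#' @return An object of class `bspline_basis`: a list with the evaluation
#'   matrix `B` (`length(x)` x `n_basis`), the extended knot vector, and the
#'   settings.
#' @examples
#' b <- bspline_basis(1:31, n_knots = 31)
#' dim(b$B)           # 31 x 33
#' range(rowSums(b$B))  # 1 1
#' @export
bspline_basis <- function(x, n_knots, degree = 3, domain = range(x)) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (!(length(n_knots) == 1 && n_knots >= 2 && n_knots == round(n_knots)))
    stop("'n_knots' must be a single integer >= 2")
  if (!(length(degree) == 1 && degree >= 1 && degree == round(degree)))
    stop("'degree' must be a single integer >= 1")
  domain <- as.numeric(domain)
  if (length(domain) != 2 || !(domain[2] > domain[1]))
    stop("'domain' must be two increasing numbers")
  knots <- extended_knots(domain[1], domain[2], n_knots, degree)
  obj <- structure(
    list(domain = domain, n_knots = as.integer(n_knots),
         degree = as.integer(degree),
         n_basis = as.integer(n_knots - 1 + degree),
         knots = knots),
    class = "bspline_basis")
  obj$B <- evaluate_basis(obj, x)
  obj
}

extended_knots <- function(lo, hi, n_knots, degree) {
  h <- (hi - lo) / (n_knots - 1)
  lo + h * seq(-degree, n_knots - 1 + degree)
}

#' Evaluate a B-spline basis at new covariate values
#'
#' @param basis a [bspline_basis()] object.
#' @param x numeric vector inside the basis domain.
#' @return evaluation matrix, `length(x)` x `n_basis`.
#' @export
evaluate_basis <- function(basis, x) {
  stopifnot(inherits(basis, "bspline_basis"))
  eps <- 1e-8 * diff(basis$domain)
  if (any(x < basis$domain[1] - eps | x > basis$domain[2] + eps))
    stop(sprintf("covariate values outside the basis domain [%g, %g]",
                 basis$domain[1], basis$domain[2]))
  x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  B <- splines::splineDesign(basis$knots, x, ord = basis$degree + 1,
                             outer.ok = FALSE)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

#' Difference penalty matrix and its eigendecomposition
#'
#' Returns the order-`order` difference penalty \eqn{D'D} for a coefficient
#' vector of length `n_basis`, together with its eigenvalues (sorted
#' ascending) and eigenvectors.  For order 2 the null space has dimension 2
#' and is spanned by the constant and linear sequences; the null-space
#' columns carry the unpenalized (fixed) part under the mixed-model
#' reparameterization.
#'
#' @param n_basis number of basis coefficients, must exceed `order`.
#' @param order difference order (default 2).
#' @return An object of class `difference_penalty`: list with `P` (the
#'   penalty matrix), `D` (the difference operator), `values` and `vectors`
#'   (eigendecomposition, ascending), `null_dim`.
#' @export
difference_penalty <- function(n_basis, order = 2) {
  if (!(length(n_basis) == 1 && n_basis == round(n_basis)))
    stop("'n_basis' must be a single integer")
  if (!(length(order) == 1 && order >= 1 && order == round(order)))
    stop("'order' must be a single integer >= 1")
  if (n_basis <= order)
    stop("'n_basis' must be greater than the penalty order")
  D <- diff(diag(n_basis), differences = order)
  P <- crossprod(D)
  e <- eigen(P, symmetric = TRUE)
  ord <- order(e$values)            # ascending
  values <- pmax(e$values[ord], 0)
  vectors <- e$vectors[, ord, drop = FALSE]
  cutoff <- 1e-10 * max(values)
  structure(
    list(n_basis = as.integer(n_basis), order = as.integer(order),
         D = D, P = P, values = values, vectors = vectors,
         null_dim = sum(values < cutoff), cutoff = cutoff),
    class = "difference_penalty")
}

#' Mixed-model reparameterization of a penalized B-spline basis
#'
#' Splits a P-spline into an unpenalized (fixed) polynomial part and a
#' penalized (random) part via the eigendecomposition of the difference
#' penalty.  The random columns are `Z = B U+` where `U+` holds the
#' eigenvectors with nonzero eigenvalue; the implied precision on the
#' transformed coefficients is the diagonal of positive eigenvalues, kept
#' as-is (not rescaled to identity).
#'
#' @param basis a [bspline_basis()] object (or a plain evaluation matrix).
#' @param penalty a [difference_penalty()] built for the same `n_basis`.
#' @return list with `X` (null-space columns, including the constant),
#'   `Z` (penalized columns, `n_basis - order` of them), `lambda` (positive
#'   eigenvalues, the diagonal precision), `U_null`, `U_plus`.
#' @export
mixed_model_transform <- function(basis, penalty) {
  B <- if (inherits(basis, "bspline_basis")) basis$B else as.matrix(basis)
  stopifnot(inherits(penalty, "difference_penalty"))
  if (ncol(B) != penalty$n_basis)
    stop("basis has ", ncol(B), " columns but penalty was built for ",
         penalty$n_basis)
  pos <- penalty$values >= penalty$cutoff
  U_plus <- penalty$vectors[, pos, drop = FALSE]
  U_null <- penalty$vectors[, !pos, drop = FALSE]
  list(X = B %*% U_null,
       Z = B %*% U_plus,
       lambda = penalty$values[pos],
       U_null = U_null, U_plus = U_plus)
}

#' Assemble the PS-ANOVA spatial design for a field trial grid
#'
#' Decomposes the 2D P-spline surface over plot coordinates into three fixed
#' linear columns (centered/scaled row, column and their product; the
#' intercept lives in the general fixed part) and five random blocks: the
#' two main smooth trends `f(r)`, `f(c)`, the two linear-by-smooth
#' interactions `h(r)c`, `r h(c)`, and the smooth-by-smooth interaction
#' `f(r,c)`, each with a diagonal precision and its own smoothing parameter
#' when fitted.
#'
#' Coordinates are 1-based integers on an `n_rows` x `n_cols` grid;
#' non-rectangular subsets (missing plots) are allowed, but all coordinates
#' must lie on the grid.  Covariates entering the fixed columns are centered
#' at the grid midpoint and scaled to unit half-range.
#'
#' @param rows,cols integer plot coordinates (same length).
#' @param n_knots_r,n_knots_c number of equally spaced knots (endpoints
#'   included) in the row and column directions.
#' @param degree spline degree (default 3).
#' @param order penalty order (default 2; the only order exercised against
#'   reference settings).
#' @param n_rows,n_cols grid dimensions; default the max coordinate.
#' @return An object of class `psanova_design` with elements `X_s`
#'   (n x 3), `Z` (named list of 5 matrices), `prec` (list of 5 diagonal
#'   precision vectors), `q` (block dimensions), plus the univariate bases
#'   and transforms needed to evaluate the surface at new coordinates.
#' @examples
#' d <- build_psanova(rep(1:6, each = 6), rep(1:6, 6), 4, 4)
#' sum(d$q)
#' @export
build_psanova <- function(rows, cols, n_knots_r, n_knots_c,
                          degree = 3, order = 2,
                          n_rows = max(rows), n_cols = max(cols)) {
  if (length(rows) != length(cols))
    stop("'rows' and 'cols' must have the same length")
  check_grid_coords(rows, n_rows, "row")
  check_grid_coords(cols, n_cols, "col")
  if (n_rows < 2 || n_cols < 2) stop("grid must be at least 2 x 2")

  basis_r <- bspline_basis(rows, n_knots_r, degree, domain = c(1, n_rows))
  basis_c <- bspline_basis(cols, n_knots_c, degree, domain = c(1, n_cols))
  pen_r <- difference_penalty(basis_r$n_basis, order)
  pen_c <- difference_penalty(basis_c$n_basis, order)
  tr_r <- mixed_model_transform(basis_r, pen_r)
  tr_c <- mixed_model_transform(basis_c, pen_c)

  design <- structure(
    list(basis_r = basis_r, basis_c = basis_c,
         pen_r = pen_r, pen_c = pen_c,
         U_plus_r = tr_r$U_plus, U_plus_c = tr_c$U_plus,
         lambda_r = tr_r$lambda, lambda_c = tr_c$lambda,
         degree = degree, order = order,
         n_rows = n_rows, n_cols = n_cols,
         r_mid = (1 + n_rows) / 2, r_half = (n_rows - 1) / 2,
         c_mid = (1 + n_cols) / 2, c_half = (n_cols - 1) / 2),
    class = "psanova_design")

  qr_ <- length(tr_r$lambda)
  qc_ <- length(tr_c$lambda)
  design$q <- c(f_r = qr_, f_c = qc_, h_r_c = qr_, r_h_c = qc_,
                f_r_c = qr_ * qc_)
  # Kronecker-sum precision for the smooth-by-smooth block, ordered to match
  # the row-wise Khatri-Rao product Z_r[i,] %x% Z_c[i,]
  design$prec <- list(
    f_r = tr_r$lambda, f_c = tr_c$lambda,
    h_r_c = tr_r$lambda, r_h_c = tr_c$lambda,
    f_r_c = rep(tr_r$lambda, each = qc_) + rep(tr_c$lambda, times = qr_))

  m <- psanova_matrices(design, rows, cols)
  design$X_s <- m$X_s
  design$Z <- m$Z
  design
}

check_grid_coords <- function(v, n, what) {
  if (any(v != round(v)))
    stop(sprintf("%s coordinates must be integers", what))
  if (any(v < 1 | v > n))
    stop(sprintf("%s coordinates outside the 1..%d grid", what, n))
  invisible(TRUE)
}

#' Evaluate PS-ANOVA design matrices at (possibly new) coordinates
#'
#' Rebuilds the fixed spatial columns and the five random blocks at
#' arbitrary in-range coordinates, e.g. a prediction grid finer than the
#' plot grid.  Extrapolation outside the original grid range is an error.
#'
#' @param design a [build_psanova()] object.
#' @param rows,cols numeric coordinates inside `[1, n_rows]` / `[1, n_cols]`.
#' @return list with `X_s` and the named `Z` list.
#' @export
psanova_matrices <- function(design, rows, cols) {
  stopifnot(inherits(design, "psanova_design"))
  if (length(rows) != length(cols))
    stop("'rows' and 'cols' must have the same length")
  if (any(rows < 1 | rows > design$n_rows) ||
      any(cols < 1 | cols > design$n_cols))
    stop("requested coordinates outside the observed grid range")
  rt <- (rows - design$r_mid) / design$r_half
  ct <- (cols - design$c_mid) / design$c_half
  Br <- evaluate_basis(design$basis_r, rows)
  Bc <- evaluate_basis(design$basis_c, cols)
  Zr <- Br %*% design$U_plus_r
  Zc <- Bc %*% design$U_plus_c
  qr_ <- ncol(Zr); qc_ <- ncol(Zc)
  # row-wise Khatri-Rao: Z5[i, ] = Zr[i, ] %x% Zc[i, ]
  Z5 <- Zr[, rep(seq_len(qr_), each = qc_), drop = FALSE] *
    Zc[, rep(seq_len(qc_), times = qr_), drop = FALSE]
  X_s <- cbind(r = rt, c = ct, rc = rt * ct)
  list(X_s = X_s,
       Z = list(f_r = Zr, f_c = Zc,
                h_r_c = Zr * ct, r_h_c = rt * Zc,
                f_r_c = Z5))
}

#' @export
print.psanova_design <- function(x, ...) {
  cat("PS-ANOVA spatial design\n")
  cat(sprintf("  grid: %d rows x %d cols; knots: %d (rows), %d (cols); degree %d, order-%d penalty\n",
              x$n_rows, x$n_cols, x$basis_r$n_knots, x$basis_c$n_knots,
              x$degree, x$order))
  cat("  random block dimensions:\n")
  print(x$q)
  cat(sprintf("  total random spatial parameters: %d\n", sum(x$q)))
  invisible(x)
}
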