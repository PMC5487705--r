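#' Plot-level trial data container
#'
#' Validates and wraps a per-plot table for a rectangular field trial:
#' integer row/column coordinates, genotype identifier, check flag,
#' resolvable-block identifier and one (possibly missing) phenotype value
#' per plot.
#'
#' @param df data.frame with columns `row`, `col`, `genotype`, `check`
#'   (logical or 0/1), `block`, `y`.
#' @param n_rows,n_cols grid dimensions (default: max coordinate present).
#' @param trait trait name (metadata only).
#' @param units trait units (metadata only).
#' @return object of class `trial_data` (a validated data.frame with
#'   attributes `n_rows`, `n_cols`, `trait`, `units`).
#' @export
trial_data <- function(df, n_rows = max(df$row), n_cols = max(df$col),
                       trait = "y", units = "") {
  need <- c("row", "col", "genotype", "check", "block", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (any(df$row != round(df$row)) || any(df$col != round(df$col)))
    stop("row/col coordinates must be integers")
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  if (any(df$row < 1 | df$row > n_rows) || any(df$col < 1 | df$col > n_cols))
    stop("coordinates outside the 1..n_rows x 1..n_cols grid")
  dup <- duplicated(df[c("row", "col")])
  if (any(dup))
    stop("duplicate plot coordinates, first at (",
         df$row[dup][1], ", ", df$col[dup][1], ")")
  df$genotype <- as.character(df$genotype)
  df$block <- as.character(df$block)
  df$check <- as.logical(df$check)
  if (anyNA(df$check)) stop("'check' must be logical or 0/1")
  obs <- !is.na(df$y)
  if (any(obs & (is.na(df$genotype) | df$genotype == "")))
    stop("every non-missing plot needs a genotype label")
  if (any(obs & (is.na(df$block) | df$block == "")))
    stop("every non-missing plot needs a block label")
  structure(df, class = c("trial_data", "data.frame"),
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            trait = trait, units = units)
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Field trial: %d x %d grid, %d plots (%d observed), %d genotypes (%d checks), %d block(s)\n",
              attr(x, "n_rows"), attr(x, "n_cols"), nrow(x),
              sum(!is.na(x$y)), length(unique(x$genotype)),
              length(unique(x$genotype[x$check])),
              length(unique(x$block))))
  NextMethod()
}

#' Default knot rule: about one knot per two plot positions
#'
#' `floor(n/2) + 1` equally spaced knots (endpoints included), capped at
#' `n`.  E.g. 77 rows -> 39 knots, 20 columns -> 11 knots.
#'
#' @param n number of rows or columns.
#' @export
default_knots <- function(n) {
  as.integer(min(floor(n / 2) + 1, n))
}

# Shared fixed/random assembly for both model builders.  Missing-phenotype
# plots are dropped from the likelihood; their coordinates remain available
# through the trial object for surface prediction.
model_frame <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  obs <- trial[!is.na(trial$y), , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed phenotypes")
  tests <- sort(unique(obs$genotype[!obs$check]))
  if (length(tests) == 0)
    stop("all genotypes are checks: no random genetic term can be fitted")
  checks <- sort(unique(obs$genotype[obs$check]))
  X <- cbind("(Intercept)" = rep(1, nrow(obs)))
  for (ck in checks)
    X <- cbind(X, as.numeric(obs$genotype == ck))
  if (length(checks))
    colnames(X)[1 + seq_along(checks)] <- paste0("check:", checks)
  blocks <- sort(unique(obs$block))
  if (length(blocks) >= 2) {
    for (b in blocks[-1]) X <- cbind(X, as.numeric(obs$block == b))
    colnames(X)[(ncol(X) - length(blocks) + 2):ncol(X)] <-
      paste0("block:", blocks[-1])
  } else {
    warning("single block: block effect dropped from the fixed part")
  }
  Zg <- outer(obs$genotype, tests, `==`) * 1
  colnames(Zg) <- tests
  list(obs = obs, X = X, Zg = Zg, tests = tests, checks = checks)
}

indicator <- function(v, levels, prefix) {
  Z <- outer(v, levels, `==`) * 1
  colnames(Z) <- paste0(prefix, levels)
  Z
}

#' Build the spatial (P-spline surface) mixed model for a trial
#'
#' Fixed part: intercept, check-variety effects, resolvable-block effect,
#' and the three linear spatial columns.  Random part: the five PS-ANOVA
#' surface blocks, random row and column effects (identity precision) and
#' independent random genotype effects for the test entries.
#'
#' @param trial a [trial_data()] object.
#' @param n_knots_r,n_knots_c knot counts; default [default_knots()] of the
#'   grid dimensions.
#' @param degree,order spline degree and penalty order.
#' @return an `mm_spec` ready for [fit_reml()].
#' @export
build_spats_model <- function(trial, n_knots_r = NULL, n_knots_c = NULL,
                              degree = 3, order = 2) {
  fr <- model_frame(trial)
  obs <- fr$obs
  n_rows <- attr(trial, "n_rows"); n_cols <- attr(trial, "n_cols")
  if (is.null(n_knots_r)) n_knots_r <- default_knots(n_rows)
  if (is.null(n_knots_c)) n_knots_c <- default_knots(n_cols)
  design <- build_psanova(obs$row, obs$col, n_knots_r, n_knots_c,
                          degree = degree, order = order,
                          n_rows = n_rows, n_cols = n_cols)
  X <- cbind(fr$X, design$X_s)
  sp_names <- colnames(design$X_s)
  random <- list()
  for (k in names(design$Z))
    random[[k]] <- list(Z = design$Z[[k]], prec = design$prec[[k]])
  random$row <- list(Z = indicator(obs$row, sort(unique(obs$row)), "row"))
  random$col <- list(Z = indicator(obs$col, sort(unique(obs$col)), "col"))
  random$geno <- list(Z = fr$Zg)
  new_mm_spec(obs$y, X, random,
              meta = list(design = design, spatial_fixed = sp_names,
                          rows = obs$row, cols = obs$col,
                          genotype = obs$genotype,
                          tests = fr$tests, checks = fr$checks,
                          trial_attr = attributes(trial)[c("n_rows", "n_cols",
                                                           "trait", "units")],
                          model = "spats"))
}

#' Build the non-spatial baseline model for a trial
#'
#' Fixed intercept, check and block effects with a single random genotype
#' block and independent error: the randomization-based model against which
#' the spatial fit is compared.
#'
#' @param trial a [trial_data()] object.
#' @return an `mm_spec`.
#' @export
build_nonspatial_model <- function(trial) {
  fr <- model_frame(trial)
  new_mm_spec(fr$obs$y, fr$X, list(geno = list(Z = fr$Zg)),
              meta = list(rows = fr$obs$row, cols = fr$obs$col,
                          genotype = fr$obs$genotype,
                          tests = fr$tests, checks = fr$checks,
                          trial_attr = attributes(trial)[c("n_rows", "n_cols",
                                                           "trait", "units")],
                          model = "nonspatial"))
}

#' Extract per-genotype BLUPs (and PEVs) from a fit
#'
#' @param fit a `spats_fit` with a genotype block.
#' @return data.frame `genotype`, `blup`, `pev`.
#' @export
genotype_blups <- function(fit) {
  stopifnot(inherits(fit, "spats_fit"))
  if (!("geno" %in% names(fit$blups))) stop("fit has no genotype block")
  data.frame(genotype = names(fit$blups$geno),
             blup = unname(fit$blups$geno),
             pev = unname(fit$pev))
}

#' Pearson correlations of genotype predictions between environments
#'
#' For every pair of environments sharing at least `min_common` test
#' genotypes, the Pearson correlation of predicted genotypic values over
#' the shared set; pairs below the threshold are flagged excluded.
#'
#' @param blups_by_env named list of data.frames with columns `genotype`
#'   and `blup` (one per environment).
#' @param min_common minimum shared genotypes for a pair to count
#'   (default 30).
#' @return data.frame `env1`, `env2`, `n_common`, `pearson`, `excluded`.
#' @export
pearson_between_environments <- function(blups_by_env, min_common = 30) {
  if (length(blups_by_env) < 2) stop("need at least 2 environments")
  envs <- names(blups_by_env)
  if (is.null(envs)) envs <- paste0("env", seq_along(blups_by_env))
  out <- list()
  for (i in seq_along(envs)[-length(envs)]) for (j in (i + 1):length(envs)) {
    a <- blups_by_env[[i]]; b <- blups_by_env[[j]]
    m <- merge(a[c("genotype", "blup")], b[c("genotype", "blup")],
               by = "genotype")
    nc <- nrow(m)
    r <- if (nc >= max(min_common, 3))
      stats::cor(m$blup.x, m$blup.y) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      env1 = envs[i], env2 = envs[j], n_common = nc, pearson = r,
      excluded = nc < min_common)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation of genotype predictions between two models
#'
#' Average-rank tie handling, over the genotypes shared by both tables.
#'
#' @param blups_a,blups_b data.frames with columns `genotype`, `blup`.
#' @return the rank correlation (single number).
#' @export
spearman_between_models <- function(blups_a, blups_b) {
  m <- merge(blups_a[c("genotype", "blup")], blups_b[c("genotype", "blup")],
             by = "genotype")
  if (nrow(m) < 3) stop("fewer than 3 shared genotypes")
  stats::cor(m$blup.x, m$blup.y, method = "spearman")
}

#' Genotypic coefficient of variation
#'
#' `100 * sqrt(sigma2_g) / mean`: the genetic standard deviation as a
#' percentage of the trial mean.
#'
#' @param fit a `spats_fit` with a genotype block.
#' @param trial_mean trial mean of the trait, must be positive.
#' @export
genotypic_cv <- function(fit, trial_mean) {
  stopifnot(inherits(fit, "spats_fit"))
  if (!is.finite(trial_mean) || trial_mean <= 0)
    stop("trial mean must be positive")
  100 * sqrt(fit$vc[["geno"]]) / trial_mean
}

#' Residual variance retained by the spatial model
#'
#' `100 * sigma2_e(spatial) / sigma2_e(non-spatial)`: the nugget of the
#' spatial fit as a percentage of the non-spatial residual variance.  Both
#' fits must use the same observations.
#'
#' @param fit_spatial,fit_nonspatial fits of the two models on the same
#'   trial.
#' @export
residual_reduction <- function(fit_spatial, fit_nonspatial) {
  stopifnot(inherits(fit_spatial, "spats_fit"),
            inherits(fit_nonspatial, "spats_fit"))
  if (fit_spatial$n != fit_nonspatial$n ||
      !isTRUE(all.equal(fit_spatial$spec$y, fit_nonspatial$spec$y)))
    stop("the two fits use different observation sets")
  100 * fit_spatial$vc[["sigma2_e"]] / fit_nonspatial$vc[["sigma2_e"]]
}

#' Side-by-side comparison of a spatial and a non-spatial fit
#'
#' @param fit_spatial,fit_nonspatial fits of both models on one trial.
#' @return list of class `comparison_report`: per-model heritability and
#'   genotypic CV, residual-variance percentage retained, and the Spearman
#'   correlation between the two genotype rankings.
#' @export
compare_models <- function(fit_spatial, fit_nonspatial) {
  mu <- mean(fit_spatial$spec$y)
  h_sp <- heritability(fit_spatial, compute_l = FALSE)
  h_ns <- heritability(fit_nonspatial, compute_l = FALSE)
  structure(list(
    H2_spatial = h_sp$H2_ED, H2_nonspatial = h_ns$H2_ED,
    cv_spatial = genotypic_cv(fit_spatial, mu),
    cv_nonspatial = genotypic_cv(fit_nonspatial, mu),
    residual_pct = residual_reduction(fit_spatial, fit_nonspatial),
    spearman = spearman_between_models(genotype_blups(fit_spatial),
                                       genotype_blups(fit_nonspatial)),
    ed_spatial = attr(effective_dimensions(fit_spatial), "ed_spatial")),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Spatial vs non-spatial model comparison\n")
  cat(sprintf("  H2:        %.3f (spatial) vs %.3f (non-spatial)\n",
              x$H2_spatial, x$H2_nonspatial))
  cat(sprintf("  CV%%:       %.2f vs %.2f\n", x$cv_spatial, x$cv_nonspatial))
  cat(sprintf("  residual variance retained: %.1f%% of non-spatial\n",
              x$residual_pct))
  cat(sprintf("  Spearman between rankings:  %.3f\n", x$spearman))
  cat(sprintf("  total spatial ED: %.1f\n", x$ed_spatial))
  invisible(x)
}
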