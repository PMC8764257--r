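# Bivariate REML: additive covariance between two traits sharing one
# relationship matrix, with trait-specific pe/block effects (independent
# across traits, as the block-diagonal covariance structure prescribes) and a
# residual covariance estimated on plants observed for both traits.

#' Fit a bivariate clonal mixed model
#'
#' Stacks two single-trait designs that share a relationship matrix and
#' estimates per-trait variance components plus the additive covariance
#' `sigma_a1a2` and residual covariance `sigma_e1e2` by AI-REML.  Non-additive
#' (pe) and block effects are uncorrelated across traits; the residual
#' covariance is carried by plants observed for both traits, and is fixed to 0
#' (with a warning) when the two traits share no plants.  The autoregressive
#' spatial residual is omitted by default and can be included per trait with
#' shared autocorrelations via `spatial = TRUE`.
#'
#' @param design1,design2 `model_design` objects sharing the kinship matrix.
#' @param spatial Include per-trait AR1xAR1 spatial residuals (shared
#'   `rho_row`, `rho_col`).
#' @param constrain Character vector of covariance parameters to fix at zero
#'   (`"additive_cov"`, `"residual_cov"`), e.g. for nesting checks.
#' @param control See [clonal_blup()].
#' @return A `bivariate_fit`: component estimates/SEs, REML log-likelihood,
#'   AIC, the genetic correlation with its delta-method SE, and bookkeeping.
#' @export
fit_bivariate <- function(design1, design2, spatial = FALSE, constrain = NULL,
                          control = default_control()) {
  stopifnot(inherits(design1, "model_design"), inherits(design2, "model_design"))
  if (!identical(rownames(design1$kinship), rownames(design2$kinship)))
    stopf("the two designs must share the same kinship matrix")
  K <- unclass(design1$kinship)

  n1 <- length(design1$y); n2 <- length(design2$y)
  y <- c(design1$y, design2$y)
  tr <- rep(1:2, c(n1, n2))
  X <- cbind(`mu_1` = as.numeric(tr == 1), `mu_2` = as.numeric(tr == 2))
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  g1 <- design1$genotype; g2 <- design2$genotype
  k1 <- match(g1, rownames(K)); k2 <- match(g2, rownames(K))

  shared12 <- match(design1$plant_id, design2$plant_id)
  shared <- which(!is.na(shared12))
  fix_ecov <- "residual_cov" %in% constrain || !length(shared)
  if (!length(shared) && !("residual_cov" %in% constrain))
    warnf("traits share no plants: residual covariance fixed to 0")
  fix_acov <- "additive_cov" %in% constrain

  C <- list(additive_1 = term_sub(i1, i1, K[k1, k1, drop = FALSE]),
            additive_2 = term_sub(i2, i2, K[k2, k2, drop = FALSE]))
  meta <- data.frame(name = c("additive_1", "additive_2"), type = "var",
                     b1 = NA_character_, b2 = NA_character_,
                     stringsAsFactors = FALSE)
  if (!fix_acov) {
    C$additive_cov <- term_sub(i1, i2, K[k1, k2, drop = FALSE])
    meta <- rbind(meta, data.frame(name = "additive_cov", type = "cov",
                                   b1 = "additive_1", b2 = "additive_2"))
  }
  C$pe_1 <- term_group(i1, g1)
  C$pe_2 <- term_group(i2, g2)
  meta <- rbind(meta, data.frame(name = c("pe_1", "pe_2"), type = "var",
                                 b1 = NA_character_, b2 = NA_character_))
  has_block <- !is.null(design1$block) && !is.null(design2$block)
  if (has_block) {
    C$block_1 <- term_group(i1, design1$block)
    C$block_2 <- term_group(i2, design2$block)
    meta <- rbind(meta, data.frame(name = c("block_1", "block_2"), type = "var",
                                   b1 = NA_character_, b2 = NA_character_))
  }
  C$residual_1 <- term_diag(c(rep(1, n1), rep(0, n2)))
  C$residual_2 <- term_diag(c(rep(0, n1), rep(1, n2)))
  meta <- rbind(meta, data.frame(name = c("residual_1", "residual_2"),
                                 type = "var", b1 = NA_character_,
                                 b2 = NA_character_))
  if (!fix_ecov) {
    C$residual_cov <- term_pairs(i1[shared], i2[shared12[shared]])
    meta <- rbind(meta, data.frame(name = "residual_cov", type = "cov",
                                   b1 = "residual_1", b2 = "residual_2"))
  }

  sp <- NULL
  if (spatial) {
    if (anyNA(c(design1$row, design1$col, design2$row, design2$col)))
      stopf("spatial model requested but plants have missing layout positions")
    sp <- list(sigmas = list(
      spatial_1 = list(idx = i1,
                       Drow = abs(outer(design1$row, design1$row, "-")),
                       Dcol = abs(outer(design1$col, design1$col, "-"))),
      spatial_2 = list(idx = i2,
                       Drow = abs(outer(design2$row, design2$row, "-")),
                       Dcol = abs(outer(design2$col, design2$col, "-")))))
    meta <- rbind(meta, data.frame(name = c("spatial_1", "spatial_2"),
                                   type = "var", b1 = NA_character_,
                                   b2 = NA_character_))
  }

  v1 <- stats::var(design1$y); v2 <- stats::var(design2$y)
  st <- stats::setNames(numeric(nrow(meta)), meta$name)
  st[c("additive_1", "pe_1", "residual_1")] <- v1 / 3
  st[c("additive_2", "pe_2", "residual_2")] <- v2 / 3
  if (has_block) st[c("block_1", "block_2")] <- c(v1, v2) / 10
  if (spatial) st[c("spatial_1", "spatial_2")] <- c(v1, v2) / 10
  if (!fix_acov) st["additive_cov"] <- 0
  if (!fix_ecov) st["residual_cov"] <- 0

  eng <- reml_engine(y, X, C, meta, sp,
                     start = list(lin = st, rho = if (spatial) c(0.1, 0.1) else NULL),
                     control = control)

  n_par <- length(eng$par_names)
  fit <- structure(list(
    traits = c(design1$trait, design2$trait),
    vc = eng$theta, se = eng$se, boundary = eng$boundary,
    logLik = eng$logL, AIC = -2 * eng$logL + 2 * n_par, n_par = n_par,
    beta = stats::setNames(eng$beta, colnames(X)),
    spatial = spatial, constrained = constrain,
    vcov_free = eng$vcov_free, free = eng$free, par_names = eng$par_names,
    convergence = list(iterations = eng$iterations, trace = eng$trace,
                       score = eng$score)
  ), class = "bivariate_fit")
  fit$r_a <- tryCatch(genetic_correlation(fit), error = function(e) NULL)
  fit
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate clonal mixed model: '%s' and '%s'\n",
              x$traits[1], x$traits[2]))
  cat(sprintf("  REML logLik %.4f, AIC %.4f\n", x$logLik, x$AIC))
  print(data.frame(component = x$par_names,
                   estimate = unname(x$vc[x$par_names]),
                   se = unname(x$se[x$par_names]), row.names = NULL))
  if (!is.null(x$r_a))
    cat(sprintf("Genetic correlation r_a = %.4f (SE %s)\n", x$r_a$r,
                ifelse(is.na(x$r_a$se), "n/a", sprintf("%.4f", x$r_a$se))))
  invisible(x)
}

#' Genetic correlation between two traits
#'
#' \eqn{r_a = \sigma_{a_1 a_2} / \sqrt{\sigma^2_{a_1} \sigma^2_{a_2}}},
#' clamped to \[-1, 1\] (with a `clamped` flag when that happens).  For a
#' `bivariate_fit` the delta-method SE is computed from the inverse
#' average-information matrix; it is reported as `NA` when any of the three
#' components sits at a boundary.
#'
#' @param x A `bivariate_fit`, or the additive covariance `sigma_a1a2`.
#' @param var1,var2 Additive variances (default method only).
#' @param ... Unused.
#' @return List with `r`, `se`, `clamped`.
#' @export
genetic_correlation <- function(x, ...) UseMethod("genetic_correlation")

#' @rdname genetic_correlation
#' @export
genetic_correlation.default <- function(x, var1, var2, ...) {
  if (!is.finite(var1) || !is.finite(var2) || var1 <= 0 || var2 <= 0)
    stopf("additive variances must be positive")
  r <- x / sqrt(var1 * var2)
  clamped <- abs(r) > 1
  list(r = max(min(r, 1), -1), se = NA_real_, clamped = clamped)
}

#' @rdname genetic_correlation
#' @export
genetic_correlation.bivariate_fit <- function(x, ...) {
  if (!"additive_cov" %in% names(x$vc))
    stopf("additive covariance was constrained to zero in this fit")
  v1 <- x$vc[["additive_1"]]; v2 <- x$vc[["additive_2"]]
  cv <- x$vc[["additive_cov"]]
  out <- genetic_correlation(cv, v1, v2)
  nm <- c("additive_1", "additive_2", "additive_cov")
  free_names <- x$par_names[x$free]
  if (!is.null(x$vcov_free) && all(nm %in% free_names) &&
      !any(x$boundary[nm])) {
    Vc <- x$vcov_free[match(nm, free_names), match(nm, free_names)]
    r <- out$r
    grad <- c(-r / (2 * v1), -r / (2 * v2), 1 / sqrt(v1 * v2))
    out$se <- sqrt(max(drop(t(grad) %*% Vc %*% grad), 0))
  }
  out
}

#' Narrow-sense heritability
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)} with
#' \eqn{\sigma^2_e} the spatially independent residual variance: block and
#' spatial variances are excluded from the denominator.  An alternative
#' full-phenotypic-variance denominator (adding block and spatial components)
#' is available behind `full_denominator = TRUE` for sensitivity analysis.
#'
#' @param x Additive genetic variance, or a `clonal_blup` fit.
#' @param pe Non-additive (clone) variance.
#' @param residual Independent residual variance.
#' @param full_denominator Include block and spatial variances in the
#'   denominator.
#' @param ... Unused.
#' @return List with `h2` and `se` (delta method from the inverse
#'   average-information matrix when available; `NA` otherwise, and whenever a
#'   component sits at a boundary).
#' @examples
#' heritability(15.41, pe = 11.50, residual = 14.04)$h2  # 0.376...
#' @export
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.default <- function(x, pe, residual, ...) {
  s <- x + pe + residual
  if (!is.finite(s) || s <= 0) stopf("total variance must be positive")
  list(h2 = x / s, se = NA_real_)
}

#' @rdname heritability
#' @export
heritability.clonal_blup <- function(x, full_denominator = FALSE, ...) {
  a <- x$vc[["additive"]]; p <- x$vc[["pe"]]; e <- x$vc[["residual"]]
  denom_extra <- 0
  if (full_denominator) {
    if ("block" %in% names(x$vc)) denom_extra <- denom_extra + x$vc[["block"]]
    if ("spatial" %in% names(x$vc)) denom_extra <- denom_extra + x$vc[["spatial"]]
  }
  s <- a + p + e + denom_extra
  if (!is.finite(s) || s <= 0) stopf("total variance must be positive")
  out <- list(h2 = a / s, se = NA_real_)
  nm <- c("additive", "pe", "residual")
  free_names <- x$par_names[x$free]
  if (!full_denominator && !is.null(x$vcov_free) && all(nm %in% free_names) &&
      !any(x$boundary[nm])) {
    Vc <- x$vcov_free[match(nm, free_names), match(nm, free_names)]
    grad <- c((p + e) / s^2, -a / s^2, -a / s^2)
    out$se <- sqrt(max(drop(t(grad) %*% Vc %*% grad), 0))
  }
  out
}

#' Assemble a trait correlation matrix from pairwise estimates
#'
#' Builds the symmetric, unit-diagonal matrix used for correlation heatmaps
#' from pairwise genetic-correlation estimates.
#'
#' @param traits Character vector giving the trait order.
#' @param pairs Data frame with columns `trait1`, `trait2`, `r`.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
assemble_correlations <- function(traits, pairs) {
  k <- length(traits)
  m <- diag(1, k)
  dimnames(m) <- list(traits, traits)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$trait1[i]; b <- pairs$trait2[i]
    if (!a %in% traits || !b %in% traits)
      stopf("pair (%s, %s) refers to a trait not in 'traits'", a, b)
    m[a, b] <- pairs$r[i]
    m[b, a] <- pairs$r[i]
  }
  m
}
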