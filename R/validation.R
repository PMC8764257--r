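# Cross-validated accuracy of breeding values and relative selection
# efficiency of marker-based over pedigree-based prediction.

#' Random k-fold partitions of the genotype set
#'
#' Folds are assigned at genotype level so that clonal ramets never straddle
#' training and validation. Within each replicate the folds partition the
#' genotype set with sizes differing by at most one. Deterministic given the
#' seed (per-replicate streams are derived from it).
#'
#' @param genotypes Character vector of genotype ids.
#' @param k Number of folds (default 10).
#' @param reps Number of random replicates (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan` data frame with columns `genotype`, `rep`, `fold`.
#' @export
make_folds <- function(genotypes, k = 10, reps = 10, seed = 1) {
  genotypes <- as.character(genotypes)
  n <- length(genotypes)
  if (k < 2) stopf("need at least 2 folds")
  if (k > n) stopf("more folds (%d) than genotypes (%d)", k, n)
  out <- vector("list", reps)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  for (r in seq_len(reps)) {
    perm <- with_seed(child_seed(seed, r), sample(genotypes))
    out[[r]] <- data.frame(genotype = perm, rep = r,
                           fold = rep(seq_len(k), times = sizes),
                           stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, out)
  attr(plan, "k") <- k
  attr(plan, "reps") <- reps
  attr(plan, "seed") <- seed
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Cross-validated accuracy of estimated breeding values
#'
#' For each replicate and fold, the phenotypes of the validation genotypes are
#' masked, breeding values for them are predicted from the training records
#' through the relationship matrix (variance components fixed at the full-data
#' estimates by default; `refit = TRUE` re-estimates them per fold), and the
#' fold accuracy is the Pearson correlation between those predictions and the
#' full-data EBVs. The result averages over all folds and replicates.
#'
#' A fold whose training data carry no kinship information about a validation
#' genotype yields a constant zero prediction; such folds are assigned
#' accuracy 0 (no signal) and counted in `n_degenerate`.
#'
#' @param fit A converged `clonal_blup` fit on the full data.
#' @param plan A `fold_plan` over (a superset of) the phenotyped genotypes.
#' @param refit Re-estimate variance components within each training fold.
#' @param mask_validation If `FALSE`, training uses all records (masking an
#'   empty set); accuracy is then exactly 1 by construction.
#' @param reference Optional named numeric vector of reference values per
#'   genotype to correlate the masked predictions against, instead of the
#'   full-data EBVs — e.g. true breeding values from the simulation harness.
#' @param control Engine control (only used when `refit = TRUE`).
#' @return List with `mean`, `sd`, `per_fold` (data frame), `n_degenerate`.
#' @export
cv_accuracy <- function(fit, plan, refit = FALSE, mask_validation = TRUE,
                        reference = NULL, control = default_control()) {
  stopifnot(inherits(fit, "clonal_blup"), inherits(plan, "fold_plan"))
  design <- fit$design
  K <- unclass(design$kinship)
  gidx <- match(design$genotype, rownames(K))
  sig_a <- fit$vc[["additive"]]
  full_ebv <- if (is.null(reference))
    stats::setNames(fit$ebv$ebv, fit$ebv$genotype)
  else reference

  # full-data covariance at the fitted components; folds use its submatrices
  tm <- model_cov_terms(design, spatial = fit$spatial,
                        include_pe = fit$include_pe)
  lin <- as.list(fit$vc[tm$meta$name])
  if (fit$spatial) lin$spatial <- fit$vc[["spatial"]]
  rho <- if (fit$spatial) fit$vc[c("rho_row", "rho_col")] else NULL
  Vfull <- engine_build_V(tm$C, tm$spatial, lin, rho, tm$n)

  reps <- attr(plan, "reps"); k <- attr(plan, "k")
  res <- vector("list", reps * k)
  n_degenerate <- 0L
  i <- 0L
  for (r in seq_len(reps)) {
    pr <- plan[plan$rep == r, ]
    for (f in seq_len(k)) {
      i <- i + 1L
      val_genos <- pr$genotype[pr$fold == f]
      val_genos <- intersect(val_genos, design$genotype)
      if (!length(val_genos)) next
      train <- if (mask_validation) which(!(design$genotype %in% val_genos))
               else seq_along(design$y)
      if (refit) {
        sub <- design
        sub$y <- design$y[train]; sub$X <- design$X[train, , drop = FALSE]
        sub$plant_id <- design$plant_id[train]
        sub$genotype <- design$genotype[train]
        sub$block <- design$block[train]
        sub$row <- design$row[train]; sub$col <- design$col[train]
        f_tr <- clonal_blup(sub, spatial = fit$spatial, control = control)
        pred <- stats::setNames(f_tr$ebv$ebv, f_tr$ebv$genotype)[val_genos]
      } else {
        Vt <- Vfull[train, train]
        Rc <- chol(Vt)
        yt <- design$y[train]; Xt <- design$X[train, , drop = FALSE]
        Viy <- backsolve(Rc, backsolve(Rc, yt, transpose = TRUE))
        ViX <- backsolve(Rc, backsolve(Rc, Xt, transpose = TRUE))
        beta <- solve(crossprod(Xt, ViX), crossprod(Xt, Viy))
        Pyt <- Viy - ViX %*% beta
        pred <- drop(sig_a * (K[val_genos, gidx[train], drop = FALSE] %*% Pyt))
      }
      truth <- full_ebv[val_genos]
      if (stats::sd(pred) < 1e-300 || stats::sd(truth) < 1e-300) {
        acc <- 0
        n_degenerate <- n_degenerate + 1L
      } else {
        acc <- stats::cor(pred, truth)
      }
      res[[i]] <- data.frame(rep = r, fold = f, accuracy = acc,
                             n_val = length(val_genos))
    }
  }
  per_fold <- do.call(rbind, res)
  list(mean = mean(per_fold$accuracy), sd = stats::sd(per_fold$accuracy),
       per_fold = per_fold, n_degenerate = n_degenerate)
}

#' Relative efficiency of GBLUP over ABLUP selection
#'
#' `RE (%) = 100 * acc_gblup / acc_ablup`, where each accuracy is the
#' cross-validated correlation between validation-set predictions and
#' full-data pedigree EBVs.
#'
#' @param acc_gblup,acc_ablup Accuracies (correlations).
#' @return RE in percent.
#' @export
relative_efficiency <- function(acc_gblup, acc_ablup) {
  if (!is.finite(acc_ablup) || acc_ablup == 0)
    stopf("ABLUP accuracy must be nonzero")
  100 * acc_gblup / acc_ablup
}

#' Relative efficiency per year
#'
#' Rescales RE by the ratio of breeding-cycle lengths: conventional
#' progeny-test selection (about 17 years) versus genomic selection (about
#' 9 years).
#'
#' @param re Relative efficiency in percent.
#' @param L_ts Breeding-cycle length for pedigree selection, years.
#' @param L_gs Breeding-cycle length for genomic selection, years.
#' @return RE per year in percent.
#' @export
relative_efficiency_per_year <- function(re, L_ts = 17, L_gs = 9) {
  if (!is.finite(L_gs) || L_gs <= 0) stopf("genomic cycle length must be positive")
  re * L_ts / L_gs
}
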