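# End-to-end evaluation: kinship construction, spatial vs non-spatial model
# comparison, ABLUP/GBLUP variance components and heritability, optional
# bivariate genetic correlations, cross-validated accuracy and relative
# selection efficiency, with machine-readable outputs.

#' Assemble a run configuration
#'
#' @param pheno Path to a phenotype/layout CSV (see [read_phenotypes()]) or a
#'   data frame.
#' @param pedigree Path to a pedigree CSV or a [pedigree] object.
#' @param markers Optional path to genotypes (`marker_format` gives the
#'   reader) or a `marker_matrix`; required when `"GBLUP"` is in `models`.
#' @param traits Trait columns to analyse.
#' @param models Any of `"ABLUP"`, `"GBLUP"`.
#' @param spatial Fit the AR1xAR1 spatial residual model (a non-spatial fit is
#'   always produced for the AIC comparison).
#' @param auto_spatial When `TRUE`, downstream results use whichever model
#'   (spatial or not) has the lower AIC; otherwise the comparison is only
#'   reported and `spatial` decides.
#' @param marker_format `"matrix-csv"` or `"vcf"`.
#' @param maf_min,max_missing Marker filter thresholds.
#' @param bivariate Optional list of length-2 character vectors: trait pairs
#'   for genetic correlations.
#' @param cv_k,cv_reps Cross-validation folds and replicates (0 reps skips CV).
#' @param seed Master seed for all randomness (fold assignment).
#' @param out_dir Optional output directory for the JSON/CSV report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(pheno, pedigree, markers = NULL, traits,
                       models = c("ABLUP", "GBLUP"), spatial = TRUE,
                       auto_spatial = FALSE, marker_format = "matrix-csv",
                       maf_min = 0.01, max_missing = 0.40,
                       bivariate = NULL, cv_k = 10, cv_reps = 10,
                       seed = 1, out_dir = NULL) {
  cfg <- list(pheno = pheno, pedigree = pedigree, markers = markers,
              traits = traits, models = match.arg(models, several.ok = TRUE),
              spatial = spatial, auto_spatial = auto_spatial,
              marker_format = marker_format, maf_min = maf_min,
              max_missing = max_missing, bivariate = bivariate,
              cv_k = cv_k, cv_reps = cv_reps, seed = seed, out_dir = out_dir)
  for (f in c("pheno", "pedigree", "markers")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("config: file '%s' (field %s) does not exist", cfg[[f]], f)
  }
  if ("GBLUP" %in% cfg$models && is.null(cfg$markers))
    stopf("config: GBLUP requested but no marker data supplied")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(run_config, lst)
}

#' Run the full genetic evaluation
#'
#' For each trait: spatial and non-spatial single-trait fits with an AIC
#' comparison, for each requested kinship source (pedigree ABLUP, marker
#' GBLUP); narrow-sense heritability; optional bivariate genetic correlations;
#' cross-validated EBV accuracy and the relative efficiency of GBLUP over
#' ABLUP (total and per year). When `out_dir` is set, writes `report.json`
#' (deterministic given config and seed), descriptive/component/accuracy
#' tables as CSV, and a timestamped `run.log`.
#'
#' @param config A `run_config` (or a YAML path understood by
#'   [read_run_config()]).
#' @return The report bundle (list). `bundle$status` is `"complete"` or
#'   `"partial"` (with `bundle$failed_stage` naming the first failure).
#' @export
run_evaluation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()), msg))
  }
  bundle <- list(seed = config$seed, status = "complete",
                 package_version = as.character(utils::packageVersion("clonalGS")))
  fail <- function(stage, err) {
    bundle$status <<- "partial"
    if (is.null(bundle$failed_stage)) bundle$failed_stage <<- stage
    say("stage %s failed: %s", stage, conditionMessage(err))
  }

  # ---- inputs ----
  pheno <- if (is.character(config$pheno)) read_phenotypes(config$pheno) else config$pheno
  ped <- if (is.character(config$pedigree)) read_pedigree(config$pedigree) else config$pedigree
  say("inputs: %d plants, %d pedigree records, seed %d",
      nrow(pheno), nrow(ped), config$seed)

  kinships <- list()
  if ("ABLUP" %in% config$models)
    kinships$ABLUP <- numerator_relationship(ped)
  if ("GBLUP" %in% config$models) {
    mk <- if (is.character(config$markers))
      read_markers(config$markers, format = config$marker_format)
    else config$markers
    flt <- filter_markers(mk, maf_min = config$maf_min,
                          max_missing = config$max_missing)
    bundle$marker_filter <- flt$report
    G <- stabilize(genomic_relationship(impute_mean(flt$markers)))
    say("G matrix: %d individuals from %d markers (stabilized: %s)",
        nrow(G), flt$report$retained, attr(G, "stabilized"))
    kinships$GBLUP <- G
  }

  # ---- descriptive statistics ----
  bundle$descriptives <- tryCatch(
    summarize_traits(pheno, config$traits),
    error = function(e) { fail("descriptives", e); NULL })

  # ---- single-trait fits ----
  fits <- list()
  comp_rows <- list()
  for (trait in config$traits) {
    for (model in names(kinships)) {
      key <- paste(trait, model, sep = ".")
      res <- tryCatch({
        d <- build_design(pheno, trait, kinships[[model]])
        f_ns <- clonal_blup(d, spatial = FALSE)
        f_sp <- if (config$spatial) clonal_blup(d, spatial = TRUE) else NULL
        use_spatial <- if (is.null(f_sp)) FALSE
          else if (config$auto_spatial) f_sp$AIC < f_ns$AIC else config$spatial
        f <- if (use_spatial) f_sp else f_ns
        h2 <- heritability(f)
        say("%s %s: logL %.3f AIC %.3f (non-spatial AIC %.3f), h2 %.3f",
            trait, model, f$logLik, f$AIC, f_ns$AIC, h2$h2)
        list(fit = f, aic_spatial = if (is.null(f_sp)) NA_real_ else f_sp$AIC,
             aic_nonspatial = f_ns$AIC, spatial_used = use_spatial, h2 = h2)
      }, error = function(e) { fail(key, e); NULL })
      if (is.null(res)) next
      fits[[key]] <- res
      vc <- res$fit$vc
      comp_rows[[key]] <- data.frame(
        trait = trait, model = model,
        pe = vc[["pe"]], additive = vc[["additive"]],
        residual = vc[["residual"]],
        block = if ("block" %in% names(vc)) vc[["block"]] else NA_real_,
        spatial = if ("spatial" %in% names(vc)) vc[["spatial"]] else NA_real_,
        rho_row = if ("rho_row" %in% names(vc)) vc[["rho_row"]] else NA_real_,
        rho_col = if ("rho_col" %in% names(vc)) vc[["rho_col"]] else NA_real_,
        h2 = res$h2$h2, h2_se = res$h2$se,
        logLik = res$fit$logLik, AIC = res$fit$AIC,
        AIC_nonspatial = res$aic_nonspatial,
        spatial_used = res$spatial_used,
        converged = res$fit$convergence$converged,
        iterations = res$fit$convergence$iterations)
  }
  }
  bundle$components <- if (length(comp_rows)) do.call(rbind, c(comp_rows, make.row.names = FALSE)) else NULL

  # ---- bivariate genetic correlations ----
  if (!is.null(config$bivariate) && "ABLUP" %in% names(kinships)) {
    biv_rows <- list()
    for (pair in config$bivariate) {
      key <- paste(pair, collapse = "-")
      res <- tryCatch({
        d1 <- build_design(pheno, pair[1], kinships$ABLUP)
        d2 <- build_design(pheno, pair[2], kinships$ABLUP)
        bf <- fit_bivariate(d1, d2)
        say("bivariate %s: r_a %.3f (spatial term omitted)", key, bf$r_a$r)
        data.frame(trait1 = pair[1], trait2 = pair[2], r = bf$r_a$r,
                   r_se = bf$r_a$se, logLik = bf$logLik)
      }, error = function(e) { fail(paste0("bivariate.", key), e); NULL })
      if (!is.null(res)) biv_rows[[key]] <- res
    }
    bundle$genetic_correlations <- if (length(biv_rows))
      do.call(rbind, c(biv_rows, make.row.names = FALSE)) else NULL
  }

  # ---- cross-validation and relative efficiency ----
  if (config$cv_reps > 0) {
    acc_rows <- list()
    for (trait in config$traits) {
      keyA <- paste(trait, "ABLUP", sep = ".")
      keyG <- paste(trait, "GBLUP", sep = ".")
      if (!keyA %in% names(fits)) next
      res <- tryCatch({
        fitA <- fits[[keyA]]$fit
        plan <- make_folds(unique(fitA$design$genotype), k = config$cv_k,
                           reps = config$cv_reps, seed = config$seed)
        accA <- cv_accuracy(fitA, plan)
        accG <- if (keyG %in% names(fits)) cv_accuracy(fits[[keyG]]$fit, plan) else NULL
        re <- if (!is.null(accG)) relative_efficiency(accG$mean, accA$mean) else NA_real_
        re_yr <- if (!is.null(accG)) relative_efficiency_per_year(re) else NA_real_
        say("cv %s: ABLUP %.3f GBLUP %s RE %s", trait, accA$mean,
            if (is.null(accG)) "n/a" else sprintf("%.3f", accG$mean),
            if (is.na(re)) "n/a" else sprintf("%.0f%%", re))
        data.frame(trait = trait, ABLUP = accA$mean, ABLUP_sd = accA$sd,
                   GBLUP = if (is.null(accG)) NA_real_ else accG$mean,
                   GBLUP_sd = if (is.null(accG)) NA_real_ else accG$sd,
                   RE = re, RE_year = re_yr)
      }, error = function(e) { fail(paste0("cv.", trait), e); NULL })
      if (!is.null(res)) acc_rows[[trait]] <- res
    }
    bundle$accuracy <- if (length(acc_rows))
      do.call(rbind, c(acc_rows, make.row.names = FALSE)) else NULL
  }

  # ---- effective population size ----
  bundle$status_number <- tryCatch({
    if ("ABLUP" %in% names(kinships)) {
      f <- average_coancestry(kinships$ABLUP)
      list(mean_coancestry = f, Ns = status_number(f))
    } else NULL
  }, error = function(e) { fail("status_number", e); NULL })

  # ---- outputs ----
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(bundle, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", dataframe = "rows")
    if (!is.null(bundle$descriptives))
      utils::write.csv(bundle$descriptives,
                       file.path(config$out_dir, "descriptives.csv"),
                       row.names = FALSE)
    if (!is.null(bundle$components))
      utils::write.csv(bundle$components,
                       file.path(config$out_dir, "components.csv"),
                       row.names = FALSE)
    if (!is.null(bundle$accuracy)) {
      tab3 <- bundle$accuracy
      tab3$RE <- round(tab3$RE)
      tab3$RE_year <- round(tab3$RE_year)
      utils::write.csv(tab3, file.path(config$out_dir, "accuracy.csv"),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  bundle$log <- log_lines
  bundle
}
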