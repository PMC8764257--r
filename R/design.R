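# Phenotype/layout tables and model design structures for the individual-tree
# mixed model  y = Xb + Z a + Z pe + Z b + e,  e = xi + eta.

#' Read a phenotype-plus-layout table
#'
#' CSV with columns `plant_id`, `genotype_id`, `block`, `row`, `col` and one or
#' more trait columns. Trait values may be missing.
#'
#' @param path CSV path.
#' @return A data frame; `row` and `col` coerced to integer.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("plant_id", "genotype_id", "block", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("phenotype file lacks column(s): %s", paste(miss, collapse = ", "))
  df$plant_id <- as.character(df$plant_id)
  df$genotype_id <- as.character(df$genotype_id)
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  dup <- df[!is.na(df$row) & !is.na(df$col), ]
  if (anyDuplicated(dup[, c("row", "col")]))
    stopf("trial layout places more than one plant in the same grid cell")
  df
}

#' Build the design for a single-trait clonal mixed model
#'
#' Drops plants with a missing trait value (count recorded), checks every
#' phenotyped genotype against the kinship labels, and assembles response,
#' intercept (plus optional covariates) and the genotype/block/layout
#' groupings used by [clonal_blup()].
#'
#' @param data Phenotype/layout data frame (see [read_phenotypes()]): columns
#'   `plant_id`, `genotype_id`, `block`, `row`, `col`, plus trait columns.
#' @param trait Name of the trait column to analyse.
#' @param kinship A `relationship_matrix` covering (at least) all phenotyped
#'   genotypes.
#' @param covariates Optional character vector of numeric covariate columns
#'   added to the fixed effects alongside the intercept.
#' @return A `model_design` object.
#' @export
build_design <- function(data, trait, kinship, covariates = NULL) {
  kinship <- as_relationship(kinship)
  if (!trait %in% names(data)) stopf("trait '%s' not found in data", trait)
  y_all <- as.numeric(data[[trait]])
  keep <- !is.na(y_all)
  n_dropped <- sum(!keep)
  if (!any(keep)) stopf("no observations: all values of '%s' are missing", trait)
  d <- data[keep, , drop = FALSE]
  y <- y_all[keep]
  if (any(!is.finite(y))) stopf("non-finite values in trait '%s'", trait)

  offenders <- setdiff(unique(d$genotype_id), rownames(kinship))
  if (length(offenders))
    stopf("genotype(s) absent from kinship labels: %s",
          paste(utils::head(offenders, 5), collapse = ", "))

  X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    for (cv in covariates) {
      if (!cv %in% names(d)) stopf("covariate '%s' not found", cv)
      X <- cbind(X, as.numeric(d[[cv]]))
      colnames(X)[ncol(X)] <- cv
    }
  }

  structure(list(
    trait = trait,
    y = y,
    X = X,
    plant_id = d$plant_id,
    genotype = as.character(d$genotype_id),
    block = if ("block" %in% names(d)) as.character(d$block) else NULL,
    row = if ("row" %in% names(d)) as.integer(d$row) else NULL,
    col = if ("col" %in% names(d)) as.integer(d$col) else NULL,
    kinship = kinship,
    n_dropped = n_dropped
  ), class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("Model design for trait '%s': %d plants, %d genotypes, %s blocks (%d dropped as missing)\n",
              x$trait, length(x$y), length(unique(x$genotype)),
              if (is.null(x$block)) "no" else length(unique(x$block)), x$n_dropped))
  invisible(x)
}

#' Separable AR1 x AR1 spatial correlation over plants
#'
#' Entry for plants at grid positions (r1, c1) and (r2, c2) is
#' \eqn{\rho_{row}^{|r1-r2|} \rho_{col}^{|c1-c2|}}, i.e. the observed-position
#' submatrix of the full-grid Kronecker correlation.
#'
#' @param rows,cols Integer grid coordinates, one per plant.
#' @param rho_row,rho_col AR1 autocorrelations, each in (-1, 1).
#' @return Correlation matrix over the plants, in input order.
#' @export
spatial_correlation <- function(rows, cols, rho_row, rho_col) {
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1)
    stopf("autocorrelation parameters must lie strictly inside (-1, 1)")
  if (length(rows) != length(cols)) stopf("rows and cols differ in length")
  if (anyNA(rows) || anyNA(cols)) stopf("plants with missing layout positions")
  Dr <- abs(outer(rows, rows, "-"))
  Dc <- abs(outer(cols, cols, "-"))
  pow_int(rho_row, Dr) * pow_int(rho_col, Dc)
}
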