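# SNP genotype I/O, quality filters, mean imputation, and the VanRaden
# genomic relationship matrix.
#
# Genotypes are coded 0, 1, 2 for the alternative-allele homozygote,
# heterozygote and reference-allele homozygote; missing calls are NA.

#' Construct a marker matrix
#'
#' @param genotypes Numeric matrix, individuals in rows, markers in columns,
#'   entries in \{0, 1, 2\} or `NA` (and, after imputation, real values in
#'   `[0, 2]`).
#' @return A `marker_matrix` object.
#' @export
marker_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) == 0L || ncol(genotypes) == 0L)
    stopf("marker matrix needs at least one individual and one marker")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  storage.mode(genotypes) <- "double"
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stopf("genotype codes must lie in [0, 2]")
  structure(genotypes, class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  miss <- mean(is.na(x))
  cat(sprintf("Marker matrix: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * miss))
  invisible(x)
}

#' Reference-allele frequencies per marker
#'
#' Computed from non-missing calls; the code counts reference alleles, so the
#' frequency is `mean(code)/2` per column.
#' @param m A `marker_matrix`.
#' @return Numeric vector, one frequency per marker.
#' @export
allele_freq <- function(m) {
  colMeans(unclass(m), na.rm = TRUE) / 2
}

#' Read SNP genotypes
#'
#' Supports VCF (biallelic SNP records; the GT field is translated so that the
#' reference homozygote is coded 2) and a plain CSV genotype matrix
#' (individuals in rows, markers in columns, missing as `NA` or `.`; values
#' taken as already coded).
#'
#' @param path File path.
#' @param format `"vcf"` or `"matrix-csv"`.
#' @return A `marker_matrix`. For VCF input the number of skipped
#'   multi-allelic records is attached as attribute `n_multiallelic`.
#' @export
read_markers <- function(path, format = c("vcf", "matrix-csv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt <- fix[, "ALT"]
    ref <- fix[, "REF"]
    biall <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
    n_multi <- sum(!biall)
    if (n_multi > 0)
      message(sprintf("read_markers: skipped %d non-biallelic record(s)", n_multi))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[biall, , drop = FALSE]
    ids <- colnames(gt)
    snps <- rownames(gt)
    if (is.null(snps)) snps <- paste0("snp", seq_len(nrow(gt)))
    # count ALT alleles then flip: ref hom (0/0) -> 2
    alt_count <- matrix(NA_real_, nrow(gt), ncol(gt))
    gt_clean <- gsub("\\|", "/", gt)
    alt_count[gt_clean == "0/0"] <- 0
    alt_count[gt_clean %in% c("0/1", "1/0")] <- 1
    alt_count[gt_clean == "1/1"] <- 2
    geno <- t(2 - alt_count)
    dimnames(geno) <- list(ids, snps)
    out <- marker_matrix(geno)
    attr(out, "n_multiallelic") <- n_multi
    out
  } else {
    df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", "."))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    marker_matrix(m)
  }
}

#' Write a marker matrix as CSV
#'
#' Inverse of `read_markers(format = "matrix-csv")`: first column `id`, one
#' column per marker.
#' @param m A `marker_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Filter markers on minor allele frequency and missingness
#'
#' Removes markers with MAF below `maf_min` or a missing-call fraction above
#' `max_missing` (both computed on non-missing calls / the full column
#' respectively).
#'
#' @param m A `marker_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param max_missing Maximum missing fraction (default 0.40).
#' @return A list with `markers` (the filtered `marker_matrix`, possibly with
#'   zero columns) and `report` (counts removed by each rule and retained,
#'   plus the thresholds).
#' @export
filter_markers <- function(m, maf_min = 0.01, max_missing = 0.40) {
  stopifnot(inherits(m, "marker_matrix"),
            maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  g <- unclass(m)
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column: fails MAF too, but missingness rules first
  missfrac <- colMeans(is.na(g))
  fail_miss <- missfrac > max_missing
  fail_maf <- maf < maf_min
  keep <- !(fail_maf | fail_miss)
  report <- list(
    n_input = ncol(g),
    removed_maf = sum(fail_maf),
    removed_missing = sum(fail_miss),
    removed = sum(!keep),
    retained = sum(keep),
    maf_min = maf_min,
    max_missing = max_missing
  )
  if (!any(keep)) warnf("all %d markers removed by filters", ncol(g))
  kept <- g[, keep, drop = FALSE]
  out <- if (ncol(kept) > 0) marker_matrix(kept) else
    structure(kept, class = c("marker_matrix", "matrix", "array"))
  list(markers = out, report = report)
}

#' Mean-impute missing genotypes
#'
#' Each missing call is replaced by the mean genotype code of the non-missing
#' calls for that marker; non-missing entries are untouched.
#'
#' @param m A `marker_matrix` (typically after [filter_markers()]).
#' @return A `marker_matrix` with no missing entries.
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  g <- unclass(m)
  if (!anyNA(g)) return(m)
  mu <- colMeans(g, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stopf("marker(s) with zero non-missing calls: %s",
          paste(utils::head(colnames(g)[is.nan(mu)], 3), collapse = ", "))
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- mu[idx[, 2]]
  marker_matrix(g)
}

#' VanRaden genomic relationship matrix
#'
#' \deqn{G = Z Z' / (\mathrm{trace}(Z Z') / n), \quad Z = M - P}
#' where `M` is the imputed genotype matrix and `P` broadcasts twice the
#' reference-allele frequency per marker. With `divisor = "individuals"`
#' (default) `n` is the number of individuals, so `mean(diag(G)) = 1`;
#' `divisor = "markers"` uses the number of markers instead.
#'
#' @param m An imputed `marker_matrix` (no missing values).
#' @param divisor `"individuals"` or `"markers"`.
#' @return A `relationship_matrix` of kind `"marker"`.
#' @export
genomic_relationship <- function(m, divisor = c("individuals", "markers")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(m, "marker_matrix"))
  g <- unclass(m)
  if (anyNA(g)) stopf("impute missing genotypes before building G (see impute_mean)")
  p <- colMeans(g) / 2
  Z <- sweep(g, 2L, 2 * p, "-")
  ZZt <- tcrossprod(Z)
  tr <- sum(diag(ZZt))
  if (tr <= 1e-12)
    stopf("degenerate input: all markers monomorphic after centering (trace is zero)")
  n <- if (divisor == "individuals") nrow(g) else ncol(g)
  relationship_matrix(ZZt / (tr / n), kind = "marker")
}
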