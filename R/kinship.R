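# Labelled symmetric relationship matrices (pedigree A or genomic G), shared
# by all model fits, plus CSV I/O and ridge stabilization.

#' Create a relationship matrix object
#'
#' @param values Square numeric matrix with identical row/column labels.
#' @param kind `"pedigree"` or `"marker"`.
#' @return A `relationship_matrix`: the matrix with a `kind` attribute.
#' @export
relationship_matrix <- function(values, kind = c("pedigree", "marker")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("relationship matrix must be square")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("relationship matrix must carry individual labels")
  if (!identical(rownames(values), colnames(values)))
    stopf("row and column labels differ")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) stopf("relationship matrix is not symmetric (max deviation %.3g)", asym)
  values <- (values + t(values)) / 2
  structure(values, kind = kind, class = c("relationship_matrix", "matrix", "array"))
}

as_relationship <- function(x) {
  if (inherits(x, "relationship_matrix")) return(x)
  relationship_matrix(x, kind = "pedigree")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals, mean diagonal %.4f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Write a relationship matrix as labelled CSV
#' @param A A `relationship_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relationship <- function(A, path) {
  df <- data.frame(id = rownames(A), as.data.frame(unclass(A), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix from labelled CSV
#' @param path CSV written by [write_relationship()] (first column `id`,
#'   remaining columns one per individual).
#' @param kind Matrix kind, `"pedigree"` or `"marker"`.
#' @return A `relationship_matrix`.
#' @export
read_relationship <- function(path, kind = c("pedigree", "marker")) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  relationship_matrix(m, kind = match.arg(kind))
}

#' Ridge-stabilize a relationship matrix
#'
#' A genomic relationship matrix built from finitely many markers (or with
#' duplicated individuals) can be singular; mixed-model equations need it
#' positive definite. When the smallest eigenvalue falls below `ridge`, the
#' ridge is added to the diagonal; otherwise the matrix is returned unchanged.
#'
#' @param G A `relationship_matrix`.
#' @param ridge Small positive scalar (default `1e-6`).
#' @return The (possibly) stabilized matrix; attribute `stabilized` records
#'   whether the ridge was applied.
#' @export
stabilize <- function(G, ridge = 1e-6) {
  stopifnot(ridge > 0)
  G <- as_relationship(G)
  lam_min <- min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values)
  applied <- lam_min < ridge
  if (applied) {
    out <- relationship_matrix(unclass(G) + diag(ridge, nrow(G)), kind = attr(G, "kind"))
  } else {
    out <- G
  }
  attr(out, "stabilized") <- applied
  out
}
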