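# Pedigree handling: reading, validation, the numerator relationship matrix A,
# and coancestry-based effective population size (status number).

UNKNOWN <- NA_character_

normalize_parent <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA"] <- UNKNOWN
  x
}

#' Construct a pedigree object
#'
#' Validates records, inserts founders for any parent that never appears as an
#' individual, and sorts topologically (parents before offspring; ties broken
#' by input order).
#'
#' @param id,sire,dam Character vectors of equal length. Unknown parents may be
#'   coded as `NA`, `""`, `"0"` or `"NA"` (case-insensitive).
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `sire`, `dam`, topologically ordered.
#' @examples
#' pedigree(c("F1", "F2", "X"), c(NA, NA, "F1"), c(NA, NA, "F2"))
#' @export
pedigree <- function(id, sire, dam) {
  id <- trimws(as.character(id))
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (length(id) == 0L) stopf("pedigree has no records")
  if (any(id == "" | is.na(id))) stopf("pedigree ids must be non-missing")
  dup <- id[duplicated(id)]
  if (length(dup)) stopf("duplicate pedigree id: '%s'", dup[1])

  # auto-insert founders for parents never declared as individuals
  parents <- unique(stats::na.omit(c(sire, dam)))
  missing_par <- setdiff(parents, id)
  if (length(missing_par)) {
    id <- c(missing_par, id)
    sire <- c(rep(UNKNOWN, length(missing_par)), sire)
    dam <- c(rep(UNKNOWN, length(missing_par)), dam)
  }

  # Kahn topological sort, stable in input order
  n <- length(id)
  idx <- seq_len(n)
  pos <- stats::setNames(idx, id)
  si <- unname(pos[sire]); di <- unname(pos[dam])
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  sire_ok <- function() is.na(si) | placed[ifelse(is.na(si), 1L, si)]
  dam_ok <- function() is.na(di) | placed[ifelse(is.na(di), 1L, di)]
  repeat {
    ready <- which(!placed & sire_ok() & dam_ok())
    if (!length(ready)) break
    order_out <- c(order_out, ready)
    placed[ready] <- TRUE
  }
  if (length(order_out) < n) {
    cyc <- id[which(!placed)[1]]
    stopf("pedigree contains a cycle involving individual '%s'", cyc)
  }

  out <- data.frame(id = id[order_out], sire = sire[order_out],
                    dam = dam[order_out], stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `id`, `sire`, `dam` (UTF-8). Unknown parents
#' may be empty, `"0"` or `"NA"`. Parents referenced but never declared are
#' inserted as founders; records are returned topologically sorted.
#'
#' @param path Path to a CSV file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(tab)))
    stopf("pedigree file must have columns id, sire, dam (got: %s)",
          paste(names(tab), collapse = ", "))
  pedigree(tab$id, tab$sire, tab$dam)
}

#' Write a pedigree to CSV
#' @param ped A [pedigree] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d individuals (%d founders)\n", nrow(x), founders))
  utils::str(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' recursion: processing individuals parents-first,
#' \eqn{a_{ij} = (a_{j,s(i)} + a_{j,d(i)})/2} for previously processed j, and
#' \eqn{a_{ii} = 1 + a_{s(i),d(i)}/2}; an unknown parent contributes 0.
#'
#' @param ped A [pedigree] object.
#' @return A `relationship_matrix` (symmetric, labelled, kind
#'   `"pedigree"`). Diagonals are `1 + F` with F the inbreeding coefficient.
#' @examples
#' ped <- pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
#' numerator_relationship(ped)
#' @export
numerator_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- unname(pos[ped$sire]); di <- unname(pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (is.na(s)) 0 else A[j, s]
      rd <- if (is.na(d)) 0 else A[j, d]
      aij <- 0.5 * (rs + rd)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  relationship_matrix(A, kind = "pedigree")
}

#' Mean coancestry of a population
#'
#' Coancestry is half the additive relationship, \eqn{f_{ij} = a_{ij}/2},
#' including self-pairs (self-coancestry of a non-inbred individual is 0.5).
#' The mean is taken over all \eqn{N^2} ordered pairs.
#'
#' @param A A pedigree-derived `relationship_matrix`.
#' @return Mean coancestry `f` (scalar).
#' @export
average_coancestry <- function(A) {
  A <- as_relationship(A)
  n <- nrow(A)
  if (n == 0L) stopf("empty relationship matrix")
  sum(A) / (2 * n^2)
}

#' Status number (effective population size)
#'
#' \eqn{N_s = 0.5 / f} where `f` is the mean coancestry including
#' self-coancestries. Equals the census number for unrelated, non-inbred
#' individuals.
#'
#' @param f Mean coancestry in (0, 1].
#' @return Status number.
#' @export
status_number <- function(f) {
  if (!is.finite(f) || f <= 0) stopf("mean coancestry must be positive, got %s", f)
  0.5 / f
}
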