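#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: processing individuals with parents before offspring,
#' `a_ij = (a_i,sire(j) + a_i,dam(j)) / 2` for i earlier than j, and
#' `a_jj = 1 + a_sire(j),dam(j) / 2`. Unknown parents contribute 0. The
#' diagonal is `1 + F` (F = inbreeding coefficient) and the matrix is
#' symmetric positive semi-definite.
#'
#' @param ped A [pedigree()].
#' @return Numeric matrix with dimnames = individual ids.
#' @export
build_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ord <- check_acyclic(ped)  # parents precede offspring
  n <- length(ord)
  sire <- stats::setNames(ped$sire, ped$id)[ord]
  dam <- stats::setNames(ped$dam, ped$id)[ord]
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  pos <- stats::setNames(seq_len(n), ord)
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1) {
      i <- seq_len(j - 1)
      as_ <- if (s > 0) A[i, s] else numeric(j - 1)
      ad_ <- if (d > 0) A[i, d] else numeric(j - 1)
      aij <- 0.5 * (as_ + ad_)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[j, j] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}
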