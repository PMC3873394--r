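# Pedigree relationship machinery: the additive (numerator) relationship
# matrix A by the tabular method, inbreeding coefficients, and the direct
# construction of A-inverse by Henderson's rules with Quaas' inbreeding
# adjustment.

.check_ordered_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) stop("expected a `pedigree` object")
  idx <- match(ped$id, ped$id)
  s <- match(ped$sire, ped$id); d <- match(ped$dam, ped$id)
  if (any(s >= idx, na.rm = TRUE) || any(d >= idx, na.rm = TRUE)) {
    stop("pedigree is not topologically ordered (parents must precede offspring)")
  }
  list(s = s, d = d)
}

#' Additive genetic relationship matrix
#'
#' Tabular method: A_ii = 1 + A_sd / 2 and A_ij = (A_js + A_jd) / 2 for
#' j preceding i, with unknown-parent terms zero.
#'
#' @param ped a topologically ordered `pedigree`.
#' @return symmetric n x n matrix with ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  par <- .check_ordered_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- par$s[i]; d <- par$d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (is.na(s)) 0 else A[s, j]
      row_d <- if (is.na(d)) 0 else A[d, j]
      A[i, j] <- A[j, i] <- 0.5 * (row_s + row_d)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Pedigree inbreeding coefficients
#'
#' F_i = A_ii - 1 from the tabular relationship matrix.
#'
#' @param ped a topologically ordered `pedigree`.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped) {
  diag(additive_relationship_matrix(ped)) - 1
}

#' Inverse of the additive relationship matrix
#'
#' Built directly by Henderson's rules with the inbreeding-aware
#' Mendelian-sampling variances (d_i = 1/2 - (F_s + F_d)/4 with both
#' parents known, 3/4 - F_p/4 with one, 1 with none).
#'
#' @param ped a topologically ordered `pedigree`.
#' @return n x n matrix satisfying A %*% Ainv = I.
#' @export
inverse_relationship_matrix <- function(ped) {
  par <- .check_ordered_pedigree(ped)
  n <- nrow(ped)
  F <- inbreeding_coefficients(ped)
  Ai <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- par$s[i]; d <- par$d[i]
    di <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (F[s] + F[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * F[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * F[d]
    } else 1
    if (di <= 0) stop("numerically singular relationship matrix at individual ", ped$id[i])
    a <- 1 / di
    Ai[i, i] <- Ai[i, i] + a
    for (p in c(s, d)) {
      if (!is.na(p)) {
        Ai[i, p] <- Ai[i, p] - a / 2
        Ai[p, i] <- Ai[p, i] - a / 2
      }
    }
    known <- c(s, d)[!is.na(c(s, d))]
    if (length(known)) {
      for (p in known) for (q in known) Ai[p, q] <- Ai[p, q] + a / 4
    }
  }
  Ai
}
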