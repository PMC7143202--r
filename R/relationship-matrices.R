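#' Relationship matrix container
#'
#' Wraps a symmetric (inverse) relationship matrix together with the animal
#' ids that define its row/column order, so that downstream code can check
#' order compatibility instead of silently reindexing.
#'
#' @param M square base or Matrix matrix.
#' @param ids character vector of animal ids, one per row.
#' @param is_inverse logical; `TRUE` when `M` is an inverse relationship
#'   matrix.
#' @return object of class `relmatrix`: a list with elements `M`, `ids`,
#'   `is_inverse`.
#' @export
relmatrix <- function(M, ids, is_inverse = FALSE) {
  ids <- as.character(ids)
  if (nrow(M) != length(ids) || ncol(M) != length(ids)) {
    stop("relationship matrix dimension does not match id vector")
  }
  structure(list(M = M, ids = ids, is_inverse = isTRUE(is_inverse)),
            class = "relmatrix")
}

#' Animal ids defining a relationship matrix's row/column order
#' @param M a `relmatrix`.
#' @return character vector of ids.
#' @export
rel_ids <- function(M) M$ids

#' Is this relationship matrix an inverse?
#' @param M a `relmatrix`.
#' @return logical.
#' @export
is_inverse <- function(M) isTRUE(M$is_inverse)

.rel_unwrap <- function(M) M$M

#' @export
print.relmatrix <- function(x, ...) {
  cat(if (x$is_inverse) "inverse " else "", "relationship matrix: ",
      length(x$ids), " animals (",
      if (methods::is(x$M, "sparseMatrix")) "sparse" else "dense",
      ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.relmatrix <- function(x, ...) {
  out <- as.matrix(x$M)
  dimnames(out) <- list(x$ids, x$ids)
  out
}

#' @export
dim.relmatrix <- function(x) dim(x$M)

.check_same_ids <- function(a_ids, b_ids, what) {
  if (length(a_ids) != length(b_ids) || any(a_ids != b_ids)) {
    stop("animal id order mismatch in ", what,
         "; matrices must share the same id order")
  }
}

#' Numerator relationship matrix by the tabular method
#'
#' Recursive (tabular) construction of the pedigree additive relationship
#' matrix A: a_ij = 0.5 (a_{s(i)j} + a_{d(i)j}) for j < i and
#' a_ii = 1 + 0.5 a_{s(i)d(i)}.  Quadratic in pedigree size; serves as the
#' exact reference for the sparse inverse.
#'
#' @param ped a [pedigree()].
#' @return dense `relmatrix` A.
#' @export
build_A_tabular <- function(ped) {
  n <- ped$n
  A <- matrix(0, n, n)
  s <- ped$sire
  d <- ped$dam
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + 0.5 * A[s[i], j]
      if (d[i] > 0L) row <- row + 0.5 * A[d[i], j]
      A[i, j] <- row
      A[j, i] <- row
    }
    aii <- 1
    if (s[i] > 0L && d[i] > 0L) aii <- aii + 0.5 * A[s[i], d[i]]
    A[i, i] <- aii
  }
  dimnames(A) <- list(ped$id, ped$id)
  relmatrix(A, ped$id)
}

#' Inbreeding coefficients by Meuwissen-Luo recursion
#'
#' Computes F_i = 0.5 a(sire_i, dam_i) without forming the full tabular A,
#' by expanding each parent pair over its ancestor path coefficients
#' (the rows of the T factor in A = T D T') and accumulating
#' sum_j t_sj t_dj d_j, where d_j is the Mendelian-sampling variance of
#' ancestor j.  Animals with an unknown parent have F = 0.
#'
#' @param ped a [pedigree()].
#' @return numeric vector of inbreeding coefficients in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  F <- numeric(n)
  dms <- numeric(n)  # Mendelian-sampling variance of each animal
  for (i in seq_len(n)) {
    dms[i] <- .mendelian_variance(s[i], d[i], F)
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    # path coefficients of sire and dam over their ancestors
    ts <- .path_coefficients(s[i], s, d)
    td <- .path_coefficients(d[i], s, d)
    common <- intersect(names(ts), names(td))
    if (length(common) == 0L) {
      F[i] <- 0
    } else {
      j <- as.integer(common)
      F[i] <- 0.5 * sum(ts[common] * td[common] * dms[j])
    }
  }
  F
}

# Row of T for animal x: coefficients on every ancestor (including x itself).
.path_coefficients <- function(x, s, d) {
  t <- numeric(x)
  t[x] <- 1
  for (k in x:1) {
    if (t[k] == 0) next
    if (s[k] > 0L) t[s[k]] <- t[s[k]] + 0.5 * t[k]
    if (d[k] > 0L) t[d[k]] <- t[d[k]] + 0.5 * t[k]
  }
  keep <- which(t != 0)
  stats::setNames(t[keep], keep)
}

.mendelian_variance <- function(si, di, F) {
  if (si > 0L && di > 0L) {
    0.5 - 0.25 * (F[si] + F[di])
  } else if (si > 0L) {
    0.75 - 0.25 * F[si]
  } else if (di > 0L) {
    0.75 - 0.25 * F[di]
  } else {
    1
  }
}

#' Sparse inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Assembles A-inverse directly from the pedigree using per-animal
#' Mendelian-sampling variances.  With `use_inbreeding = TRUE` (default)
#' the variances account for parental inbreeding via [compute_inbreeding()],
#' making the result the exact inverse of the tabular A.
#'
#' @param ped a [pedigree()].
#' @param use_inbreeding account for inbreeding in the Mendelian-sampling
#'   variances; disabling this reproduces the "A-inverse ignoring
#'   inbreeding" convention used for sensitivity checks.
#' @return sparse symmetric `relmatrix` with `is_inverse = TRUE`.
#' @export
build_A_inverse <- function(ped, use_inbreeding = TRUE) {
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  F <- if (use_inbreeding) compute_inbreeding(ped) else numeric(n)
  dms <- vapply(seq_len(n), function(i) .mendelian_variance(s[i], d[i], F),
                numeric(1))
  b <- 1 / dms
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  idx <- seq_len(n)
  add(idx, idx, b)
  has_s <- s > 0L
  has_d <- d > 0L
  # animal-parent blocks
  add(idx[has_s], s[has_s], -0.5 * b[has_s])
  add(s[has_s], idx[has_s], -0.5 * b[has_s])
  add(idx[has_d], d[has_d], -0.5 * b[has_d])
  add(d[has_d], idx[has_d], -0.5 * b[has_d])
  # parent-parent blocks
  add(s[has_s], s[has_s], 0.25 * b[has_s])
  add(d[has_d], d[has_d], 0.25 * b[has_d])
  both <- has_s & has_d
  add(s[both], d[both], 0.25 * b[both])
  add(d[both], s[both], 0.25 * b[both])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  relmatrix(Ainv, ped$id, is_inverse = TRUE)
}

#' Pedigree relationships among the genotyped subset (A22)
#'
#' Restricts the tabular A to the given animals, in the given order
#' (normally the row order of the genotype matrix).
#'
#' @param ped a [pedigree()].
#' @param genotyped_ids animal ids of the genotyped subset.
#' @return dense `relmatrix` A22 in `genotyped_ids` order.
#' @export
subset_A22 <- function(ped, genotyped_ids) {
  idx <- ped_index(ped, genotyped_ids)
  A <- build_A_tabular(ped)
  A22 <- .rel_unwrap(A)[idx, idx, drop = FALSE]
  relmatrix(A22, as.character(genotyped_ids))
}

#' Export a relationship matrix as coordinate (i, j, value) TSV
#'
#' Writes the upper triangle (including diagonal) of a symmetric matrix with
#' animal ids, one nonzero entry per line.
#'
#' @param M a `relmatrix`.
#' @param path output path.
#' @param tol entries with |value| <= tol are omitted.
#' @export
write_relmatrix <- function(M, path, tol = 0) {
  ids <- rel_ids(M)
  Md <- as.matrix(.rel_unwrap(M))
  keep <- which(upper.tri(Md, diag = TRUE) & abs(Md) > tol, arr.ind = TRUE)
  df <- data.frame(id_i = ids[keep[, 1L]], id_j = ids[keep[, 2L]],
                   value = Md[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
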