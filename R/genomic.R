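#' Read a genotype matrix and SNP map
#'
#' The genotype file is a PLINK `.raw`-style TSV: first column `animal`,
#' remaining columns one per SNP (header = SNP ids), entries 0/1/2 counting
#' copies of the A allele.  The map file is a `.map`-style TSV with columns
#' `chrom`, `snp_id`, `bp`.  Missing genotypes are rejected: imputation is
#' assumed to have happened upstream.
#'
#' @param geno_path,map_path file paths.
#' @return list with `geno` (integer matrix, animal ids as rownames) and
#'   `map` (data.frame `snp_id`, `chrom`, `bp`, `p` = NA until computed).
#' @export
read_genotypes <- function(geno_path, map_path) {
  g <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (names(g)[1L] != "animal") stop("genotype file must start with an 'animal' column")
  ids <- as.character(g$animal)
  geno <- as.matrix(g[, -1L, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  if (anyNA(geno)) stop("missing genotypes are not supported; impute upstream")
  if (!all(geno %in% 0:2)) stop("genotypes must be coded 0/1/2")
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "snp_id", "bp")
  if (!all(need %in% names(map))) stop("map file must have columns chrom, snp_id, bp")
  map <- data.frame(snp_id = as.character(map$snp_id),
                    chrom = as.character(map$chrom),
                    bp = as.numeric(map$bp), p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!identical(colnames(geno), map$snp_id)) {
    stop("SNP ids in genotype header and map disagree")
  }
  .check_map_sorted(map)
  message(sprintf("read %d animals x %d SNPs", nrow(geno), ncol(geno)))
  list(geno = geno, map = map)
}

.check_map_sorted <- function(map) {
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (any(diff(bp) <= 0)) {
      stop("bp positions must be strictly increasing within chromosome ", ch)
    }
  }
  invisible(TRUE)
}

#' Write genotypes and SNP map in the package's TSV formats
#'
#' @param geno animals x SNP 0/1/2 matrix with animal ids as rownames.
#' @param map SNP map data.frame (`snp_id`, `chrom`, `bp`).
#' @param geno_path,map_path output paths.
#' @export
write_genotypes <- function(geno, map, geno_path, map_path) {
  df <- data.frame(animal = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, geno_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(map[, c("chrom", "snp_id", "bp")], map_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(geno_path)
}

#' Observed allele frequencies
#'
#' Frequency of the counted allele at each SNP, `p = mean(genotype) / 2`,
#' estimated in the genotyped sample.
#'
#' @param geno animals x SNP 0/1/2 matrix.
#' @return numeric vector of frequencies.
#' @export
allele_frequencies <- function(geno) {
  colMeans(geno) / 2
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' SNPs whose minor allele frequency `min(p, 1 - p)` is strictly below the
#' threshold are excluded; a SNP sitting exactly on the threshold is kept.
#' Observed frequencies are recorded into the returned map.
#'
#' @param geno animals x SNP 0/1/2 matrix.
#' @param map SNP map aligned with `geno` columns.
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.05.
#' @return list with filtered `geno` and `map` (map gains column `p`).
#' @export
filter_maf <- function(geno, map, threshold = 0.05) {
  if (threshold < 0 || threshold >= 0.5) stop("MAF threshold must be in [0, 0.5)")
  if (ncol(geno) != nrow(map)) stop("genotype columns and map rows disagree")
  p <- allele_frequencies(geno)
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  if (!any(keep)) stop("all SNPs removed by MAF filter")
  message(sprintf("MAF filter (%.3g): kept %d of %d SNPs", threshold,
                  sum(keep), length(keep)))
  map <- map[keep, , drop = FALSE]
  map$p <- p[keep]
  rownames(map) <- NULL
  list(geno = geno[, keep, drop = FALSE], map = map)
}

#' Center gene content by allele frequencies
#'
#' Z = genotype - 2p columnwise.  With frequencies observed in the same
#' sample the column means of Z are exactly zero.
#'
#' @param geno animals x SNP 0/1/2 matrix.
#' @param p per-SNP allele frequencies (or a map with a `p` column).
#' @return dense numeric matrix Z with the same dimnames.
#' @export
center_Z <- function(geno, p) {
  if (is.data.frame(p)) p <- p$p
  if (anyNA(p)) stop("allele frequencies missing; run filter_maf() first")
  if (length(p) != ncol(geno)) stop("frequency vector length mismatch")
  sweep(geno, 2L, 2 * p, `-`)
}

#' VanRaden normalizing constant
#'
#' lambda = 1 / sum_i 2 p_i (1 - p_i), the ratio of per-SNP to total additive
#' variance under equal SNP contributions.
#'
#' @param p per-SNP allele frequencies (or a map with a `p` column).
#' @return scalar lambda.
#' @export
compute_lambda <- function(p) {
  if (is.data.frame(p)) p <- p$p
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("degenerate allele frequencies: sum 2p(1-p) is zero")
  1 / denom
}

#' Genomic relationship matrix (VanRaden, optionally SNP-weighted)
#'
#' G = Z D Z' / sum_i 2 p_i (1 - p_i), with D a diagonal matrix of per-SNP
#' variance weights.  Unit weights give the plain VanRaden G; weighted runs
#' keep the same denominator because the weights are normalized to sum to
#' the SNP count.
#'
#' @param Zc centered gene-content matrix from [center_Z()].
#' @param p per-SNP allele frequencies (or a map with a `p` column).
#' @param weights per-SNP positive weights; default all 1.
#' @return dense symmetric `relmatrix` G over the genotyped animals.
#' @export
build_G <- function(Zc, p, weights = NULL) {
  if (is.data.frame(p)) p <- p$p
  M <- ncol(Zc)
  if (is.null(weights)) weights <- rep(1, M)
  if (length(weights) != M) stop("weights length must equal SNP count")
  if (any(weights <= 0)) stop("SNP weights must be positive")
  denom <- sum(2 * p * (1 - p))
  Zw <- sweep(Zc, 2L, weights, `*`)
  G <- tcrossprod(Zw, Zc) / denom
  G <- (G + t(G)) / 2
  relmatrix(G, rownames(Zc))
}

#' Blend G with the pedigree relationships of the genotyped animals
#'
#' G_b = alpha G + (1 - alpha) A22.  Blending guarantees invertibility when
#' there are more genotyped animals than SNPs (G alone is then singular).
#'
#' @param G genomic `relmatrix`.
#' @param A22 pedigree `relmatrix` of the same animals in the same order.
#' @param alpha weight on G in `(0, 1]`; default 0.95.
#' @return blended `relmatrix`.
#' @export
blend_G <- function(G, A22, alpha = 0.95) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  .check_same_ids(rel_ids(G), rel_ids(A22), "blend_G")
  Gb <- alpha * .rel_unwrap(G) + (1 - alpha) * as.matrix(.rel_unwrap(A22))
  relmatrix(Gb, rel_ids(G))
}

#' Single-step inverse relationship matrix H-inverse
#'
#' H-inverse = A-inverse with (G_b-inverse - A22-inverse) added into the
#' block of genotyped animals.  With no genotyped animals, or with G_b equal
#' to A22, the correction vanishes and H-inverse equals A-inverse.
#'
#' @param A_inv sparse `relmatrix` from [build_A_inverse()].
#' @param A22_inv inverse of the genotyped-block pedigree relationships
#'   (dense `relmatrix`, `is_inverse = TRUE`), or `NULL` when no animals are
#'   genotyped.
#' @param G_b_inv inverse of the (blended) genomic relationships, same order
#'   as `A22_inv`, or `NULL`.
#' @param genotyped_index integer positions of the genotyped animals within
#'   the pedigree order of `A_inv`, aligned with the rows of `A22_inv`.
#' @return sparse symmetric `relmatrix` H-inverse (`is_inverse = TRUE`).
#' @export
build_H_inverse <- function(A_inv, A22_inv = NULL, G_b_inv = NULL,
                            genotyped_index = integer(0)) {
  ids <- rel_ids(A_inv)
  n <- length(ids)
  At <- methods::as(methods::as(.rel_unwrap(A_inv), "generalMatrix"),
                    "TsparseMatrix")
  if (length(genotyped_index) == 0L) {
    H <- Matrix::sparseMatrix(i = At@i + 1L, j = At@j + 1L, x = At@x,
                              dims = c(n, n), dimnames = list(ids, ids))
    return(relmatrix(H, ids, is_inverse = TRUE))
  }
  if (is.null(A22_inv) || is.null(G_b_inv)) {
    stop("A22_inv and G_b_inv required when genotyped animals are present")
  }
  if (any(genotyped_index < 1L | genotyped_index > n)) {
    stop("genotyped_index out of range")
  }
  .check_same_ids(rel_ids(A22_inv), rel_ids(G_b_inv), "build_H_inverse")
  .check_same_ids(ids[genotyped_index], rel_ids(A22_inv), "build_H_inverse")
  delta <- as.matrix(.rel_unwrap(G_b_inv)) - as.matrix(.rel_unwrap(A22_inv))
  g <- length(genotyped_index)
  # triplet assembly: duplicate (i, j) entries are summed by sparseMatrix
  H <- Matrix::sparseMatrix(
    i = c(At@i + 1L, rep(genotyped_index, times = g)),
    j = c(At@j + 1L, rep(genotyped_index, each = g)),
    x = c(At@x, as.numeric(delta)),
    dims = c(n, n), dimnames = list(ids, ids))
  relmatrix(H, ids, is_inverse = TRUE)
}

#' Invert a symmetric positive-definite relationship matrix
#'
#' Cholesky-based inverse; fails with an informative error when the matrix
#' is not positive definite (e.g., unblended G with more animals than SNPs).
#'
#' @param M a `relmatrix`.
#' @return dense `relmatrix` with the `is_inverse` flag toggled.
#' @export
invert_relmatrix <- function(M) {
  Md <- as.matrix(.rel_unwrap(M))
  ch <- tryCatch(chol(Md), error = function(e) {
    stop("relationship matrix is not positive definite: ", conditionMessage(e))
  })
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(Md)
  relmatrix(inv, rel_ids(M), is_inverse = !is_inverse(M))
}
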