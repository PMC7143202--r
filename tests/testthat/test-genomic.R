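make_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2L, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                       each = n)]),
              n, m)
  dimnames(g) <- list(sprintf("an%03d", seq_len(n)),
                      sprintf("snp%03d", seq_len(m)))
  storage.mode(g) <- "integer"
  g
}

make_map <- function(geno, n_chrom = 2) {
  m <- ncol(geno)
  chrom <- sort(rep(seq_len(n_chrom), length.out = m))
  bp <- unlist(lapply(table(chrom), function(k) seq_len(k) * 1e6))
  data.frame(snp_id = colnames(geno), chrom = as.character(chrom),
             bp = as.numeric(bp), p = NA_real_, stringsAsFactors = FALSE)
}

test_that("MAF filter drops monomorphic SNPs, keeps the boundary, matches brute force", {
  g <- make_geno(10, 20, seed = 2)
  g[, 3] <- 0L                      # monomorphic: p = 0
  g[, 7] <- c(1L, rep(0L, 9))      # p = 0.05 exactly: boundary kept
  map <- make_map(g)
  flt <- filter_maf(g, map, 0.05)
  expect_false("snp003" %in% colnames(flt$geno))
  expect_true("snp007" %in% colnames(flt$geno))

  # oracle: per-column frequency computed directly
  p <- apply(g, 2, function(col) mean(col) / 2)
  keep <- pmin(p, 1 - p) >= 0.05
  expect_identical(colnames(flt$geno), colnames(g)[keep])
  expect_equal(flt$map$p, unname(p[keep]))

  expect_error(filter_maf(g, map, 0.6), "threshold")
  expect_error(filter_maf(matrix(0L, 5, 2,
                                 dimnames = list(NULL, c("a", "b"))),
                          data.frame(snp_id = c("a", "b"),
                                     chrom = "1", bp = c(1, 2)),
                          0.05),
               "all SNPs removed")
})

test_that("centering subtracts twice the allele frequency", {
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("x", "y"), "s1"))
  expect_equal(as.numeric(center_Z(g, 0.5)), c(-1, 1))

  g2 <- make_geno(15, 8, seed = 3)
  p <- colMeans(g2) / 2
  Zc <- center_Z(g2, p)
  expect_equal(colMeans(Zc), rep(0, 8), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(Zc, sweep(g2, 2, 2 * p), ignore_attr = TRUE)
})

test_that("VanRaden lambda is the reciprocal heterozygosity sum", {
  expect_equal(compute_lambda(0.5), 2.0)
  expect_equal(compute_lambda(c(0.5, 0.5)), 1.0)
  expect_equal(compute_lambda(c(0.1, 0.2, 0.3)), 1 / 0.92)
})

test_that("G matches hand arithmetic and is linear in the weights", {
  Zc <- matrix(c(-1, 1), 2, 1, dimnames = list(c("x", "y"), "s1"))
  G <- build_G(Zc, 0.5)
  expect_equal(as.matrix(G), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  G2 <- build_G(Zc, 0.5, weights = 2)
  expect_equal(as.matrix(G2), 2 * as.matrix(G))
})

test_that("G with unit weights is invariant to allele relabeling", {
  g <- make_geno(12, 10, seed = 4)
  p <- colMeans(g) / 2
  G1 <- build_G(center_Z(g, p), p)
  flip <- c(2, 5)
  g2 <- g
  g2[, flip] <- 2L - g2[, flip]
  p2 <- p
  p2[flip] <- 1 - p2[flip]
  G2 <- build_G(center_Z(g2, p2), p2)
  expect_equal(as.matrix(G1), as.matrix(G2), tolerance = 1e-12)
})

test_that("mean diagonal of G tracks 1 + mean inbreeding on simulated data", {
  sim <- small_sim()
  flt <- filter_maf(sim$geno_all, sim$map, 0)
  # centering with founder frequencies gives the pedigree expectation
  pf <- sim$map$founder_p[match(flt$map$snp_id, sim$map$snp_id)]
  G <- build_G(center_Z(flt$geno, pf), pf)
  Fbar <- mean(compute_inbreeding(sim$ped))
  expect_equal(mean(diag(as.matrix(G))), 1 + Fbar, tolerance = 0.05)
})

test_that("blending restores invertibility and keeps the A22 fixed point", {
  sim <- small_sim()
  ids <- sim$genotyped_ids[1:40]
  A22 <- subset_A22(sim$ped, ids)
  flt <- filter_maf(sim$geno_all[ids, 21:35], sim$map[21:35, ], 0)
  G <- build_G(center_Z(flt$geno, flt$map), flt$map)  # 40 animals, <=15 SNPs: singular
  expect_error(invert_relmatrix(G), "not positive definite")
  Gb <- blend_G(G, A22, alpha = 0.95)
  expect_no_error(invert_relmatrix(Gb))

  expect_equal(as.matrix(blend_G(A22, A22, 0.95)), as.matrix(A22))
  expect_equal(as.matrix(blend_G(G, A22, 1)), as.matrix(G))
  expect_error(blend_G(G, subset_A22(sim$ped, rev(ids)), 0.95), "mismatch")
})

test_that("H-inverse reduces to A-inverse in both degenerate cases", {
  ped <- random_pedigree(30, seed = 6)
  A_inv <- build_A_inverse(ped)
  # no genotyped animals
  H0 <- build_H_inverse(A_inv)
  expect_equal(as.matrix(H0), as.matrix(A_inv), tolerance = 1e-12)
  # all animals genotyped with G = A22 (= A): correction cancels
  A22 <- subset_A22(ped, ped$id)
  A22_inv <- invert_relmatrix(A22)
  H1 <- build_H_inverse(A_inv, A22_inv, A22_inv, seq_len(ped$n))
  expect_equal(as.matrix(H1), as.matrix(A_inv), tolerance = 1e-8)
})

test_that("H agrees with the joint-density oracle in the mixed case", {
  sim <- small_sim()
  ped <- sim$ped
  ids <- sim$genotyped_ids[1:20]
  idx <- ped_index(ped, ids)
  flt <- filter_maf(sim$geno_all[ids, ], sim$map, 0.05)
  A22 <- subset_A22(ped, ids)
  G <- blend_G(build_G(center_Z(flt$geno, flt$map), flt$map), A22, 0.95)
  A_inv <- build_A_inverse(ped)
  H_inv <- build_H_inverse(A_inv, invert_relmatrix(A22),
                           invert_relmatrix(G), idx)
  H <- solve(as.matrix(H_inv))

  # oracle: H = [[A11 + A12 A22i (G - A22) A22i A21, A12 A22i G],
  #              [G A22i A21, G]] on the (ungenotyped, genotyped) split
  A <- as.matrix(build_A_tabular(ped))
  n1 <- setdiff(seq_len(ped$n), idx)
  A11 <- A[n1, n1]; A12 <- A[n1, idx]; A22d <- A[idx, idx]
  A22i <- solve(A22d)
  Gd <- as.matrix(G)
  Ho <- matrix(0, ped$n, ped$n)
  Ho[n1, n1] <- A11 + A12 %*% A22i %*% (Gd - A22d) %*% A22i %*% t(A12)
  Ho[n1, idx] <- A12 %*% A22i %*% Gd
  Ho[idx, n1] <- t(Ho[n1, idx])
  Ho[idx, idx] <- Gd
  expect_equal(H, Ho, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("genotype TSVs round-trip through write/read", {
  g <- make_geno(8, 6, seed = 9)
  map <- make_map(g)
  gf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, map, gf, mf)
  back <- read_genotypes(gf, mf)
  expect_equal(back$geno, g, ignore_attr = FALSE)
  expect_equal(back$map$bp, map$bp)
  expect_equal(back$map$snp_id, map$snp_id)
})
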