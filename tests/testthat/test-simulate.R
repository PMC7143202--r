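test_that("pedigree generator respects structure and determinism", {
  # founders only
  cfg0 <- sim_config(n_founders = 2, n_generations = 0, n_snp = 10)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(ped0$n, 2L)
  expect_true(all(ped0$sire == 0L & ped0$dam == 0L))

  # every non-founder has two known parents from an earlier generation
  cfg <- sim_config(n_founders = 10, n_generations = 3, litter_rate = 2,
                    n_snp = 10, seed = 4)
  ped <- simulate_pedigree(cfg)
  nonf <- which(ped$generation > 0)
  expect_true(all(ped$sire[nonf] > 0 & ped$dam[nonf] > 0))
  expect_true(all(ped$generation[ped$sire[nonf]] <
                    ped$generation[nonf]))

  # identical config: byte-identical pedigree
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)
})

test_that("gene dropping respects inheritance and Hardy-Weinberg sampling", {
  # founders only: genotype mean ~ 2p within 4 standard errors
  cfg <- sim_config(n_founders = 300, n_generations = 0, n_snp = 40,
                    n_chromosomes = 2, seed = 6)
  ped <- simulate_pedigree(cfg)
  gg <- simulate_genotypes(ped, cfg)
  p <- gg$map$founder_p
  se <- sqrt(2 * p * (1 - p) / 300)
  expect_true(all(abs(colMeans(gg$geno) - 2 * p) < 4 * se + 1e-9))
  # map sorted within chromosome
  for (ch in unique(gg$map$chrom)) {
    expect_true(all(diff(gg$map$bp[gg$map$chrom == ch]) > 0))
  }

  # no mutation: offspring of two homozygous-reference parents is 0
  sim <- small_sim()
  ped <- sim$ped; G <- sim$geno_all
  off <- which(ped$sire > 0 & ped$dam > 0)
  both0 <- G[ped$sire[off], , drop = FALSE] == 0L &
    G[ped$dam[off], , drop = FALSE] == 0L
  expect_true(all(G[off, , drop = FALSE][both0] == 0L))
  # and offspring dosage never exceeds what the parents can transmit
  both2 <- G[ped$sire[off], , drop = FALSE] == 2L &
    G[ped$dam[off], , drop = FALSE] == 2L
  expect_true(all(G[off, , drop = FALSE][both2] == 2L))
})

test_that("parent-offspring genomic relationship approaches the pedigree 0.5", {
  cfg <- sim_config(n_founders = 60, n_generations = 1, litter_rate = 2,
                    n_snp = 1500, n_chromosomes = 5, seed = 13)
  ped <- simulate_pedigree(cfg)
  gg <- simulate_genotypes(ped, cfg)
  pf <- gg$map$founder_p
  Zc <- center_Z(gg$geno, pf)
  G <- as.matrix(build_G(Zc, pf))
  off <- which(ped$sire > 0)
  rel <- G[cbind(off, ped$sire[off])]
  expect_equal(mean(rel), 0.5, tolerance = 0.05)
})

test_that("polygenic breeding values carry the pedigree covariance", {
  rels <- c()
  for (seed in 1:5) {
    cfg <- sim_config(n_founders = 120, n_generations = 2, litter_rate = 2,
                      n_snp = 10, qtl_variance_fraction = 0, seed = 700 + seed)
    ped <- simulate_pedigree(cfg)
    gg <- simulate_genotypes(ped, cfg)
    tr <- simulate_phenotypes(ped, gg$geno, cfg)$truth
    off <- which(ped$sire > 0)
    rels <- c(rels, cov(tr$tbv[off], tr$tbv[ped$sire[off]]) /
                var(tr$tbv))
  }
  expect_equal(mean(rels), 0.5, tolerance = 0.1)
})

test_that("pure-residual phenotypes have residual variance within cells", {
  cfg <- sim_config(n_founders = 400, n_generations = 1, litter_rate = 2,
                    n_snp = 10, sigma_a2 = 0, sigma_pe2 = 0,
                    sigma_e2 = 900, qtl_variance_fraction = 0,
                    n_herds = 1, n_years = 1, n_seasons = 1,
                    n_countries = 2, trait_bounds = c(100, 700),
                    hys_sd = 0, country_sd = 0, b_age = c(0, 0),
                    seed = 21)
  sim <- simulate_dataset(cfg)
  expect_equal(var(sim$pheno$y), 900, tolerance = 0.2 * 900)
})

test_that("phenotypes respect bounds, cell sizes, and record structure", {
  sim <- small_sim()
  expect_true(all(sim$pheno$y >= 270 & sim$pheno$y <= 700))
  expect_true(all(table(sim$pheno$hys) >= 3))
  expect_false(anyDuplicated(sim$pheno$animal) > 0)  # primiparous

  cfg <- sim_config(n_founders = 60, n_generations = 2, n_snp = 50,
                    seed = 31)
  multi <- simulate_dataset(cfg, kind = "multiparous")
  reps <- table(multi$pheno$animal)
  expect_true(all(reps >= 2 & reps <= 4))
  expect_true(all(multi$pheno$parity >= 2))
})

test_that("generator configuration errors are explicit", {
  expect_error(sim_config(n_founders = 1), "founders")
  expect_error(sim_config(qtl_variance_fraction = 1.2), "qtl_variance")
  expect_error(sim_config(trait_bounds = c(700, 270)), "lower < upper")
  expect_error(sim_config(genotyping_fraction = 0), "genotyping_fraction")
  cfg <- sim_config(n_founders = 20, n_generations = 1, n_snp = 20,
                    sigma_a2 = 0, qtl_variance_fraction = 0.5, seed = 2)
  ped <- simulate_pedigree(cfg)
  gg <- simulate_genotypes(ped, cfg)
  expect_error(simulate_phenotypes(ped, gg$geno, cfg), "sigma_a2 > 0")
})

test_that("whole data sets are reproducible and written files round-trip", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_snp = 60,
                    n_chromosomes = 2, seed = 55)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$qtl_indices, s2$truth$qtl_indices)

  dir <- withr::local_tempdir()
  write_simulation(s1, dir)
  ped_back <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_identical(ped_back$id, s1$ped$id)
  geno_back <- read_genotypes(file.path(dir, "genotypes.tsv"),
                              file.path(dir, "snp_map.tsv"))
  expect_equal(geno_back$geno, s1$geno, ignore_attr = FALSE)
  ph_back <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(ph_back$y, s1$pheno$y)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$realized_h2, s1$truth$realized_h2, tolerance = 1e-12)
})
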