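#' Simulation configuration
#'
#' Collects every parameter of the synthetic livestock generator.  Defaults
#' emulate the data structure of a multi-country dairy fertility
#' evaluation: a low-heritability interval trait (default generating
#' variances sigma_a2 = 201.3, sigma_pe2 = 71.4, sigma_e2 = 3728.7, i.e.
#' h2 of about 0.05) recorded on cows distributed over herds within four
#' countries, with calving intervals restricted to 270-700 days, a minority
#' of pedigreed animals genotyped, and a handful of true QTL hidden among
#' neutral SNPs.
#'
#' @param n_founders number of founder animals (half of each sex).
#' @param n_generations number of descendant generations.
#' @param litter_rate expected offspring per dam per generation.
#' @param n_sires number of breeding males used per generation, emulating
#'   artificial-insemination usage in dairy populations: a small sire pool
#'   produces the large paternal half-sib families that carry most of the
#'   information about additive variance in cattle data.
#' @param n_snp total SNP count across the genome.
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_bp physical length per chromosome (bp).
#' @param qtl_count number of causal SNPs.
#' @param qtl_variance_fraction fraction of the additive variance assigned
#'   to the explicit QTL (the rest is polygenic).
#' @param sigma_a2,sigma_pe2,sigma_e2 generating variance components
#'   (trait units squared, days^2).
#' @param n_herds,n_years,n_seasons,n_countries fixed-effect structure.
#' @param genotyping_fraction fraction of non-founder animals genotyped.
#' @param trait_bounds closed interval (days) phenotypes must fall in.
#' @param bound_mode `"resample"` redraws the residual until the record is
#'   in bounds (keeps the linear model exact); `"truncate"` clips.
#' @param mu overall trait mean (days).
#' @param hys_sd,country_sd,parity_sd standard deviations of the simulated
#'   fixed-effect levels (days).
#' @param age_range age at first calving range (months), drawn uniformly.
#' @param b_age linear and quadratic regressions of the trait on centered
#'   age (days/month, days/month^2).
#' @param seed integer RNG seed; stage s of the generator seeds the RNG
#'   with `seed + s` so runs are reproducible end to end.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 3, litter_rate = 2,
                       n_sires = 30,
                       n_snp = 2000, n_chromosomes = 5,
                       chromosome_length_bp = 1e8,
                       qtl_count = 5, qtl_variance_fraction = 0.4,
                       sigma_a2 = 201.3, sigma_pe2 = 71.4,
                       sigma_e2 = 3728.7,
                       n_herds = 8, n_years = 3, n_seasons = 4,
                       n_countries = 4, genotyping_fraction = 0.6,
                       trait_bounds = c(270, 700),
                       bound_mode = c("resample", "truncate"),
                       mu = 400, hys_sd = 15, country_sd = 10,
                       parity_sd = 8, age_range = c(22, 36),
                       b_age = c(1.2, 0.08), seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              litter_rate = litter_rate, n_sires = as.integer(n_sires),
              n_snp = as.integer(n_snp),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              qtl_count = as.integer(qtl_count),
              qtl_variance_fraction = qtl_variance_fraction,
              sigma_a2 = sigma_a2, sigma_pe2 = sigma_pe2,
              sigma_e2 = sigma_e2, n_herds = as.integer(n_herds),
              n_years = as.integer(n_years),
              n_seasons = as.integer(n_seasons),
              n_countries = as.integer(n_countries),
              genotyping_fraction = genotyping_fraction,
              trait_bounds = trait_bounds,
              bound_mode = match.arg(bound_mode), mu = mu,
              hys_sd = hys_sd, country_sd = country_sd,
              parity_sd = parity_sd, age_range = age_range,
              b_age = b_age, seed = as.integer(seed))
  if (cfg$n_founders < 2) stop("need at least 2 founders")
  if (cfg$sigma_a2 < 0 || cfg$sigma_pe2 < 0 || cfg$sigma_e2 < 0) {
    stop("variances must be non-negative")
  }
  if (cfg$qtl_variance_fraction < 0 || cfg$qtl_variance_fraction > 1) {
    stop("qtl_variance_fraction must lie in [0, 1]")
  }
  if (cfg$genotyping_fraction <= 0 || cfg$genotyping_fraction > 1) {
    stop("genotyping_fraction must lie in (0, 1]")
  }
  if (cfg$trait_bounds[1L] >= cfg$trait_bounds[2L]) {
    stop("trait_bounds must satisfy lower < upper")
  }
  if (cfg$qtl_count > cfg$n_snp) stop("more QTL than SNPs")
  if (cfg$n_sires < 1) stop("need at least one sire per generation")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0, half male, half female) are followed by
#' `n_generations` of offspring: every female of the previous generation
#' produces around `litter_rate` offspring, each by a male drawn from a
#' pool of at most `n_sires` breeding males of the previous generation
#' (falling back to older males if a generation has none), mimicking
#' artificial-insemination sire usage.  Offspring sex is random, with at
#' least one of each sex forced per generation so matings remain possible.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] with `sex` and `generation` metadata.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  id <- sprintf("F%03d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  sire <- rep("0", nf)
  dam <- rep("0", nf)
  gen <- rep(0L, nf)
  prev_ids <- id
  prev_sex <- sex
  for (g in seq_len(cfg$n_generations)) {
    dams <- prev_ids[prev_sex == "F"]
    males <- prev_ids[prev_sex == "M"]
    if (length(males) == 0L) males <- id[sex == "M"]
    if (length(males) > cfg$n_sires) males <- sample(males, cfg$n_sires)
    if (length(males) == 0L || length(dams) == 0L) {
      stop("impossible configuration: no ",
           if (length(males) == 0L) "males" else "females",
           " available for generation ", g)
    }
    n_off_per_dam <- floor(cfg$litter_rate) +
      stats::rbinom(length(dams), 1L, cfg$litter_rate - floor(cfg$litter_rate))
    n_off <- sum(n_off_per_dam)
    if (n_off == 0L) stop("impossible configuration: litter_rate produces no offspring")
    off_dam <- rep(dams, n_off_per_dam)
    off_sire <- sample(males, n_off, replace = TRUE)
    off_sex <- sample(c("M", "F"), n_off, replace = TRUE)
    if (!any(off_sex == "M")) off_sex[1L] <- "M"
    if (!any(off_sex == "F")) off_sex[min(2L, n_off)] <- "F"
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    sex <- c(sex, off_sex); gen <- c(gen, rep(g, n_off))
    prev_ids <- off_id
    prev_sex <- off_sex
  }
  pedigree(id, sire, dam, sex = sex, generation = gen)
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn per SNP from allele frequencies
#' Uniform(0.05, 0.95); each offspring receives one recombinant gamete per
#' parent, with crossover probabilities between adjacent SNPs from
#' Haldane's map function at 1 cM per Mb, and independent segregation
#' across chromosomes.  There is no mutation, so every allele is traceable
#' to a founder allele.
#'
#' @param ped a topologically ordered [pedigree()].
#' @param cfg a [sim_config()].
#' @return list `geno` (animals x SNP 0/1/2 integer matrix over all
#'   pedigree animals), `map` (data.frame `snp_id`, `chrom`, `bp`,
#'   `founder_p`, `p = NA`).
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  M <- cfg$n_snp
  per_chr <- diff(round(seq(0, M, length.out = cfg$n_chromosomes + 1L)))
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per_chr)
  bp <- unlist(lapply(per_chr, function(m) {
    sort(sample.int(cfg$chromosome_length_bp, m))
  }))
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(M)), chrom = chrom,
                    bp = as.numeric(bp),
                    founder_p = stats::runif(M, 0.05, 0.95), p = NA_real_,
                    stringsAsFactors = FALSE)
  # per-SNP haplotype switch probability: 0.5 at each chromosome start
  # (random starting haplotype, independent chromosomes), Haldane
  # recombination fraction within chromosomes at 1 cM/Mb.
  switch_p <- numeric(M)
  pos <- 0L
  for (m in per_chr) {
    j <- pos + seq_len(m)
    d_morgan <- diff(map$bp[j]) * 1e-8
    switch_p[j] <- c(0.5, 0.5 * (1 - exp(-2 * d_morgan)))
    pos <- pos + m
  }
  n <- ped$n
  H1 <- matrix(0L, n, M)
  H2 <- matrix(0L, n, M)
  pfound <- map$founder_p
  gamete <- function(hA, hB) {
    phase <- cumsum(stats::rbinom(M, 1L, switch_p)) %% 2L
    ifelse(phase == 0L, hA, hB)
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    H1[i, ] <- if (s > 0L) gamete(H1[s, ], H2[s, ]) else
      stats::rbinom(M, 1L, pfound)
    H2[i, ] <- if (d > 0L) gamete(H1[d, ], H2[d, ]) else
      stats::rbinom(M, 1L, pfound)
  }
  geno <- H1 + H2
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(ped$id, map$snp_id)
  list(geno = geno, map = map)
}

#' Simulate phenotypes with known truth
#'
#' True breeding values are the sum of an explicit QTL part (allele
#' substitution effects on centered gene content, rescaled so the QTL
#' explain `qtl_variance_fraction` of `sigma_a2`) and a polygenic part
#' dropped down the pedigree with Mendelian-sampling variances that account
#' for parental inbreeding.  Records are assigned herd-year-season cells
#' (merged until every cell holds at least 3 records so the fixed effects
#' stay estimable), country (crossed with herd so both stay estimable
#' under reference-level constraints), parity for the repeatability
#' model, and an age-at-first-calving covariate acting through centered
#' linear and quadratic regressions.  Records falling outside
#' `trait_bounds` are re-drawn (or truncated, per config).
#'
#' Phenotyped animals are the non-founder females ("cows").
#'
#' @param ped a [pedigree()] with `sex` metadata.
#' @param geno genotype matrix over all pedigree animals.
#' @param cfg a [sim_config()].
#' @param kind `"primiparous"` (one record per cow) or `"multiparous"`
#'   (2-4 records per cow with a permanent-environment effect).
#' @return list `pheno` (data.frame `animal`, `y`, `herd`, `year`,
#'   `season`, `hys`, `country`, `parity`, `age`) and `truth` (list
#'   `tbv`, `qtl_indices`, `qtl_effects`, `true_variance_components`,
#'   `realized_h2`).
#' @export
simulate_phenotypes <- function(ped, geno, cfg,
                                kind = c("primiparous", "multiparous")) {
  kind <- match.arg(kind)
  if (is.null(ped$sex)) stop("pedigree lacks sex metadata")
  if (nrow(geno) != ped$n) stop("genotypes must cover all pedigree animals")
  set.seed(cfg$seed + 2L)
  n <- ped$n
  # --- true breeding values -------------------------------------------------
  qtl_idx <- integer(0)
  qtl_eff <- numeric(0)
  qg <- numeric(n)
  if (cfg$qtl_count > 0L && cfg$qtl_variance_fraction > 0) {
    if (cfg$sigma_a2 == 0) {
      stop("qtl_variance_fraction > 0 requires sigma_a2 > 0")
    }
    qtl_idx <- sort(sample.int(ncol(geno), cfg$qtl_count))
    beta <- stats::rnorm(cfg$qtl_count)
    Zq <- scale(geno[, qtl_idx, drop = FALSE], center = TRUE, scale = FALSE)
    raw <- as.numeric(Zq %*% beta)
    v <- mean(raw^2) - mean(raw)^2
    if (v <= 0) stop("degenerate QTL genotypes; increase founder diversity")
    sc <- sqrt(cfg$qtl_variance_fraction * cfg$sigma_a2 / v)
    beta <- beta * sc
    qg <- raw * sc
    qtl_eff <- beta
  }
  sigma_poly <- (1 - cfg$qtl_variance_fraction) * cfg$sigma_a2
  poly <- numeric(n)
  if (sigma_poly > 0) {
    F <- compute_inbreeding(ped)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      pa <- 0
      if (s > 0L) pa <- pa + 0.5 * poly[s]
      if (d > 0L) pa <- pa + 0.5 * poly[d]
      dms <- .mendelian_variance(s, d, F)
      poly[i] <- pa + stats::rnorm(1L, 0, sqrt(dms * sigma_poly))
    }
  }
  tbv <- stats::setNames(qg + poly, ped$id)
  # --- record structure -----------------------------------------------------
  cows <- which(ped$sex == "F" & (ped$sire > 0L | ped$dam > 0L))
  if (length(cows) == 0L) stop("no non-founder females to phenotype")
  n_rec_per_cow <- if (kind == "primiparous") rep(1L, length(cows)) else
    sample(2:4, length(cows), replace = TRUE)
  rec_cow <- rep(cows, n_rec_per_cow)
  nrec <- length(rec_cow)
  herd_of_cow <- sample.int(cfg$n_herds, length(cows), replace = TRUE)
  # country is drawn per cow, crossed with herd, so that the country
  # effect stays estimable next to the herd-year-season effect under
  # reference-level constraints (full nesting would alias the two).
  country_of_cow <- sample.int(cfg$n_countries, length(cows),
                               replace = TRUE)
  herd <- rep(herd_of_cow, n_rec_per_cow)
  parity <- if (kind == "primiparous") rep(1L, nrec) else
    unlist(lapply(n_rec_per_cow, function(k) 1L + seq_len(k)))
  year <- sample.int(cfg$n_years, nrec, replace = TRUE)
  season <- sample.int(cfg$n_seasons, nrec, replace = TRUE)
  hys <- .merge_small_hys(herd, year, season, min_size = 3L)
  # --- effects --------------------------------------------------------------
  hys_levels <- unique(hys)
  hys_eff <- stats::setNames(stats::rnorm(length(hys_levels), 0, cfg$hys_sd),
                             hys_levels)
  country <- rep(country_of_cow, n_rec_per_cow)
  country_eff <- stats::rnorm(cfg$n_countries, 0, cfg$country_sd)
  parity_eff <- stats::rnorm(max(parity), 0, cfg$parity_sd)
  age_of_cow <- stats::runif(length(cows), cfg$age_range[1L],
                             cfg$age_range[2L])
  age <- rep(age_of_cow, n_rec_per_cow)
  age_c <- age - mean(age)
  pe_of_cow <- if (kind == "multiparous" && cfg$sigma_pe2 > 0) {
    stats::rnorm(length(cows), 0, sqrt(cfg$sigma_pe2))
  } else {
    numeric(length(cows))
  }
  pe <- rep(pe_of_cow, n_rec_per_cow)
  fixed_part <- cfg$mu + hys_eff[hys] + country_eff[country] +
    parity_eff[parity] * (kind == "multiparous") +
    cfg$b_age[1L] * age_c + cfg$b_age[2L] * age_c^2
  base <- as.numeric(fixed_part) + tbv[rec_cow] + pe
  e <- stats::rnorm(nrec, 0, sqrt(cfg$sigma_e2))
  y <- base + e
  lo <- cfg$trait_bounds[1L]; hi <- cfg$trait_bounds[2L]
  if (cfg$bound_mode == "resample") {
    for (tries in seq_len(200L)) {
      out <- which(y < lo | y > hi)
      if (length(out) == 0L) break
      e[out] <- stats::rnorm(length(out), 0, sqrt(cfg$sigma_e2))
      y[out] <- base[out] + e[out]
    }
    y <- pmin(pmax(y, lo), hi)  # safeguard for pathological cells
  } else {
    y <- pmin(pmax(y, lo), hi)
  }
  pheno <- data.frame(animal = ped$id[rec_cow], y = y, herd = herd,
                      year = year, season = season, hys = hys,
                      country = country, parity = parity, age = age,
                      stringsAsFactors = FALSE)
  resid <- tbv[rec_cow] + pe + (y - base)
  vt <- mean(tbv[rec_cow]^2) - mean(tbv[rec_cow])^2
  vr <- mean(resid^2) - mean(resid)^2
  truth <- list(
    tbv = tbv,
    qtl_indices = qtl_idx,
    qtl_effects = qtl_eff,
    true_variance_components = list(sigma_a2 = cfg$sigma_a2,
                                    sigma_pe2 = cfg$sigma_pe2,
                                    sigma_e2 = cfg$sigma_e2),
    realized_h2 = vt / vr
  )
  list(pheno = pheno, truth = truth)
}

# Build herd-year-season contemporary groups of at least min_size records:
# within each herd, year-season cells (in calendar order) are combined
# greedily until each group reaches the minimum; herds too small to host a
# group on their own are pooled across herds the same way.
.merge_small_hys <- function(herd, year, season, min_size = 3L) {
  hys <- rep(NA_character_, length(herd))
  leftovers <- integer(0)
  for (h in unique(herd)) {
    rows <- which(herd == h)
    if (length(rows) < min_size) {
      leftovers <- c(leftovers, rows)
      next
    }
    ord <- rows[order(year[rows], season[rows])]
    cell <- paste(year[ord], season[ord])
    sizes <- rle(cell)$lengths
    grp <- integer(0)
    g <- 1L
    acc <- 0L
    for (k in sizes) {
      grp <- c(grp, rep(g, k))
      acc <- acc + k
      if (acc >= min_size) {
        g <- g + 1L
        acc <- 0L
      }
    }
    if (acc > 0L && acc < min_size) grp[grp == g] <- g - 1L
    hys[ord] <- sprintf("h%s_g%d", h, grp)
  }
  if (length(leftovers)) {
    ord <- leftovers[order(year[leftovers], season[leftovers])]
    grp <- pmin((seq_along(ord) - 1L) %/% min_size + 1L,
                max(1L, length(ord) %/% min_size))
    hys[ord] <- sprintf("pool_g%d", grp)
  }
  hys
}

#' Simulate a complete data set with truth
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()], then samples the genotyped subset: a fraction
#' of the non-founder animals, preferring phenotyped cows first (the
#' animals a breeding program genotypes), topped up with other non-founders.
#'
#' @param cfg a [sim_config()].
#' @param kind passed to [simulate_phenotypes()].
#' @return list `ped`, `geno_all` (all animals), `geno` (genotyped subset),
#'   `map`, `pheno`, `truth`, `genotyped_ids`, `cfg`.
#' @export
simulate_dataset <- function(cfg, kind = c("primiparous", "multiparous")) {
  kind <- match.arg(kind)
  ped <- simulate_pedigree(cfg)
  gg <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, gg$geno, cfg, kind = kind)
  set.seed(cfg$seed + 3L)
  nonfounders <- ped$id[ped$sire > 0L | ped$dam > 0L]
  n_geno <- max(1L, round(cfg$genotyping_fraction * length(nonfounders)))
  phenotyped <- unique(ph$pheno$animal)
  pool1 <- intersect(nonfounders, phenotyped)
  pool2 <- setdiff(nonfounders, phenotyped)
  genotyped_ids <- if (n_geno <= length(pool1)) {
    sample(pool1, n_geno)
  } else {
    c(pool1, sample(pool2, min(n_geno - length(pool1), length(pool2))))
  }
  genotyped_ids <- ped$id[sort(ped_index(ped, genotyped_ids))]
  list(ped = ped, geno_all = gg$geno,
       geno = gg$geno[genotyped_ids, , drop = FALSE], map = gg$map,
       pheno = ph$pheno, truth = ph$truth, genotyped_ids = genotyped_ids,
       cfg = cfg)
}

#' Write a simulated data set to plain-text files
#'
#' Emits the pedigree CSV, genotype + map TSVs (genotyped subset),
#' phenotype CSV and a truth JSON into a directory.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(sim$ped, file.path(dir, "pedigree.csv"))
  write_genotypes(sim$geno, sim$map, file.path(dir, "genotypes.tsv"),
                  file.path(dir, "snp_map.tsv"))
  utils::write.csv(sim$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$tbv <- as.list(truth$tbv)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phenotype CSV
#'
#' Expects the column layout written by [write_simulation()]: `animal`,
#' `y`, `hys`, `country`, `age` and optionally `herd`, `year`, `season`,
#' `parity`.
#'
#' @param path file path.
#' @return phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "y", "hys", "country", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file lacks columns: ",
                         paste(miss, collapse = ", "))
  df$animal <- as.character(df$animal)
  df
}
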