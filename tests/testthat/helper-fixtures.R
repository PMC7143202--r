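# Shared fixtures and independent oracles for the test suite.

# Random valid pedigree with overlapping generations, single-known-parent
# animals, and the occasional inbred mating; exercises the relationship
# machinery harder than the structured generator does.
random_pedigree <- function(n, n_founders = max(4L, round(n / 5)),
                            seed = 1) {
  set.seed(seed)
  id <- sprintf("a%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- seq_len(i - 1L)
    pair <- sample(pool, 2L)
    sire[i] <- id[pair[1L]]
    if (stats::runif(1) < 0.9) dam[i] <- id[pair[2L]]  # 10% unknown dams
  }
  pedigree(id, sire, dam)
}

# Dense GLS/BLUP oracle: solves the mixed model through the record-level
# covariance V = Za K Za' sa2 + Zp Zp' spe2 + I se2 by direct inversion.
gls_oracle <- function(design, K, vc) {
  y <- design$y
  X <- design$X
  Za <- as.matrix(design$Z_a)
  V <- vc$sigma_a2 * (Za %*% K %*% t(Za))
  if (!is.null(design$Z_pe)) {
    Zp <- as.matrix(design$Z_pe)
    V <- V + vc$sigma_pe2 * tcrossprod(Zp)
  }
  diag(V) <- diag(V) + vc$sigma_e2
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% b
  a <- vc$sigma_a2 * K %*% t(Za) %*% Vi %*% resid
  list(fixed = as.numeric(b), ebv = as.numeric(a))
}

# Small deterministic trio pedigree used across tests.
trio_pedigree <- function() {
  pedigree(c("sire", "dam", "off"), c(NA, NA, "sire"), c(NA, NA, "dam"))
}

# Random phenotype table over the cows of a simulated data set, or a
# hand-rolled one over arbitrary animals for design-matrix tests.
toy_phenotypes <- function(ped, animals, seed = 1, n_hys = 3,
                           n_country = 2) {
  set.seed(seed)
  n <- length(animals)
  data.frame(
    animal = animals,
    y = stats::rnorm(n, 400, 20),
    hys = sample(sprintf("hys%d", seq_len(n_hys)), n, replace = TRUE),
    country = sample(sprintf("c%d", seq_len(n_country)), n, replace = TRUE),
    age = stats::runif(n, 22, 36),
    stringsAsFactors = FALSE
  )
}

# Small simulated data set reused by several files (cheap to build).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = 60, n_generations = 3, litter_rate = 2,
                        n_snp = 300, n_chromosomes = 3,
                        qtl_variance_fraction = 0.5, seed = 42)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
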