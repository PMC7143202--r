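toy_scan_data <- function(n_animals = 15, m = 24, seed = 2) {
  set.seed(seed)
  Zc <- matrix(rnorm(n_animals * m), n_animals, m,
               dimnames = list(sprintf("an%d", seq_len(n_animals)),
                               sprintf("s%d", seq_len(m))))
  map <- data.frame(snp_id = colnames(Zc),
                    chrom = rep(c("1", "2"), each = m / 2),
                    bp = as.numeric(rep(seq_len(m / 2) * 1e5, 2)),
                    p = runif(m, 0.1, 0.9), stringsAsFactors = FALSE)
  list(Zc = Zc, map = map, u = rnorm(m, 0, 0.1))
}

test_that("window variances match a brute-force loop over animals", {
  d <- toy_scan_data()
  ws <- window_scan(d$u, d$Zc, d$map, sigma_a2 = 2,
                    window_sizes = c(1, 5))
  # no window spans two chromosomes
  expect_true(all(d$map$chrom[ws$first_snp] == d$map$chrom[ws$last_snp]))
  # brute force every window
  for (i in seq_len(nrow(ws))) {
    idx <- ws$first_snp[i]:ws$last_snp[i]
    vals <- vapply(seq_len(nrow(d$Zc)),
                   function(a) sum(d$Zc[a, idx] * d$u[idx]), numeric(1))
    v <- mean(vals^2) - mean(vals)^2
    expect_equal(ws$pct_var[i], 100 * v / 2, tolerance = 1e-10)
  }
  # expected window counts: full-width windows only, per chromosome
  expect_equal(sum(ws$n_snp == 1), 24)
  expect_equal(sum(ws$n_snp == 5), 2 * (12 - 5 + 1))

  # non-overlapping ("distinct") mode advances by the window width
  wd <- window_scan(d$u, d$Zc, d$map, sigma_a2 = 2, window_sizes = 5,
                    sliding = FALSE)
  expect_equal(nrow(wd), 2 * 2)  # floor((12 - 5)/5) + 1 per chromosome
  expect_true(all(wd$first_snp %in% ws$first_snp))
})

test_that("zero effects give zero percent everywhere; bad inputs error", {
  d <- toy_scan_data()
  ws <- window_scan(rep(0, 24), d$Zc, d$map, sigma_a2 = 2,
                    window_sizes = 5)
  expect_true(all(ws$pct_var == 0))
  expect_error(window_scan(d$u, d$Zc, d$map, sigma_a2 = 0), "sigma_a2")
  expect_error(window_scan(d$u, d$Zc, d$map, 2, window_sizes = 30),
               "window sizes")
})

test_that("window variance adds over SNPs only when columns are orthogonal", {
  # orthogonal columns: variance of the sum is the sum of variances
  Zo <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) * 2
  rownames(Zo) <- sprintf("a%d", 1:4)
  colnames(Zo) <- c("s1", "s2")
  map <- data.frame(snp_id = c("s1", "s2"), chrom = "1", bp = c(1e5, 2e5),
                    p = c(0.5, 0.5))
  u <- c(0.3, -0.2)
  ws <- window_scan(u, Zo, map, sigma_a2 = 1, window_sizes = c(1, 2))
  ones <- ws$pct_var[ws$n_snp == 1]
  expect_equal(ws$pct_var[ws$n_snp == 2], sum(ones), tolerance = 1e-10)

  # correlated (LD) columns: strictly more than the sum of the parts
  Zl <- cbind(c(1, 1, -1, -1), c(1, 1, -1, 1)) * 2
  dimnames(Zl) <- dimnames(Zo)
  wl <- window_scan(c(0.3, 0.2), Zl, map, sigma_a2 = 1,
                    window_sizes = c(1, 2))
  expect_gt(wl$pct_var[wl$n_snp == 2], sum(wl$pct_var[wl$n_snp == 1]))
})

test_that("window selection thresholds and merges overlapping survivors", {
  w <- data.frame(chrom = c("1", "1", "1", "2"),
                  first_snp = c(1L, 3L, 30L, 40L),
                  last_snp = c(5L, 7L, 34L, 44L),
                  start_bp = c(100, 300, 3000, 100),
                  end_bp = c(500, 700, 3400, 500),
                  n_snp = 5L,
                  pct_var = c(0.30, 0.45, 0.10, 0.25),
                  iteration = 2L, stringsAsFactors = FALSE)
  sel <- select_windows(w, 0.20)
  expect_equal(nrow(sel), 2L)            # two overlapping survivors merge
  r1 <- sel[sel$chrom == "1", ]
  expect_equal(r1$start_bp, 100)
  expect_equal(r1$end_bp, 700)
  expect_equal(r1$max_pct, 0.45)
  expect_equal(r1$n_windows, 2L)

  expect_equal(nrow(select_windows(w, 0)), 3L)   # all, merged
  expect_equal(nrow(select_windows(w, 99)), 0L)  # none
})

test_that("gene mapping uses inclusive intervals and flags chromosome mismatches", {
  regions <- data.frame(chrom = c("1", "2"), start_bp = c(100, 1000),
                        end_bp = c(200, 2000), first_snp = 1L,
                        last_snp = 2L, n_windows = 1L, max_pct = 0.5,
                        stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("g_inside", "g_abut", "g_far", "g_chr2"),
                    chrom = c("1", "1", "1", "2"),
                    start = c(120, 200, 5000, 1500),
                    end = c(180, 350, 6000, 1600),
                    stringsAsFactors = FALSE)
  out <- map_windows_to_genes(regions, ann)
  expect_equal(out$genes[1], "g_inside,g_abut")  # abutting gene included
  expect_equal(out$genes[2], "g_chr2")

  # brute-force all-pairs oracle
  for (i in seq_len(nrow(regions))) {
    hits <- ann$gene_id[ann$chrom == regions$chrom[i] &
                          ann$start <= regions$end_bp[i] &
                          ann$end >= regions$start_bp[i]]
    expect_equal(out$genes[i], paste(hits, collapse = ","))
  }

  bad <- regions; bad$chrom <- c("chr1", "chr2")
  expect_error(map_windows_to_genes(bad, ann), "missing from annotation")
})

test_that("annotation readers agree across 1-based TSV and BED conventions", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write.table(data.frame(gene_id = "g1", chrom = "3", start = 101,
                         end = 200),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("3\t100\t200\tg1", bed)
  a1 <- read_gene_annotation(tsv, "tsv")
  a2 <- read_gene_annotation(bed, "bed")
  expect_equal(a1$start, a2$start)
  expect_equal(a1$end, a2$end)
})
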