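#' Sliding-window scan of genetic variance explained
#'
#' For every window of `n` consecutive SNPs on one chromosome, the window's
#' genetic value for each genotyped animal is the sum of its centered gene
#' content times the estimated SNP effects, and the window's score is the
#' empirical variance of those values across animals as a percentage of the
#' total additive genetic variance:
#' \deqn{100 \cdot \mathrm{Var}\left(\sum_{j \in w} Z_j \hat u_j\right) / \sigma_a^2.}
#' Windows advance one SNP at a time (`sliding = TRUE`) or by their own
#' width; windows that would span a chromosome end are dropped, and
#' chromosomes shorter than the window size produce no windows.
#' The variance uses the population denominator (n).
#'
#' @param effects per-SNP effects aligned with the columns of `Zc`.
#' @param Zc centered gene content of the genotyped animals.
#' @param map SNP map aligned with `Zc` columns.
#' @param sigma_a2 total additive genetic variance (> 0).
#' @param window_sizes integer window widths; default `c(1, 5, 10, 20, 50)`.
#' @param sliding step of 1 SNP when TRUE (default), non-overlapping
#'   windows otherwise.
#' @param iteration optional iteration tag recorded in the output.
#' @return data.frame with one row per window: `chrom`, `first_snp`,
#'   `last_snp` (column indices into `map`), `start_bp`, `end_bp`, `n_snp`,
#'   `pct_var`, `iteration`.
#' @export
window_scan <- function(effects, Zc, map, sigma_a2,
                        window_sizes = c(1, 5, 10, 20, 50),
                        sliding = TRUE, iteration = NA_integer_) {
  if (sigma_a2 <= 0) stop("sigma_a2 must be strictly positive")
  M <- ncol(Zc)
  if (length(effects) != M || nrow(map) != M) {
    stop("effects, genotype columns and map must align")
  }
  if (any(window_sizes < 1 | window_sizes > M)) {
    stop("window sizes must lie in [1, SNP count]")
  }
  g <- nrow(Zc)
  out <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    Mc <- length(cols)
    # per-animal cumulative genetic value along the chromosome
    Tm <- sweep(Zc[, cols, drop = FALSE], 2L, effects[cols], `*`)
    C <- Tm
    if (Mc > 1L) for (j in 2:Mc) C[, j] <- C[, j - 1L] + Tm[, j]
    for (n in window_sizes) {
      if (Mc < n) {
        message(sprintf("chromosome %s has %d SNPs; no %d-SNP windows",
                        ch, Mc, n))
        next
      }
      starts <- if (sliding) seq_len(Mc - n + 1L) else seq(1L, Mc - n + 1L,
                                                           by = n)
      ends <- starts + n - 1L
      W <- C[, ends, drop = FALSE]
      inner <- starts > 1L
      if (any(inner)) {
        W[, inner] <- W[, inner] - C[, starts[inner] - 1L, drop = FALSE]
      }
      v <- colMeans(W^2) - colMeans(W)^2
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        first_snp = cols[starts],
        last_snp = cols[ends],
        start_bp = map$bp[cols[starts]],
        end_bp = map$bp[cols[ends]],
        n_snp = n,
        pct_var = 100 * v / sigma_a2,
        iteration = iteration,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    stop("no windows produced; check window sizes against chromosome lengths")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select and merge windows above a variance threshold
#'
#' Keeps windows explaining at least `threshold_pct` percent of the
#' additive genetic variance, then merges overlapping survivors on the same
#' chromosome into regions.  Each region reports the merged bp span, the
#' number of qualifying windows merged, and the maximum window percentage.
#'
#' @param windows data.frame from [window_scan()].
#' @param threshold_pct retention threshold in percent (default 0.20);
#'   windows with `pct_var >= threshold_pct` survive.
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp`,
#'   `first_snp`, `last_snp`, `n_windows`, `max_pct`.
#' @export
select_windows <- function(windows, threshold_pct = 0.20) {
  if (threshold_pct < 0) stop("threshold must be non-negative")
  keep <- windows[windows$pct_var >= threshold_pct, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), first_snp = integer(0),
                      last_snp = integer(0), n_windows = integer(0),
                      max_pct = numeric(0), stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$chrom, keep$start_bp, keep$end_bp), , drop = FALSE]
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(keep))) {
    w <- keep[i, ]
    if (!is.null(cur) && cur$chrom == w$chrom && w$start_bp <= cur$end_bp) {
      cur$end_bp <- max(cur$end_bp, w$end_bp)
      cur$last_snp <- max(cur$last_snp, w$last_snp)
      cur$first_snp <- min(cur$first_snp, w$first_snp)
      cur$n_windows <- cur$n_windows + 1L
      cur$max_pct <- max(cur$max_pct, w$pct_var)
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
      cur <- list(chrom = w$chrom, start_bp = w$start_bp, end_bp = w$end_bp,
                  first_snp = w$first_snp, last_snp = w$last_snp,
                  n_windows = 1L, max_pct = w$pct_var)
    }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- do.call(rbind, lapply(regions, as.data.frame))
  out$chrom <- as.character(out$chrom)
  rownames(out) <- NULL
  out
}

#' Read a gene annotation table
#'
#' Accepts either a 4-column 1-based inclusive TSV (`gene_id`, `chrom`,
#' `start`, `end`) or a BED file (`chrom`, `start`, `end`, `name`;
#' 0-based half-open, converted to 1-based inclusive by adding 1 to the
#' start).
#'
#' @param path file path.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df))) {
      stop("annotation TSV must have columns gene_id, chrom, start, end")
    }
    ann <- df[, need]
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED annotation needs 4 columns")
    ann <- data.frame(gene_id = df[[4L]], chrom = as.character(df[[1L]]),
                      start = df[[2L]] + 1L, end = df[[3L]],
                      stringsAsFactors = FALSE)
  }
  if (any(ann$start > ann$end)) stop("gene start after end in annotation")
  ann$chrom <- as.character(ann$chrom)
  ann
}

#' Map selected regions to overlapping genes
#'
#' A gene overlaps a region when their 1-based inclusive bp intervals
#' intersect, i.e. `gene$start <= region$end_bp && gene$end >=
#' region$start_bp`; a gene that exactly abuts a region boundary is
#' included.
#'
#' @param regions data.frame from [select_windows()].
#' @param annotation data.frame from [read_gene_annotation()].
#' @return `regions` with an added `genes` column (comma-separated gene
#'   ids, empty string when none).
#' @export
map_windows_to_genes <- function(regions, annotation) {
  if (nrow(regions) == 0L) {
    regions$genes <- character(0)
    return(regions)
  }
  unmatched <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(unmatched)) {
    stop("region chromosomes missing from annotation: ",
         paste(unmatched, collapse = ", "))
  }
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- annotation$chrom == r$chrom &
      annotation$start <= r$end_bp & annotation$end >= r$start_bp
    paste(annotation$gene_id[hit], collapse = ",")
  }, character(1))
  regions
}

#' Manhattan-style plot of window variance percentages
#'
#' Plots per-window percentage of additive genetic variance against
#' genome-wide position, one panel color per chromosome, for a single
#' window size.
#'
#' @param windows data.frame from [window_scan()].
#' @param n_snp window size to plot (default the largest present).
#' @param threshold_pct optional horizontal reference line.
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(windows, n_snp = max(windows$n_snp),
                           threshold_pct = NULL, ...) {
  w <- windows[windows$n_snp == n_snp, , drop = FALSE]
  chroms <- unique(w$chrom)
  offset <- 0
  xs <- numeric(nrow(w))
  cols <- integer(nrow(w))
  for (k in seq_along(chroms)) {
    sel <- w$chrom == chroms[k]
    xs[sel] <- offset + (w$start_bp[sel] + w$end_bp[sel]) / 2
    cols[sel] <- 1L + (k %% 2L)
    offset <- offset + max(w$end_bp[sel])
  }
  graphics::plot(xs, w$pct_var, col = c("grey30", "steelblue")[cols],
                 pch = 16, cex = 0.5, xlab = "genome position",
                 ylab = "% additive genetic variance",
                 main = sprintf("%d-SNP windows", n_snp), ...)
  if (!is.null(threshold_pct)) {
    graphics::abline(h = threshold_pct, col = "firebrick", lty = 2)
  }
  invisible(NULL)
}
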