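#' Pipeline configuration
#'
#' Declarative configuration for a full run: input paths, model choice and
#' the analysis constants.  Defaults follow routine practice for this kind
#' of evaluation: MAF threshold 0.05, trait bounds 270-700 days, five
#' reweighting iterations with the GWAS read off iteration 2, sliding
#' windows of 1/5/10/20/50 SNPs, a 0.20% variance threshold for declaring
#' a region, and G blended with A22 at alpha 0.95.
#'
#' @param pedigree,genotypes,map,phenotypes input file paths.
#' @param annotation optional gene annotation path (TSV or BED).
#' @param annotation_format `"tsv"` or `"bed"`.
#' @param model_kind `"primiparous"` or `"multiparous"`.
#' @param pedigree_only skip genomic stages and report pedigree-BLUP EBVs.
#' @param maf_threshold minor allele frequency threshold (default 0.05).
#' @param trait_bounds inclusive phenotype bounds in days (default 270-700).
#' @param n_iter weighted single-step iterations (default 5).
#' @param gwas_iteration iteration whose SNP effects feed the window scan
#'   (default 2).
#' @param window_sizes SNP window widths (default 1, 5, 10, 20, 50).
#' @param threshold_pct window selection threshold in percent (default 0.20).
#' @param blend_alpha weight on G when blending with A22 (default 0.95).
#' @param accuracy_mode `"sqrt"` or `"literal"` (see [compute_accuracy()]).
#' @param vc optional [variance_components()]; estimated by REML when NULL.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pedigree, genotypes, map, phenotypes,
                            annotation = NULL,
                            annotation_format = c("tsv", "bed"),
                            model_kind = c("primiparous", "multiparous"),
                            pedigree_only = FALSE, maf_threshold = 0.05,
                            trait_bounds = c(270, 700), n_iter = 5,
                            gwas_iteration = 2,
                            window_sizes = c(1, 5, 10, 20, 50),
                            threshold_pct = 0.20, blend_alpha = 0.95,
                            accuracy_mode = c("sqrt", "literal"),
                            vc = NULL, seed = 1) {
  cfg <- list(pedigree = pedigree, genotypes = genotypes, map = map,
              phenotypes = phenotypes, annotation = annotation,
              annotation_format = match.arg(annotation_format),
              model_kind = match.arg(model_kind),
              pedigree_only = isTRUE(pedigree_only),
              maf_threshold = maf_threshold, trait_bounds = trait_bounds,
              n_iter = as.integer(n_iter),
              gwas_iteration = as.integer(gwas_iteration),
              window_sizes = as.integer(window_sizes),
              threshold_pct = threshold_pct, blend_alpha = blend_alpha,
              accuracy_mode = match.arg(accuracy_mode), vc = vc,
              seed = as.integer(seed))
  if (cfg$maf_threshold < 0 || cfg$maf_threshold >= 0.5) {
    stop("maf_threshold must lie in [0, 0.5)")
  }
  if (cfg$gwas_iteration > cfg$n_iter) {
    stop("gwas_iteration cannot exceed n_iter")
  }
  if (cfg$threshold_pct < 0) stop("threshold_pct must be non-negative")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; entries in
#' `overrides` (e.g. parsed command-line flags) replace file values.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Restrict phenotypes to the plausible trait range
#'
#' Drops records outside the closed interval `bounds` (both endpoints
#' retained) and logs how many were removed.
#'
#' @param pheno phenotype data.frame with a `y` column.
#' @param bounds length-2 numeric, lower < upper.
#' @return filtered data.frame.
#' @export
filter_phenotypes <- function(pheno, bounds = c(270, 700)) {
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L]) {
    stop("bounds must be (lower, upper) with lower < upper")
  }
  keep <- pheno$y >= bounds[1L] & pheno$y <= bounds[2L]
  removed <- sum(!keep)
  message(sprintf("trait filter [%g, %g]: removed %d of %d records",
                  bounds[1L], bounds[2L], removed, nrow(pheno)))
  out <- pheno[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records left after trait filtering")
  rownames(out) <- NULL
  out
}

#' Run the full evaluation pipeline
#'
#' Reads the inputs, filters phenotypes and SNPs, builds the relationship
#' machinery, estimates (or accepts) variance components, runs the
#' weighted single-step iteration, scans windows at the configured
#' iteration, selects and annotates regions, and writes every intermediate
#' artifact plus a machine-readable manifest into `out_dir`.  In
#' `pedigree_only` mode the genomic stages are skipped and pedigree-BLUP
#' EBVs are reported instead.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @return invisible list with the in-memory results (`vc`, `fit` or
#'   `solution`, `windows`, `regions`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ped <- stage("read_pedigree", read_pedigree(cfg$pedigree))
  gin <- stage("read_genotypes", read_genotypes(cfg$genotypes, cfg$map))
  pheno <- stage("read_phenotypes", read_phenotypes(cfg$phenotypes))
  pheno <- stage("filter_phenotypes",
                 filter_phenotypes(pheno, cfg$trait_bounds))
  flt <- stage("filter_maf",
               filter_maf(gin$geno, gin$map, cfg$maf_threshold))
  spec <- model_spec(cfg$model_kind,
                     relationship = if (cfg$pedigree_only) "A" else "H",
                     accuracy_mode = cfg$accuracy_mode)
  design <- stage("build_design", build_design(pheno, spec, ped))
  A_inv <- stage("build_A_inverse", build_A_inverse(ped))
  vc <- cfg$vc
  if (is.null(vc)) {
    vc <- stage("estimate_reml", estimate_reml(design, A_inv))
    jsonlite::write_json(
      list(sigma_a2 = vc$sigma_a2, sigma_pe2 = vc$sigma_pe2,
           sigma_e2 = vc$sigma_e2, h2 = vc$h2,
           se = as.list(vc$se), converged = vc$converged,
           n_iter = vc$n_iter, loglik = vc$loglik),
      file.path(out_dir, "reml.json"), auto_unbox = TRUE, digits = NA)
  }
  results <- list(vc = vc)
  if (cfg$pedigree_only) {
    sol <- stage("solve_mme", solve_mme(design, A_inv, vc))
    results$solution <- sol
    .write_solution(sol, ped, out_dir, prefix = "pblup")
  } else {
    genotyped_ids <- rownames(flt$geno)
    Zc <- stage("center_Z", center_Z(flt$geno, flt$map))
    fit <- stage("run_wssgblup",
                 run_wssgblup(design, ped, Zc, flt$map, vc,
                              n_iter = cfg$n_iter,
                              blend_alpha = cfg$blend_alpha,
                              A_inv = A_inv))
    results$fit <- fit
    for (it in seq_len(cfg$n_iter)) {
      .write_solution(fit$iterations[[it]]$solution, ped, out_dir,
                      prefix = sprintf("wssgblup_iter%d", it))
    }
    eff <- fit$iterations[[cfg$gwas_iteration]]$effects
    windows <- stage("window_scan",
                     window_scan(eff, Zc, flt$map, vc$sigma_a2,
                                 window_sizes = cfg$window_sizes,
                                 iteration = cfg$gwas_iteration))
    utils::write.table(windows, file.path(out_dir, "windows.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    top_size <- max(cfg$window_sizes)
    regions <- stage("select_windows",
                     select_windows(windows[windows$n_snp == top_size, ],
                                    cfg$threshold_pct))
    if (!is.null(cfg$annotation)) {
      ann <- stage("read_gene_annotation",
                   read_gene_annotation(cfg$annotation,
                                        cfg$annotation_format))
      regions <- stage("map_windows_to_genes",
                       map_windows_to_genes(regions, ann))
    }
    utils::write.table(regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    grDevices::png(file.path(out_dir, "manhattan.png"), width = 1200,
                   height = 500)
    plot_manhattan(windows, n_snp = top_size,
                   threshold_pct = cfg$threshold_pct)
    grDevices::dev.off()
    results$windows <- windows
    results$regions <- regions
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$vc <- NULL
  manifest <- list(
    config = cfg_plain,
    variance_components = list(sigma_a2 = vc$sigma_a2,
                               sigma_pe2 = vc$sigma_pe2,
                               sigma_e2 = vc$sigma_e2, h2 = vc$h2),
    counts = list(n_pedigree = ped$n, n_records = nrow(pheno),
                  n_snp_in = ncol(gin$geno), n_snp_kept = ncol(flt$geno),
                  n_genotyped = if (cfg$pedigree_only) 0L else
                    nrow(flt$geno)),
    package_version = as.character(utils::packageVersion("wssgblup"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

.write_solution <- function(sol, ped, out_dir, prefix) {
  df <- data.frame(animal = names(sol$ebv), ebv = as.numeric(sol$ebv))
  if (!is.null(sol$pev)) {
    df$pev <- as.numeric(sol$pev)
    df$reliability <- as.numeric(sol$reliability)
    df$accuracy <- as.numeric(sol$accuracy)
  }
  utils::write.table(df, file.path(out_dir, paste0(prefix, "_ebv.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fx <- data.frame(effect = names(sol$fixed),
                   estimate = as.numeric(sol$fixed))
  utils::write.table(fx, file.path(out_dir, paste0(prefix, "_fixed.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
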