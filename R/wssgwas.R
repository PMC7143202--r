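#' Back-solve SNP effects from genomic breeding values
#'
#' Given GEBVs of the genotyped animals, recovers per-SNP allele
#' substitution effects as
#' \deqn{\hat u = D Z' [Z D Z']^{-1} \hat a_g,}
#' the conditional expectation of SNP effects given breeding values under
#' the weighted SNP-variance model.  When `Z D Z'` is numerically singular
#' (more animals than SNPs) a declared ridge is added to the diagonal.
#'
#' Note that when allele frequencies are observed in the same animals, the
#' columns of `Zc` sum to zero, so `Z D Z'` is exactly singular; that is
#' the blended-G* path used by [run_wssgblup()].  The direct solve is for
#' full-rank instances (external frequencies or validation cases).
#'
#' @param a_g named numeric vector of GEBVs for the genotyped animals, in
#'   the row order of `Zc`.
#' @param Zc centered gene-content matrix ([center_Z()]).
#' @param weights per-SNP variance weights (default unit).
#' @param p per-SNP allele frequencies; required with `G_inv` to form the
#'   normalizing constant lambda.
#' @param G_inv optional inverse of the (blended, weighted) genomic
#'   relationship matrix as a `relmatrix` or plain matrix; when supplied,
#'   effects are computed as `lambda D Z' G*^-1 a_g`.
#' @param ridge relative diagonal ridge applied when the direct system
#'   fails to factorize or leaves a large residual (default 1e-8).
#' @return numeric vector of SNP effects (names = SNP ids).
#' @export
backsolve_snp_effects <- function(a_g, Zc, weights = NULL, p = NULL,
                                  G_inv = NULL, ridge = 1e-8) {
  if (length(a_g) != nrow(Zc)) stop("GEBV vector and genotype rows disagree")
  if (!is.null(names(a_g)) && !is.null(rownames(Zc)) &&
      !identical(names(a_g), rownames(Zc))) {
    stop("GEBV order does not match genotype row order")
  }
  M <- ncol(Zc)
  if (is.null(weights)) weights <- rep(1, M)
  if (length(weights) != M) stop("weights length must equal SNP count")
  if (!is.null(G_inv)) {
    if (is.data.frame(p)) p <- p$p
    if (is.null(p)) stop("allele frequencies needed with G_inv")
    Gi <- if (inherits(G_inv, "relmatrix")) .rel_unwrap(G_inv) else G_inv
    lam <- compute_lambda(p)
    sol <- lam * as.numeric(Gi %*% a_g)
  } else {
    Zw <- sweep(Zc, 2L, weights, `*`)
    S <- tcrossprod(Zw, Zc)
    S <- (S + t(S)) / 2
    sol <- .solve_refined(S, a_g)
    if (is.null(sol)) {
      S <- S + diag(ridge * mean(diag(S)), nrow(S))
      sol <- .solve_refined(S, a_g, must_work = TRUE)
    }
  }
  u <- weights * as.numeric(crossprod(Zc, sol))
  names(u) <- colnames(Zc)
  u
}

# Cholesky solve with iterative refinement; returns NULL when the matrix
# does not factorize or the refined residual stays large (near-singular).
.solve_refined <- function(S, b, must_work = FALSE) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    if (must_work) stop("system singular even after ridging")
    return(NULL)
  }
  chsolve <- function(v) backsolve(ch, backsolve(ch, v, transpose = TRUE))
  sol <- chsolve(b)
  scale <- max(1, max(abs(b)))
  for (k in seq_len(10L)) {
    r <- b - as.numeric(S %*% sol)
    if (max(abs(r)) <= 1e-13 * scale) break
    corr <- chsolve(r)
    if (max(abs(corr)) > max(1, max(abs(sol)))) break  # diverging: singular
    sol <- sol + corr
  }
  if (!must_work && max(abs(b - as.numeric(S %*% sol))) > 1e-9 * scale) {
    return(NULL)
  }
  sol
}

#' Update SNP variance weights from estimated effects
#'
#' Each SNP's weight is its estimated variance contribution
#' d_i = u_i^2 2 p_i (1 - p_i), normalized so the weights sum to the SNP
#' count M (keeping the scale of the weighted genomic relationship matrix
#' stable across iterations).  Zero-effect SNPs are floored at a small
#' epsilon so the weight matrix stays invertible.
#'
#' @param effects per-SNP effects from [backsolve_snp_effects()].
#' @param p per-SNP allele frequencies (or a map with a `p` column).
#' @param floor_eps lower bound applied before normalization (default 1e-8).
#' @return numeric weight vector summing to `length(effects)`.
#' @export
update_weights <- function(effects, p, floor_eps = 1e-8) {
  if (is.data.frame(p)) p <- p$p
  if (length(effects) != length(p)) stop("effects and frequencies disagree")
  if (any(!is.finite(effects))) stop("non-finite SNP effects")
  d <- effects^2 * 2 * p * (1 - p)
  if (all(d == 0)) {
    warning("all SNP effects are zero; returning uniform weights")
    return(rep(1, length(d)))
  }
  d <- pmax(d, floor_eps)
  d * length(d) / sum(d)
}

#' Run the weighted single-step GBLUP iteration
#'
#' Implements the iterative reweighting scheme: start from unit SNP weights
#' (iteration 1 is plain ssGBLUP), and at each iteration build the weighted
#' genomic relationship matrix, blend it with the genotyped-block pedigree
#' relationships, assemble H-inverse, solve the mixed-model equations,
#' back-solve SNP effects from the genotyped animals' GEBVs, and convert
#' the effects into the next iteration's weights.
#'
#' @param design output of [build_design()].
#' @param ped the [pedigree()].
#' @param Zc centered gene content of the genotyped animals.
#' @param map SNP map with observed frequencies (`p` column).
#' @param vc a [variance_components()].
#' @param n_iter number of iterations (default 5).
#' @param blend_alpha weight on G when blending with A22 (default 0.95).
#' @param compute_pev compute PEV/accuracy at every iteration (default
#'   TRUE; the per-iteration mean accuracy is NA when disabled).
#' @param A_inv,A22 optionally precomputed [build_A_inverse()] /
#'   [subset_A22()] results (recomputed when NULL).
#' @return object of class `wssgblup_fit`: list of per-iteration records
#'   (`weights`, `effects`, `solution`, `mean_accuracy`), plus the shared
#'   matrices and settings.
#' @export
run_wssgblup <- function(design, ped, Zc, map, vc, n_iter = 5,
                         blend_alpha = 0.95, compute_pev = TRUE,
                         A_inv = NULL, A22 = NULL) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  genotyped_ids <- rownames(Zc)
  genotyped_index <- ped_index(ped, genotyped_ids)
  if (is.null(A_inv)) A_inv <- build_A_inverse(ped)
  if (is.null(A22)) A22 <- subset_A22(ped, genotyped_ids)
  A22_inv <- invert_relmatrix(A22)
  M <- ncol(Zc)
  weights <- rep(1, M)
  iterations <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    G <- build_G(Zc, map, weights = weights)
    Gb <- blend_G(G, A22, alpha = blend_alpha)
    Gb_inv <- invert_relmatrix(Gb)
    H_inv <- build_H_inverse(A_inv, A22_inv, Gb_inv, genotyped_index)
    sol <- solve_mme(design, H_inv, vc, compute_pev = compute_pev)
    a_g <- sol$ebv[genotyped_index]
    effects <- backsolve_snp_effects(a_g, Zc, weights = weights,
                                     p = map, G_inv = Gb_inv)
    iterations[[it]] <- list(
      iteration = it,
      weights = weights,
      effects = effects,
      solution = sol,
      mean_accuracy = if (compute_pev) mean(sol$accuracy) else NA_real_
    )
    weights <- update_weights(effects, map)
  }
  fit <- list(iterations = iterations, n_iter = n_iter,
              genotyped_ids = genotyped_ids,
              genotyped_index = genotyped_index,
              blend_alpha = blend_alpha, vc = vc, map = map)
  class(fit) <- "wssgblup_fit"
  fit
}

#' @export
print.wssgblup_fit <- function(x, ...) {
  acc <- vapply(x$iterations, `[[`, numeric(1), "mean_accuracy")
  cat("weighted ssGBLUP fit: ", x$n_iter, " iterations, ",
      length(x$genotyped_ids), " genotyped animals\n", sep = "")
  cat("mean PEV-based accuracy by iteration: ",
      paste(sprintf("%.3f", acc), collapse = ", "), "\n", sep = "")
  invisible(x)
}
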