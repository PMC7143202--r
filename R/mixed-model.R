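#' Specify the evaluation model
#'
#' Two models are supported, mirroring routine dairy fertility evaluations:
#' a single-record animal model for first-lactation records
#' (`"primiparous"`: herd-year-season and country fixed effects, linear and
#' quadratic age-at-first-calving covariates, animal additive effect) and a
#' repeatability animal model for later lactations (`"multiparous"`: the
#' same plus a parity fixed effect and a permanent-environment random
#' effect).
#'
#' @param kind `"primiparous"` or `"multiparous"`.
#' @param relationship `"H"` for single-step (pedigree + genomic) or `"A"`
#'   for pedigree-only BLUP.
#' @param accuracy_mode `"sqrt"` (accuracy = sqrt(1 - PEV / sigma_a2)) or
#'   `"literal"` (returns 1 - PEV / sigma_a2 itself, i.e. reliability).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("primiparous", "multiparous"),
                       relationship = c("H", "A"),
                       accuracy_mode = c("sqrt", "literal")) {
  kind <- match.arg(kind)
  spec <- list(
    kind = kind,
    relationship = match.arg(relationship),
    accuracy_mode = match.arg(accuracy_mode),
    use_pe = kind == "multiparous"
  )
  class(spec) <- "model_spec"
  spec
}

#' Build design matrices for the mixed model
#'
#' Constructs y, the fixed-effects matrix X (intercept, herd-year-season and
#' country dummies with drop-first constraints, parity dummies for the
#' repeatability model, centered age and centered-age-squared covariates),
#' the record-to-animal incidence Z_a over all pedigree animals, and for the
#' repeatability model the record-to-animal incidence Z_pe over animals with
#' records.
#'
#' @param pheno phenotype data.frame with columns `animal`, `y`, `hys`,
#'   `country`, `age` and, for the repeatability model, `parity`.
#' @param spec a [model_spec()].
#' @param ped a [pedigree()]; every `animal` must be present.
#' @return list `y`, `X`, `Z_a` (sparse, records x pedigree animals),
#'   `Z_pe` (sparse or NULL), `animal_ids`, `pe_ids`, `records`.
#' @export
build_design <- function(pheno, spec, ped) {
  need <- c("animal", "y", "hys", "country", "age")
  if (spec$use_pe) need <- c(need, "parity")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  idx <- ped_index(ped, pheno$animal)
  if (!spec$use_pe && anyDuplicated(pheno$animal)) {
    stop("primiparous model admits one record per animal; found repeats")
  }
  nrec <- nrow(pheno)
  age_c <- pheno$age - mean(pheno$age)
  fe <- data.frame(hys = factor(pheno$hys), country = factor(pheno$country))
  if (spec$use_pe) fe$parity <- factor(pheno$parity)
  fe$y <- pheno$y
  fe$age_c <- age_c
  fe$age_c2 <- age_c^2
  # constant factors carry no contrasts and are absorbed by the intercept
  terms <- names(fe)[vapply(fe, is.factor, logical(1))]
  constant <- terms[vapply(fe[terms], nlevels, integer(1)) < 2L]
  if (length(constant)) {
    message("constant fixed effect(s) absorbed by the intercept: ",
            paste(constant, collapse = ", "))
    terms <- setdiff(terms, constant)
  }
  form <- stats::reformulate(c(terms, "age_c", "age_c2"), response = "y")
  X <- stats::model.matrix(form, data = fe)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effects matrix is rank deficient; confounded columns: ",
         paste(dropped, collapse = ", "))
  }
  Z_a <- Matrix::sparseMatrix(i = seq_len(nrec), j = idx, x = 1,
                              dims = c(nrec, ped$n),
                              dimnames = list(NULL, ped$id))
  Z_pe <- NULL
  pe_ids <- NULL
  if (spec$use_pe) {
    pe_ids <- unique(as.character(pheno$animal))
    j <- match(as.character(pheno$animal), pe_ids)
    Z_pe <- Matrix::sparseMatrix(i = seq_len(nrec), j = j, x = 1,
                                 dims = c(nrec, length(pe_ids)),
                                 dimnames = list(NULL, pe_ids))
  }
  list(y = as.numeric(pheno$y), X = X, Z_a = Z_a, Z_pe = Z_pe,
       animal_ids = ped$id, pe_ids = pe_ids, records = pheno, spec = spec)
}

#' Variance components container
#'
#' @param sigma_a2 additive genetic variance.
#' @param sigma_pe2 permanent-environment variance (0 for single-record
#'   models).
#' @param sigma_e2 residual variance.
#' @param se optional named numeric vector of standard errors.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(sigma_a2, sigma_pe2 = 0, sigma_e2,
                                se = NULL) {
  if (sigma_a2 < 0 || sigma_pe2 < 0 || sigma_e2 <= 0) {
    stop("variances must be non-negative and sigma_e2 strictly positive")
  }
  vc <- list(sigma_a2 = sigma_a2, sigma_pe2 = sigma_pe2,
             sigma_e2 = sigma_e2, se = se)
  vc$h2 <- sigma_a2 / (sigma_a2 + sigma_pe2 + sigma_e2)
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_a2 = %.4g, sigma_pe2 = %.4g, sigma_e2 = %.4g (h2 = %.4f)\n",
              x$sigma_a2, x$sigma_pe2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\begin{bmatrix} X'X & X'Z_a & X'Z_p \\ Z_a'X & Z_a'Z_a + K^{-1}\lambda_a & Z_a'Z_p \\ Z_p'X & Z_p'Z_a & Z_p'Z_p + I\lambda_p \end{bmatrix}
#'   \begin{bmatrix} \hat b \\ \hat a \\ \hat p \end{bmatrix} =
#'   \begin{bmatrix} X'y \\ Z_a'y \\ Z_p'y \end{bmatrix}}
#' with \eqn{\lambda_a = \sigma_e^2/\sigma_a^2} and
#' \eqn{\lambda_p = \sigma_e^2/\sigma_{pe}^2}.  `K_inv` is the inverse
#' relationship matrix: H-inverse for single-step runs, A-inverse for
#' pedigree BLUP.  Prediction error variances are read off the inverse of
#' the coefficient matrix: PEV_i = C^{aa}_{ii} sigma_e2.
#'
#' @param design output of [build_design()].
#' @param K_inv `relmatrix` with `is_inverse = TRUE` over the pedigree
#'   animals, in pedigree order.
#' @param vc a [variance_components()].
#' @param compute_pev invert the coefficient matrix for PEV/reliability
#'   (cubic in its size; disable inside iteration loops that do not need it).
#' @return object of class `mme_solution`: `fixed` (named vector), `ebv`
#'   (named, all pedigree animals), `pe` (named or NULL), `pev`,
#'   `reliability`, `accuracy` (NULL unless `compute_pev`), `vc`, `spec`.
#' @export
solve_mme <- function(design, K_inv, vc, compute_pev = TRUE) {
  if (!is_inverse(K_inv)) stop("K_inv must carry is_inverse = TRUE")
  .check_same_ids(rel_ids(K_inv), design$animal_ids, "solve_mme")
  if (vc$sigma_a2 <= 0) stop("sigma_a2 must be strictly positive to solve the MME")
  use_pe <- !is.null(design$Z_pe)
  if (use_pe && vc$sigma_pe2 <= 0) {
    stop("repeatability model requires sigma_pe2 > 0")
  }
  lam_a <- vc$sigma_e2 / vc$sigma_a2
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Za <- design$Z_a
  W <- cbind(X, Za)
  if (use_pe) W <- cbind(W, design$Z_pe)
  Cd <- as.matrix(Matrix::crossprod(W))
  p <- ncol(X); q <- ncol(Za)
  ai <- p + seq_len(q)
  Cd[ai, ai] <- Cd[ai, ai] + as.matrix(.rel_unwrap(K_inv)) * lam_a
  if (use_pe) {
    pi_ <- p + q + seq_len(ncol(design$Z_pe))
    Cd[cbind(pi_, pi_)] <- Cd[cbind(pi_, pi_)] + vc$sigma_e2 / vc$sigma_pe2
  }
  rhs <- as.numeric(Matrix::crossprod(W, design$y))
  ch <- tryCatch(chol(Cd), error = function(e) {
    stop("mixed-model equations are singular (inestimable model): ",
         conditionMessage(e))
  })
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  fixed <- stats::setNames(sol[seq_len(p)], colnames(design$X))
  ebv <- stats::setNames(sol[ai], design$animal_ids)
  pe <- if (use_pe) stats::setNames(sol[p + q + seq_len(ncol(design$Z_pe))],
                                    design$pe_ids) else NULL
  out <- list(fixed = fixed, ebv = ebv, pe = pe, pev = NULL,
              reliability = NULL, accuracy = NULL, vc = vc,
              spec = design$spec, n_records = length(design$y),
              n_fixed = p)
  if (compute_pev) {
    Cinv_diag <- diag(chol2inv(ch))[ai]
    out$pev <- stats::setNames(Cinv_diag * vc$sigma_e2, design$animal_ids)
    acc <- compute_accuracy(out, vc,
                            mode = design$spec$accuracy_mode %||% "sqrt")
    out$reliability <- acc$reliability
    out$accuracy <- acc$accuracy
  }
  class(out) <- "mme_solution"
  out
}

#' @export
print.mme_solution <- function(x, ...) {
  cat("mixed-model solution: ", length(x$fixed), " fixed effects, ",
      length(x$ebv), " breeding values\n", sep = "")
  if (!is.null(x$accuracy)) {
    cat(sprintf("mean accuracy %.3f\n", mean(x$accuracy)))
  }
  invisible(x)
}

#' Reliability and accuracy from prediction error variance
#'
#' Reliability r2 = 1 - PEV / sigma_a2.  In `"sqrt"` mode the reported
#' accuracy is sqrt(r2), the correlation between true and estimated breeding
#' value; `"literal"` mode reports r2 itself.  Values falling outside [0, 1]
#' by numerical error are clipped with a warning.
#'
#' @param sol an `mme_solution` with PEV present.
#' @param vc a [variance_components()] with `sigma_a2 > 0`.
#' @param mode `"sqrt"` or `"literal"`.
#' @return list `reliability`, `accuracy` (named per animal).
#' @export
compute_accuracy <- function(sol, vc, mode = c("sqrt", "literal")) {
  mode <- match.arg(mode)
  if (vc$sigma_a2 <= 0) stop("accuracy undefined for sigma_a2 = 0")
  if (is.null(sol$pev)) stop("solution carries no PEV; rerun with compute_pev = TRUE")
  r2 <- 1 - sol$pev / vc$sigma_a2
  out_of_range <- r2 < -1e-8 | r2 > 1 + 1e-8
  if (any(out_of_range)) {
    warning(sum(out_of_range), " reliabilities outside [0, 1]; clipped")
  }
  r2 <- pmin(pmax(r2, 0), 1)
  acc <- if (mode == "sqrt") sqrt(r2) else r2
  list(reliability = r2, accuracy = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
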