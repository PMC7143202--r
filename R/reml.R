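#' Estimate variance components by REML
#'
#' Average-information REML with a monotone EM fallback, parameterized on
#' the variance components of the fitted model: additive genetic variance
#' (with covariance structure given by the relationship matrix), a
#' permanent-environment variance for the repeatability model, and the
#' residual.  AI steps are attempted first (with step halving); whenever an
#' AI proposal leaves the parameter space or decreases the restricted
#' likelihood, an EM step is taken instead, so the likelihood trajectory is
#' non-decreasing.  Components collapsing to zero are pinned at a small
#' positive bound.  Standard errors come from the inverse AI matrix at
#' convergence.
#'
#' For single-record models (animal + residual only) the record-level
#' covariance `Z K Z'` is eigendecomposed once, after which every iteration
#' costs O(n p) instead of O(n^3).
#'
#' @param design output of [build_design()].
#' @param K_inv relationship `relmatrix` over the pedigree animals; either
#'   an inverse (`is_inverse = TRUE`, inverted internally) or the
#'   relationship matrix itself.
#' @param init optional [variance_components()] starting values.
#' @param max_iter iteration cap (default 500).
#' @param tol convergence tolerance on the maximum relative parameter
#'   change (default 1e-8).
#' @param verbose print the likelihood trajectory.
#' @return a [variance_components()] with extra fields `loglik`
#'   (trajectory), `converged`, `n_iter`, `se`.
#' @export
estimate_reml <- function(design, K_inv, init = NULL, max_iter = 500,
                          tol = 1e-8, verbose = FALSE) {
  y <- design$y
  X <- design$X
  n <- length(y)
  use_pe <- !is.null(design$Z_pe)
  K <- if (is_inverse(K_inv)) {
    chol2inv(chol(as.matrix(.rel_unwrap(K_inv))))
  } else {
    as.matrix(.rel_unwrap(K_inv))
  }
  .check_same_ids(rel_ids(K_inv), design$animal_ids, "estimate_reml")
  Ka <- as.matrix(design$Z_a %*% K %*% Matrix::t(design$Z_a))
  vy <- stats::var(y)
  lower <- 1e-8 * vy
  if (is.null(init)) {
    theta <- if (use_pe) c(a = 0.25, pe = 0.10, e = 0.65) * vy
             else c(a = 0.25, e = 0.75) * vy
  } else {
    theta <- if (use_pe) c(a = init$sigma_a2, pe = init$sigma_pe2,
                           e = init$sigma_e2)
             else c(a = init$sigma_a2, e = init$sigma_e2)
  }
  theta <- pmax(theta, lower)
  qlev <- if (use_pe) c(a = ncol(design$Z_a), pe = ncol(design$Z_pe), e = n)
          else c(a = ncol(design$Z_a), e = n)

  if (use_pe) {
    Kpe <- as.matrix(Matrix::tcrossprod(design$Z_pe))
    state_fun <- function(th) .reml_state_dense(y, X, list(a = Ka, pe = Kpe), th)
  } else {
    eg <- eigen(Ka, symmetric = TRUE)
    yt <- as.numeric(crossprod(eg$vectors, y))
    Xt <- crossprod(eg$vectors, X)
    state_fun <- function(th) .reml_state_eigen(yt, Xt, eg$values, th)
  }

  st <- state_fun(theta)
  trajectory <- st$loglik
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # AI proposal with step halving, EM fallback
    delta <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
    new_theta <- NULL
    new_st <- NULL
    if (!is.null(delta)) {
      for (step in c(1, 0.5, 0.25)) {
        cand <- theta + step * delta
        if (any(cand < lower)) next
        cand_st <- state_fun(cand)
        if (cand_st$loglik >= st$loglik - 1e-10) {
          new_theta <- cand; new_st <- cand_st
          break
        }
      }
    }
    if (is.null(new_theta)) {
      cand <- theta + theta^2 / qlev * (st$yPViPy - st$trPVi)
      cand <- pmax(cand, lower)
      new_theta <- cand
      new_st <- state_fun(cand)
    }
    rel_change <- max(abs(new_theta - theta) / pmax(theta, lower))
    theta <- new_theta
    st <- new_st
    trajectory <- c(trajectory, st$loglik)
    if (verbose) message(sprintf("iter %3d  loglik %.6f  theta %s", it,
                                 st$loglik,
                                 paste(signif(theta, 6), collapse = " ")))
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  se <- tryCatch(sqrt(diag(solve(st$AI))), error = function(e) rep(NA_real_,
                                                                   length(theta)))
  names(se) <- names(theta)
  if (!converged) {
    warning("REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  vc <- variance_components(sigma_a2 = theta[["a"]],
                            sigma_pe2 = if (use_pe) theta[["pe"]] else 0,
                            sigma_e2 = theta[["e"]],
                            se = se)
  vc$loglik <- trajectory
  vc$converged <- converged
  vc$n_iter <- n_iter
  vc
}

# Dense-V REML quantities: loglik, score, AI matrix, and the EM ingredients
# y'P Vi P y and tr(P Vi) for each component (residual last).
.reml_state_dense <- function(y, X, Klist, theta) {
  n <- length(y)
  nc <- length(theta)
  V <- diag(theta[nc], n)
  for (k in seq_len(nc - 1L)) V <- V + theta[k] * Klist[[k]]
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  Wx <- Vinv %*% X
  XtVX <- crossprod(X, Wx)
  chx <- chol(XtVX)
  S <- chol2inv(chx)
  P <- Vinv - Wx %*% S %*% t(Wx)
  Py <- as.numeric(P %*% y)
  u <- vector("list", nc)
  trPVi <- numeric(nc)
  yPViPy <- numeric(nc)
  for (k in seq_len(nc)) {
    if (k < nc) {
      u[[k]] <- as.numeric(Klist[[k]] %*% Py)
      trPVi[k] <- sum(P * Klist[[k]])
    } else {
      u[[k]] <- Py
      trPVi[k] <- sum(diag(P))
    }
    yPViPy[k] <- sum(Py * u[[k]])
  }
  AI <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    Pui <- as.numeric(P %*% u[[i]])
    for (j in i:nc) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(u[[j]] * Pui)
    }
  }
  score <- -0.5 * (trPVi - yPViPy)
  loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
  list(loglik = loglik, score = score, AI = AI, trPVi = trPVi,
       yPViPy = yPViPy)
}

# Eigen-path REML quantities for the single-random-effect model:
# V = theta_a * diag(lambda) + theta_e * I in the rotated basis.
.reml_state_eigen <- function(yt, Xt, lambda, theta) {
  v <- theta[["a"]] * lambda + theta[["e"]]
  vinv <- 1 / v
  Wx <- Xt * vinv
  XtVX <- crossprod(Xt, Wx)
  chx <- chol(XtVX)
  S <- chol2inv(chx)
  B <- Wx %*% S                       # n x p
  Py <- yt * vinv - as.numeric(B %*% crossprod(Wx, yt))
  Pdiag <- vinv - rowSums(B * Wx)
  Pu <- function(u) u * vinv - as.numeric(B %*% crossprod(Wx, u))
  u_a <- lambda * Py
  trPVi <- c(a = sum(lambda * Pdiag), e = sum(Pdiag))
  yPViPy <- c(a = sum(Py * u_a), e = sum(Py * Py))
  Pua <- Pu(u_a)
  PPy <- Pu(Py)
  AI <- 0.5 * matrix(c(sum(u_a * Pua), sum(Py * Pua),
                       sum(Py * Pua), sum(Py * PPy)), 2, 2)
  score <- -0.5 * (trPVi - yPViPy)
  loglik <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(chx))) + sum(yt * Py))
  list(loglik = loglik, score = score, AI = AI, trPVi = trPVi,
       yPViPy = yPViPy)
}
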