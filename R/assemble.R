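## Assembly of the mixed model equations for either parameterisation.
## The coefficient matrix is
##   MV: [X'R^-1 X, X'R^-1 Z; Z'R^-1 X, Z'R^-1 Z + sum_t Kinv_t (x) Sigma_t^-1]
##   PC: as above with Z* = Z (I (x) Q_t) and Kinv_t (x) I_q,
## built on a fixed structural pattern (explicit zeros retained) so that the
## patterns of all parameter derivatives stay contained in the pattern of C.

## numeric (or structural) W, Rinv triplets over the design groups
.w_rinv_triplets <- function(design, covs = NULL, Qlist = NULL,
                             structural = FALSE) {
  param <- design$param
  Wi <- Wj <- integer(0); Wx <- numeric(0)
  Ri <- Rj <- integer(0); Rx <- numeric(0)
  for (g in design$groups) {
    coef_fix <- rep(1, g$m_fix)
    coef_term <- if (!length(g$term_p)) numeric(0)
      else if (structural || param == "mv") rep(1, length(g$term_p))
      else mapply(function(t, j, k) Qlist[[t]][j, k],
                  g$term_tidx, g$term_j, g$term_k)
    p <- c(g$fix_p, g$term_p)
    slot <- c(g$fix_slot, g$term_slot)
    coef <- c(coef_fix, coef_term)
    if (length(p)) {
      Wi <- c(Wi, as.vector(g$obsmat[, p, drop = FALSE]))
      Wj <- c(Wj, as.vector(g$colmat[, slot, drop = FALSE]))
      Wx <- c(Wx, rep(coef, each = g$n_g))
    }
    Rb <- if (structural) matrix(1, g$npos, g$npos)
      else solve(covs$E[g$o, g$o, drop = FALSE])
    idx <- which(lower.tri(Rb, diag = TRUE), arr.ind = TRUE)
    Ri <- c(Ri, as.vector(g$obsmat[, idx[, 1L], drop = FALSE]))
    Rj <- c(Rj, as.vector(g$obsmat[, idx[, 2L], drop = FALSE]))
    Rx <- c(Rx, rep(Rb[idx], each = g$n_g))
  }
  W <- Matrix::sparseMatrix(i = Wi, j = Wj, x = Wx,
                            dims = c(design$nobs, design$neq))
  Rinv <- Matrix::sparseMatrix(i = Ri, j = Rj, x = Rx,
                               dims = c(design$nobs, design$nobs),
                               symmetric = TRUE)
  list(W = W, Rinv = Rinv)
}

## relationship part of C_uu, embedded at the term offsets
.rel_part <- function(design, covs = NULL, structural = FALSE) {
  q <- design$q
  blocks <- lapply(seq_along(design$terms), function(t) {
    K <- design$terms[[t]]$rel$mat
    if (structural) {
      Kp <- K; Kp@x[] <- 1
      B <- if (design$param == "mv") matrix(1, q, q) else Matrix::Diagonal(q)
      Matrix::forceSymmetric(Matrix::kronecker(Kp, B), "L")
    } else if (design$param == "mv") {
      Sinv <- solve(covs$G[[t]])
      Matrix::forceSymmetric(Matrix::kronecker(K, Sinv), "L")
    } else {
      Matrix::forceSymmetric(Matrix::kronecker(K, Matrix::Diagonal(q)), "L")
    }
  })
  zf <- Matrix::Matrix(0, design$nfix, design$nfix, sparse = TRUE)
  Matrix::forceSymmetric(do.call(Matrix::bdiag, c(list(zf), blocks)), "L")
}

## structural zero-valued pattern of C, cached on the design
.structural_pattern <- function(design) {
  if (!is.null(design$cache$P0)) return(design$cache$P0)
  tp <- .w_rinv_triplets(design, structural = TRUE)
  Cd <- Matrix::forceSymmetric(Matrix::crossprod(tp$W, tp$Rinv %*% tp$W), "L")
  relp <- .rel_part(design, structural = TRUE)
  nfix <- design$nfix
  tri <- function(M) {
    Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    keep <- Tm@i >= Tm@j
    cbind(Tm@i[keep] + 1L, Tm@j[keep] + 1L)
  }
  td <- tri(Cd); tr <- tri(relp)
  nnz <- list(
    bb = sum(td[, 1L] <= nfix),
    bu = sum(td[, 1L] > nfix & td[, 2L] <= nfix),
    uu_data = sum(td[, 2L] > nfix),
    uu_rel = nrow(tr)
  )
  P0 <- Cd + relp
  P0@x[] <- 0
  total <- {
    Tm <- methods::as(methods::as(P0, "generalMatrix"), "TsparseMatrix")
    sum(Tm@i >= Tm@j)
  }
  nnz$total <- total
  design$cache$P0 <- list(P0 = P0, nnz = nnz)
  design$cache$P0
}

#' Assemble the mixed model equations
#'
#' Builds the coefficient matrix and right-hand side of the MME for the
#' design's parameterisation at the given covariance values.  The sparsity
#' pattern is structural (independent of the covariance values), so that
#' every derivative of `C` with respect to the working parameters has its
#' pattern contained in the pattern of `C`.
#'
#' @param design an [build_design()] object.
#' @param covs a [cov_params()].
#' @return an object of class `mme_system`: `C` (symmetric sparse lower),
#'   `rhs`, `W`, `Rinv`, equation map, parameterisation, and the structural
#'   nonzero accounts.
#' @export
assemble_mme <- function(design, covs) {
  stopifnot(inherits(design, "mme_design"), inherits(covs, "cov_params"),
            covs$q == design$q)
  param <- design$param
  Qlist <- if (param == "pc") lapply(covs$G, pc_transform)
  tp <- .w_rinv_triplets(design, covs, Qlist)
  RW <- tp$Rinv %*% tp$W
  Cdata <- Matrix::forceSymmetric(Matrix::crossprod(tp$W, RW), "L")
  relp <- .rel_part(design, covs)
  sp <- .structural_pattern(design)
  C <- Matrix::forceSymmetric(Cdata + relp, "L") + sp$P0
  rhs <- as.vector(Matrix::crossprod(tp$W, tp$Rinv %*% design$y))
  structure(list(
    param = param, C = C, rhs = rhs, W = tp$W, Rinv = tp$Rinv,
    y = design$y, neq = design$neq, nfix = design$nfix,
    eqmap = design$eqmap, covs = covs, Qlist = Qlist,
    nnz = sp$nnz
  ), class = "mme_system")
}

#' @export
print.mme_system <- function(x, ...) {
  cat("<mme_system> param:", x$param, " neq:", x$neq,
      " nnz(C, lower):", x$nnz$total, "\n")
  invisible(x)
}

#' Nonzero accounting of an assembled system
#'
#' Structural lower-triangle nonzero counts of the coefficient matrix, total
#' and per block: fixed-by-fixed, fixed-by-random, the data part of the
#' random-by-random block, and its relationship part (each off-diagonal
#' element of the inverse relationship matrix contributes a `q x q` block
#' under MV but only `q` entries under PC).
#'
#' @param sys an [assemble_mme()] result.
#' @return a tibble with columns `block` and `nnz`.
#' @export
nnz_accounting <- function(sys) {
  tibble::tibble(
    block = c("Cbb", "Cbu", "Cuu_data", "Cuu_rel", "total"),
    nnz = as.numeric(c(sys$nnz$bb, sys$nnz$bu, sys$nnz$uu_data,
                       sys$nnz$uu_rel, sys$nnz$total))
  )
}

#' Solve an assembled system
#'
#' @param sys an [assemble_mme()] result.
#' @return list with the sparse Cholesky factor (`fct`) and the solution
#'   vector (`x`): fixed effects first, then random terms ordered
#'   traits/components within individuals.
#' @export
solve_mme <- function(sys) {
  fct <- chol_factor(sys$C, eqmap = sys$eqmap)
  list(fct = fct, x = chol_solve(fct, sys$rhs))
}
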