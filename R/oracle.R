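## Dense brute-force oracles: direct evaluation of the REML likelihood, its
## gradient (by central finite differences) and the average-information
## matrix through V = Z (K (x) Sigma_u) Z' + R and the projection matrix
## P = V^-1 - V^-1 X (X' V^-1 X)^- X' V^-1, independent of the sparse MME
## path.  Only feasible for small systems; used for verification.

#' Dense model matrices for the oracle path
#'
#' @param design an [build_design()] object.
#' @return list with dense `X`, per-term dense `Z` and relationship `K`
#'   matrices, and the observation covariance builder.
#' @export
oracle_context <- function(design) {
  nobs <- design$nobs
  X <- matrix(0, nobs, design$nfix)
  for (f in seq_len(ncol(design$fxmat))) {
    ok <- !is.na(design$fxmat[, f])
    X[cbind(which(ok), design$fxmat[ok, f])] <- 1
  }
  q <- design$q
  Zs <- lapply(design$terms, function(tt) {
    Z <- matrix(0, nobs, tt$N * q)
    lv <- tt$lvl[design$obs_rec]
    ok <- !is.na(lv)
    Z[cbind(which(ok), (lv[ok] - 1L) * q + design$obs_trait[ok])] <- 1
    Z
  })
  Ks <- lapply(design$terms, function(tt) solve(as.matrix(tt$rel$mat)))
  list(X = X, Z = Zs, K = Ks, nobs = nobs)
}

.oracle_R <- function(design, covs) {
  Rb <- matrix(0, design$nobs, design$nobs)
  for (g in design$groups) {
    Eo <- covs$E[g$o, g$o, drop = FALSE]
    for (r in seq_len(g$n_g)) {
      idx <- g$obsmat[r, ]
      Rb[idx, idx] <- Eo
    }
  }
  Rb
}

.oracle_V <- function(design, covs, ctx) {
  V <- .oracle_R(design, covs)
  for (t in seq_along(design$terms)) {
    G <- kronecker(ctx$K[[t]], covs$G[[t]])
    V <- V + ctx$Z[[t]] %*% G %*% t(ctx$Z[[t]])
  }
  (V + t(V)) / 2
}

#' Dense REML likelihood (oracle)
#'
#' Evaluates `-2 logL = log|V| + log|X'V^{-1}X| + y'Py` (constant dropped),
#' the same quantity [loglik_mme()] computes through the MME.
#'
#' @param design an [build_design()] object (small instances only).
#' @param covs a [cov_params()].
#' @param ctx optional precomputed [oracle_context()].
#' @return scalar `-2 logL`.
#' @export
oracle_loglik <- function(design, covs, ctx = oracle_context(design)) {
  V <- .oracle_V(design, covs, ctx)
  Vi <- solve(V)
  XtViX <- t(ctx$X) %*% Vi %*% ctx$X
  P <- Vi - Vi %*% ctx$X %*% solve(XtViX, t(ctx$X) %*% Vi)
  y <- design$y
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(y) %*% P %*% y)
}

#' Dense projection matrix P (oracle)
#'
#' @inheritParams oracle_loglik
#' @return dense `P = V^{-1} - V^{-1}X (X'V^{-1}X)^- X'V^{-1}`.
#' @export
oracle_P <- function(design, covs, ctx = oracle_context(design)) {
  V <- .oracle_V(design, covs, ctx)
  Vi <- solve(V)
  XtViX <- t(ctx$X) %*% Vi %*% ctx$X
  P <- Vi - Vi %*% ctx$X %*% solve(XtViX, t(ctx$X) %*% Vi)
  (P + t(P)) / 2
}

#' Finite-difference gradient of the dense likelihood (oracle)
#'
#' Central finite differences of [oracle_loglik()] over the working
#' (Cholesky-log) parameter vector.
#'
#' @inheritParams oracle_loglik
#' @param h step size.
#' @return numeric gradient of `-2 logL` over `theta`.
#' @export
oracle_gradient_fd <- function(design, covs, h = 1e-5,
                               ctx = oracle_context(design)) {
  theta <- theta_pack(covs)
  nms <- names(design$terms)
  vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (oracle_loglik(design, theta_unpack(tp, design$q, nms), ctx) -
       oracle_loglik(design, theta_unpack(tm, design$q, nms), ctx)) / (2 * h)
  }, 0)
}

## dense dV/dtheta_k
.oracle_dV <- function(design, covs, ctx, mt, i, j) {
  q <- design$q
  if (mt == ".residual") {
    Le <- t(chol(covs$E))
    Ek <- .dL_elem(Le, i, j)
    dE <- Ek %*% t(Le) + Le %*% t(Ek)
    dR <- matrix(0, design$nobs, design$nobs)
    for (g in design$groups) {
      dEo <- dE[g$o, g$o, drop = FALSE]
      for (r in seq_len(g$n_g)) {
        idx <- g$obsmat[r, ]
        dR[idx, idx] <- dEo
      }
    }
    dR
  } else {
    t0 <- match(mt, names(design$terms))
    L <- t(chol(covs$G[[t0]]))
    Ek <- .dL_elem(L, i, j)
    dS <- Ek %*% t(L) + L %*% t(Ek)
    ctx$Z[[t0]] %*% kronecker(ctx$K[[t0]], dS) %*% t(ctx$Z[[t0]])
  }
}

#' Dense average-information matrix (oracle)
#'
#' Direct evaluation of `AI_ij = (1/2) y'P (dV/di) P (dV/dj) P y` with dense
#' `P` and `dV`.
#'
#' @inheritParams oracle_loglik
#' @return dense symmetric matrix over the working parameters.
#' @export
oracle_ai <- function(design, covs, ctx = oracle_context(design)) {
  P <- oracle_P(design, covs, ctx)
  Py <- as.vector(P %*% design$y)
  pt <- param_table(design$q, names(design$terms))
  Fs <- lapply(seq_len(nrow(pt)), function(k) {
    dV <- .oracle_dV(design, covs, ctx, pt$matrix[k], pt$row[k], pt$col[k])
    as.vector(dV %*% Py)
  })
  Fm <- do.call(cbind, Fs)
  AI <- 0.5 * t(Fm) %*% P %*% Fm
  (AI + t(AI)) / 2
}

#' Dense GLS / BLUP solutions (oracle)
#'
#' @inheritParams oracle_loglik
#' @return list with fixed-effect estimates `beta` and per-term random
#'   solutions `u` (ordered traits within individuals).
#' @export
oracle_gls <- function(design, covs, ctx = oracle_context(design)) {
  V <- .oracle_V(design, covs, ctx)
  Vi <- solve(V)
  XtViX <- t(ctx$X) %*% Vi %*% ctx$X
  beta <- solve(XtViX, t(ctx$X) %*% Vi %*% design$y)
  r <- design$y - ctx$X %*% beta
  u <- lapply(seq_along(design$terms), function(t) {
    G <- kronecker(ctx$K[[t]], covs$G[[t]])
    as.vector(G %*% t(ctx$Z[[t]]) %*% Vi %*% r)
  })
  names(u) <- names(design$terms)
  list(beta = as.vector(beta), u = u)
}
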