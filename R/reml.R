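## The average-information REML engine.
##
## -2 logL (constant dropped) is evaluated from the MME as
##   log|R| + sum_t [ q log|K_t| + N_t log|Sigma_t| ] + log|C| + y'Py   (MV)
##   log|R| + sum_t   q log|K_t|                      + log|C*| + y'P*y (PC)
## with y'Py = y'R^-1 y - rhs' x.  First derivatives combine tr(R^-1 dR),
## N tr(Sigma^-1 dSigma), tr(C^-1 dC) (via the Takahashi inverse subset) and
## the derivative of the data quadratic expressed through the MME solution.
## Under PC the relationship part H^-1 (x) I_q does not depend on the
## genetic parameters, so their derivatives touch only the data part of the
## coefficient matrix.  The average-information matrix is
## AI_ij = (1/2) f_i' P f_j with f_i = (dV/dtheta_i) Py, each P f obtained by
## one extra MME solve on the current factorisation.

#' Evaluate the REML log-likelihood through the mixed model equations
#'
#' @param design an [build_design()] object.
#' @param covs a [cov_params()].
#' @return an object of class `reml_eval` with `-2 logL` (`m2ll`), its
#'   components, the assembled system, its Cholesky factor, the solution
#'   vector and the working residual `t = R^{-1}(y - W x)`.
#' @export
loglik_mme <- function(design, covs) {
  sys <- assemble_mme(design, covs)
  sol <- solve_mme(sys)
  x <- sol$x
  fct <- sol$fct
  Riy <- as.vector(sys$Rinv %*% design$y)
  yPy <- sum(design$y * Riy) - sum(sys$rhs * x)
  logR <- 0
  for (g in design$groups) {
    logR <- logR + g$n_g *
      as.numeric(determinant(covs$E[g$o, g$o, drop = FALSE],
                             logarithm = TRUE)$modulus)
  }
  relterm <- 0
  for (t in seq_along(design$terms)) {
    tt <- design$terms[[t]]
    relterm <- relterm + design$q * rel_logdet_K(tt$rel)
    if (design$param == "mv") {
      relterm <- relterm + tt$N *
        as.numeric(determinant(covs$G[[t]], logarithm = TRUE)$modulus)
    }
  }
  resid <- design$y - as.vector(sys$W %*% x)
  tvec <- as.vector(sys$Rinv %*% resid)
  structure(list(
    m2ll = logR + relterm + chol_logdet(fct) + yPy,
    yPy = yPy, logdetC = chol_logdet(fct), logR = logR, relterm = relterm,
    sys = sys, fct = fct, x = x, tvec = tvec
  ), class = "reml_eval")
}

## gathered q x q blocks of C^{-1} weighted by the inverse relationship
## matrix: T[s,t] = sum_{a,b} Kinv[a,b] Cinv[eq(a,s), eq(b,t)]
.gather_T <- function(inv, Kmat, offset, q) {
  Tm <- methods::as(Kmat, "TsparseMatrix")  # symmetric: lower triplets
  ka <- pmax(Tm@i, Tm@j) + 1L
  kb <- pmin(Tm@i, Tm@j) + 1L
  kx <- Tm@x
  nk <- length(kx)
  er <- offset + (ka - 1L) * q
  ec <- offset + (kb - 1L) * q
  rows <- rep(er, each = q * q) + rep(seq_len(q), times = q)
  cols <- rep(ec, each = q * q) + rep(seq_len(q), each = q)
  vals <- cinv_elements(inv, rows, cols)
  A <- matrix(vals, q * q, nk)  # column k = vec of block (a_k, b_k), [s,t]
  dg <- ka == kb
  Td <- matrix(A[, dg, drop = FALSE] %*% kx[dg], q, q)
  To <- matrix(A[, !dg, drop = FALSE] %*% kx[!dg], q, q)
  Td + To + t(To)
}

## per-group iterate context shared by all gradient terms
.group_context <- function(design, covs, ev, inv) {
  param <- design$param
  Qlist <- ev$sys$Qlist
  lapply(design$groups, function(g) {
    m <- g$m
    pairs_r <- g$colmat[, rep(seq_len(m), times = m), drop = FALSE]
    pairs_c <- g$colmat[, rep(seq_len(m), each = m), drop = FALSE]
    vals <- cinv_elements(inv, as.vector(pairs_r), as.vector(pairs_c))
    Gsum <- matrix(colSums(matrix(vals, nrow = g$n_g)), m, m)
    A <- .group_template(g, Qlist, param)
    Rb <- solve(covs$E[g$o, g$o, drop = FALSE])
    Tg <- matrix(ev$tvec[g$obsmat], nrow = g$n_g)
    Xc <- matrix(ev$x[g$colmat], nrow = g$n_g)
    list(g = g, Gsum = Gsum, A = A, Rb = Rb, B2 = t(A) %*% Rb,
         Tg = Tg, Xc = Xc)
  })
}

#' Gradient and average-information matrix at the current evaluation
#'
#' Computes the first derivatives of `-2 logL` with respect to the working
#' (Cholesky-log) parameters and the average-information matrix of `logL`,
#' reusing the Cholesky factor of the evaluation.
#'
#' @param design an [build_design()] object.
#' @param covs a [cov_params()].
#' @param ev the matching [loglik_mme()] evaluation.
#' @return list with `grad` (of `-2 logL`), `AI` (average information of
#'   `logL`, symmetric PSD) and the parameter table.
#' @export
reml_derivatives <- function(design, covs, ev) {
  q <- design$q
  param <- design$param
  terms <- design$terms
  nterm <- length(terms)
  pt <- param_table(q, names(terms))
  npar <- nrow(pt)
  Lg <- lapply(covs$G, function(S) t(chol(S)))
  Le <- t(chol(covs$E))
  Sinv_g <- lapply(covs$G, solve)
  inv <- inverse_subset(ev$fct)
  ctx <- .group_context(design, covs, ev, inv)
  grad <- numeric(npar)
  Fmat <- matrix(0, design$nobs, npar)

  ## term-level shared quantities
  Ulist <- lapply(seq_len(nterm), function(t) {
    tt <- terms[[t]]
    matrix(ev$x[tt$offset + seq_len(tt$N * q)], nrow = q)
  })
  lvl_obs <- lapply(terms, function(tt) tt$lvl[design$obs_rec])

  if (param == "mv") {
    Tlist <- lapply(seq_len(nterm), function(t) {
      .gather_T(inv, terms[[t]]$rel$mat, terms[[t]]$offset, q)
    })
    UKU <- lapply(seq_len(nterm), function(t) {
      UK <- Ulist[[t]] %*% terms[[t]]$rel$mat  # q x N
      as.matrix(UK %*% t(Ulist[[t]]))
    })
  }

  for (p in seq_len(npar)) {
    mt <- pt$matrix[p]; i <- pt$row[p]; j <- pt$col[p]
    if (mt == ".residual") {
      Ek <- .dL_elem(Le, i, j)
      dE <- Ek %*% t(Le) + Le %*% t(Ek)
      gval <- 0
      for (cx in ctx) {
        o <- cx$g$o
        dRo <- dE[o, o, drop = FALSE]
        Ko <- cx$Rb %*% dRo %*% cx$Rb
        gval <- gval + cx$g$n_g * sum(cx$Rb * dRo)           # d log|R|
        gval <- gval - sum(cx$Gsum * (t(cx$A) %*% Ko %*% cx$A)) # tr(C^-1 dC)
        gval <- gval - sum((cx$Tg %*% dRo) * cx$Tg)           # d y'Py
        Fg <- cx$Tg %*% dRo
        Fmat[as.vector(cx$g$obsmat), p] <- as.vector(Fg)
      }
      grad[p] <- gval
    } else {
      tm <- match(mt, names(terms))
      Ek <- .dL_elem(Lg[[tm]], i, j)
      dS <- Ek %*% t(Lg[[tm]]) + Lg[[tm]] %*% t(Ek)
      if (param == "mv") {
        dSinv <- -Sinv_g[[tm]] %*% dS %*% Sinv_g[[tm]]
        grad[p] <- terms[[tm]]$N * sum(Sinv_g[[tm]] * dS) +
          sum(Tlist[[tm]] * dSinv) + sum(UKU[[tm]] * dSinv)
        Bmat <- dS %*% Sinv_g[[tm]]
      } else {
        escale <- if (i == j) Lg[[tm]][j, j] else 1
        gval <- 0
        for (cx in ctx) {
          g <- cx$g
          if (!(tm %in% g$slot_t)) next
          pos_i <- match(i, g$o)
          if (is.na(pos_i)) next                 # trait i unobserved here
          slot_j <- g$m_fix + which(g$slot_t == tm & g$slot_k == j)
          if (!length(slot_j)) next
          gval <- gval + 2 * escale *
            sum(cx$Gsum[, slot_j] * cx$B2[, pos_i]) # tr(C^-1 dC)
          gval <- gval - 2 * escale *
            sum(cx$Tg[, pos_i] * cx$Xc[, slot_j])   # d y'Py
        }
        grad[p] <- gval
        Q <- Lg[[tm]]
        Bmat <- Ek + Q %*% t(Ek) %*% solve(t(Q))
      }
      ## F column: f = Z_t (I (x) Bmat) u_t, rows picked by (trait, level)
      BU <- Bmat %*% Ulist[[tm]]
      lv <- lvl_obs[[tm]]
      ok <- !is.na(lv)
      Fmat[ok, p] <- BU[cbind(design$obs_trait[ok], lv[ok])]
    }
  }

  RiF <- as.matrix(ev$sys$Rinv %*% Fmat)
  XF <- as.matrix(Matrix::crossprod(ev$sys$W, RiF))
  Xsol <- chol_solve(ev$fct, XF)
  AI <- 0.5 * (crossprod(Fmat, RiF) - crossprod(XF, Xsol))
  AI <- (AI + t(AI)) / 2
  list(grad = grad, AI = AI, param_table = pt)
}

#' One damped Newton (AI-REML) update
#'
#' Proposes the full Newton step on the working parameters,
#' `theta + omega * AI^{-1} s` with `s = -grad(-2logL)/2` and `omega = 1`,
#' and halves `omega` (up to 10 times) until `-2 logL` does not deteriorate.
#' A numerically singular AI matrix triggers a scaled gradient-ascent step.
#'
#' @param design an [build_design()] object.
#' @param covs current [cov_params()].
#' @param ev current [loglik_mme()] evaluation (recomputed when `NULL`).
#' @param der current [reml_derivatives()] (recomputed when `NULL`).
#' @return list with updated `covs`, `theta`, `ev`, the likelihood
#'   improvement `dL` (on `-2 logL`, non-negative when accepted), the step
#'   factor `omega` used, `accepted`, and the derivatives used.
#' @export
reml_iterate <- function(design, covs, ev = NULL, der = NULL) {
  if (is.null(ev)) ev <- loglik_mme(design, covs)
  if (is.null(der)) der <- reml_derivatives(design, covs, ev)
  theta <- theta_pack(covs)
  s <- -0.5 * der$grad
  step <- tryCatch(solve(der$AI, s), error = function(e) NULL)
  fallback <- is.null(step)
  if (fallback) step <- s / max(diag(der$AI), 1e-8)
  omega <- 1
  accepted <- FALSE
  new_ev <- NULL; new_theta <- theta; new_covs <- covs
  for (h in 0:10) {
    cand <- theta + omega * step
    covc <- tryCatch(theta_unpack(cand, design$q, names(design$terms)),
                     error = function(e) NULL)
    evc <- if (is.null(covc)) NULL else
      tryCatch(loglik_mme(design, covc), error = function(e) NULL)
    if (!is.null(evc) && is.finite(evc$m2ll) &&
        evc$m2ll <= ev$m2ll + 1e-10) {
      accepted <- TRUE
      new_ev <- evc; new_theta <- cand; new_covs <- covc
      break
    }
    omega <- omega / 2
  }
  list(covs = new_covs, theta = new_theta,
       ev = if (accepted) new_ev else ev,
       dL = if (accepted) ev$m2ll - new_ev$m2ll else 0,
       omega = omega, accepted = accepted, fallback = fallback, der = der)
}

## default starting values: half the pairwise-complete phenotypic covariance
## to the residual, the other half split over the random terms
.default_start <- function(design) {
  q <- design$q
  S <- stats::cov(design$Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0.05 * max(ev$values, 1e-6))
  S <- ev$vectors %*% diag(lam, q) %*% t(ev$vectors)
  nterm <- length(design$terms)
  G <- stats::setNames(
    lapply(seq_len(nterm), function(t) 0.5 * S / nterm),
    names(design$terms)
  )
  cov_params(G, 0.5 * S)
}

#' Fit a multivariate animal model by AI-REML
#'
#' Estimates the covariance matrices of all random terms and the residual by
#' maximising the restricted likelihood with the damped average-information
#' Newton algorithm, under either the standard multivariate (`"mv"`) or the
#' principal-components (`"pc"`) parameterisation.  The two parameterisations
#' are equivalent models and converge through identical likelihood values to
#' identical estimates; they differ in the sparsity of the coefficient
#' matrix and the cost per iterate.
#'
#' @param data phenotype data (see [build_design()]).
#' @param spec a [model_spec()].
#' @param rels named list of [rel_factor] objects.
#' @param param `"mv"` or `"pc"`.
#' @param start optional [cov_params()] starting values; the default uses
#'   half the phenotypic covariance for the residual and splits the other
#'   half over the random terms.
#' @param maxit maximum number of AI-REML iterates.
#' @param tol_L convergence tolerance on the change in `-2 logL`.
#' @param tol_g convergence tolerance on the largest absolute gradient
#'   element.
#' @param verbose print iterate-level progress.
#' @return an object of class `reml_fit`; see [tidy.reml_fit()],
#'   [glance.reml_fit()] and [autoplot.reml_fit()].
#' @export
reml_fit <- function(data, spec, rels = list(), param = c("mv", "pc"),
                     start = NULL, maxit = 50L, tol_L = 5e-4, tol_g = 1e-3,
                     verbose = FALSE) {
  param <- match.arg(param)
  design <- build_design(spec, data, rels, param = param, quiet = !verbose)
  covs <- if (is.null(start)) .default_start(design) else start
  ev <- loglik_mme(design, covs)
  traj <- list()
  converged <- FALSE
  der <- NULL
  dL_last <- Inf
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    der <- reml_derivatives(design, covs, ev)
    gmax <- max(abs(der$grad))
    if (dL_last < tol_L && gmax < tol_g) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    st <- reml_iterate(design, covs, ev, der)
    traj[[it]] <- tibble::tibble(
      iter = it, m2ll = st$ev$m2ll, dL = st$dL, grad_max = gmax,
      omega = st$omega, accepted = st$accepted, fallback = st$fallback
    )
    if (verbose) {
      message(sprintf("it %2d  -2logL %.6f  dL %.3e  |g|max %.3e  omega %.3f",
                      it, st$ev$m2ll, st$dL, gmax, st$omega))
    }
    if (!st$accepted) break
    covs <- st$covs
    ev <- st$ev
    dL_last <- st$dL
  }
  der <- reml_derivatives(design, covs, ev)
  if (dL_last < tol_L && max(abs(der$grad)) < tol_g) converged <- TRUE
  AIinv <- tryCatch(solve(der$AI), error = function(e) NULL)
  se_theta <- if (!is.null(AIinv)) sqrt(pmax(diag(AIinv), 0))
  cov_se <- if (!is.null(AIinv)) .cov_scale_se(covs, AIinv, design)
  structure(list(
    estimates = covs, theta = theta_pack(covs),
    m2ll = ev$m2ll, grad = der$grad, AI = der$AI, AIinv = AIinv,
    se_theta = se_theta, se_cov = cov_se,
    trajectory = dplyr::bind_rows(traj),
    converged = converged, niter = it, param = param,
    neq = design$neq, nnz = ev$sys$nnz, nnz_L = ev$fct$nnz_L,
    traits = design$traits, term_names = names(design$terms),
    solutions = ev$x, eqmap = design$eqmap, spec = spec
  ), class = "reml_fit")
}

## delta-method standard errors on the covariance scale
.cov_scale_se <- function(covs, AIinv, design) {
  q <- design$q
  pt <- param_table(q, names(design$terms))
  npar <- nrow(pt)
  Ls <- c(lapply(covs$G, function(S) t(chol(S))), list(t(chol(covs$E))))
  mats <- c(names(covs$G), ".residual")
  J <- matrix(0, npar, npar)  # rows: vech elements; cols: theta
  vech_idx <- which(lower.tri(diag(q), diag = TRUE))
  for (p in seq_len(npar)) {
    m <- match(pt$matrix[p], mats)
    L <- Ls[[m]]
    Ek <- .dL_elem(L, pt$row[p], pt$col[p])
    dS <- Ek %*% t(L) + L %*% t(Ek)
    rows <- which(pt$matrix == pt$matrix[p])
    J[rows, p] <- dS[vech_idx]
  }
  V <- J %*% AIinv %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  ij <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    matrix = pt$matrix,
    row = design$traits[ij[rep(seq_len(nrow(ij)), length(mats)), 1L]],
    col = design$traits[ij[rep(seq_len(nrow(ij)), length(mats)), 2L]],
    se = se
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit (", x$param, " parameterisation)\n", sep = "")
  cat("  -2 logL:", format(x$m2ll, digits = 10),
      " iterates:", x$niter,
      " converged:", x$converged, "\n")
  cat("  equations:", x$neq, " nnz(C):", x$nnz$total,
      " nnz(L):", x$nnz_L, "\n")
  for (nm in names(x$estimates$G)) {
    cat("  Sigma_", nm, ":\n", sep = "")
    print(round(x$estimates$G[[nm]], 5))
  }
  cat("  Sigma_e:\n")
  print(round(x$estimates$E, 5))
  invisible(x)
}
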