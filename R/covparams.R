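## Cholesky-log parameterisation of the covariance matrices: each q x q
## covariance matrix (one per random term, plus the residual) is represented
## by the elements of its lower Cholesky factor, column-major, with the
## diagonal on the log scale.  This keeps every iterate inside the parameter
## space and is the scale on which the Newton updates operate.

#' Covariance parameter container
#'
#' @param G named list of symmetric positive definite `q x q` genetic (or
#'   other random-term) covariance matrices, one per random term and in term
#'   order.
#' @param E symmetric positive definite `q x q` residual covariance matrix.
#' @return an object of class `cov_params`.
#' @export
cov_params <- function(G, E) {
  if (is.matrix(G)) G <- list(direct = G)
  G <- lapply(G, .check_spd)
  E <- .check_spd(E)
  structure(list(G = G, E = E, q = nrow(E)), class = "cov_params")
}

.check_spd <- function(S) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix is not positive definite")
  S
}

## lower Cholesky factor, column-major packing with logged diagonal
.pack_one <- function(S) {
  L <- t(chol(S))
  q <- nrow(S)
  th <- numeric(0)
  for (j in seq_len(q)) {
    col <- L[j:q, j]
    col[1L] <- log(col[1L])
    th <- c(th, col)
  }
  th
}

.unpack_one <- function(th, q) {
  L <- matrix(0, q, q)
  pos <- 1L
  for (j in seq_len(q)) {
    k <- q - j + 1L
    col <- th[pos:(pos + k - 1L)]
    col[1L] <- exp(col[1L])
    L[j:q, j] <- col
    pos <- pos + k
  }
  L
}

#' Pack covariance matrices into the working parameter vector
#'
#' @param covs a [cov_params()].
#' @return numeric vector `theta`: Cholesky-log parameters of each random
#'   term covariance matrix in term order, then of the residual.
#' @export
theta_pack <- function(covs) {
  unlist(c(lapply(covs$G, .pack_one), list(.pack_one(covs$E))),
         use.names = FALSE)
}

#' Unpack a working parameter vector into covariance matrices
#'
#' @param theta parameter vector as produced by [theta_pack()].
#' @param q number of traits.
#' @param term_names names of the random terms.
#' @return a [cov_params()]; the Cholesky factors are attached as
#'   attribute `"L"` (list, residual last).
#' @export
theta_unpack <- function(theta, q, term_names = "direct") {
  npm <- q * (q + 1L) / 2L
  nterm <- length(term_names)
  stopifnot(length(theta) == (nterm + 1L) * npm)
  Ls <- lapply(seq_len(nterm + 1L), function(m) {
    .unpack_one(theta[(m - 1L) * npm + seq_len(npm)], q)
  })
  G <- stats::setNames(lapply(Ls[seq_len(nterm)], tcrossprod), term_names)
  out <- cov_params(G, tcrossprod(Ls[[nterm + 1L]]))
  attr(out, "L") <- Ls
  out
}

#' Parameter bookkeeping table
#'
#' One row per working parameter: which covariance matrix it belongs to
#' (random terms in order, then the residual), the `(row, col)` of the
#' Cholesky-factor element, and whether it is a (log-scale) diagonal.
#'
#' @param q number of traits.
#' @param term_names names of the random terms.
#' @return a tibble with columns `idx`, `matrix`, `row`, `col`, `diag`.
#' @export
param_table <- function(q, term_names = "direct") {
  one <- do.call(rbind, lapply(seq_len(q), function(j) {
    cbind(row = j:q, col = j)
  }))
  mats <- c(term_names, ".residual")
  out <- do.call(rbind, lapply(seq_along(mats), function(m) {
    tibble::tibble(matrix = mats[m], row = one[, "row"], col = one[, "col"],
                   diag = one[, "row"] == one[, "col"])
  }))
  out$idx <- seq_len(nrow(out))
  out[, c("idx", "matrix", "row", "col", "diag")]
}

## Elementary derivative of the Cholesky factor w.r.t. working parameter k:
## dL = e_i e_j' (off-diagonal) or l_jj e_j e_j' (logged diagonal).
.dL_elem <- function(L, i, j) {
  E <- matrix(0, nrow(L), ncol(L))
  E[i, j] <- if (i == j) L[j, j] else 1
  E
}

#' Principal-component (Cholesky) loading of a covariance matrix
#'
#' Returns the lower-triangular `Q` with `Q Q' = Sigma`, so that
#' `Q^{-1} Sigma Q^{-T} = I`: the loading that rescales genetic effects to
#' unit-variance principal-component scores in the equivalent-model
#' parameterisation.
#'
#' @param Sigma symmetric positive definite matrix.
#' @return lower-triangular matrix with strictly positive diagonal.
#' @export
pc_transform <- function(Sigma) {
  t(chol(.check_spd(Sigma)))
}
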