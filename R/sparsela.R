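## Sparse symmetric linear algebra: fill-reducing ordering, symbolic and
## numeric Cholesky factorisation, triangular solves, log-determinant, and
## the Takahashi sparse inverse subset used by the REML trace terms.
## Factorisation itself is delegated to Matrix/CHOLMOD (simplicial LL');
## the inverse subset is computed by compiled code on the factor pattern.

#' Make a positive definite proxy matrix from a sparsity pattern
#'
#' Replaces the values of a symmetric sparse matrix (or pattern matrix) with
#' ones off the diagonal and a diagonally dominant diagonal, yielding a
#' positive definite matrix with the same nonzero pattern.  Used for purely
#' structural analyses (ordering, symbolic factorisation).
#'
#' @param C a symmetric sparse matrix or pattern ("nMatrix") of class from
#'   the Matrix package.
#' @return a `dsCMatrix` with the same pattern and positive definite values.
#' @export
pattern_pd <- function(C) {
  C <- methods::as(methods::as(C, "CsparseMatrix"), "symmetricMatrix")
  Tm <- methods::as(methods::as(C, "generalMatrix"), "TsparseMatrix")
  i <- Tm@i + 1L
  j <- Tm@j + 1L
  n <- nrow(C)
  off <- i != j
  ii <- c(i[off], seq_len(n))
  jj <- c(j[off], seq_len(n))
  deg <- tabulate(i[off], nbins = n)
  xx <- c(rep(1, sum(off)), deg + n)
  keep <- ii >= jj
  Matrix::sparseMatrix(
    i = ii[keep], j = jj[keep], x = xx[keep],
    dims = c(n, n), symmetric = TRUE
  )
}

#' Fill-reducing ordering of a symmetric sparse pattern
#'
#' Returns the fill-reducing permutation CHOLMOD selects (approximate minimum
#' degree family) for a symmetric positive definite matrix with the given
#' pattern.  The permutation is 1-based: row/column `perm[k]` of the input is
#' pivot `k` of the factorisation.
#'
#' @param C symmetric sparse matrix or pattern.
#' @return integer permutation vector of length `nrow(C)`.
#' @export
reorder_amd <- function(C) {
  f <- Matrix::Cholesky(pattern_pd(C), LDL = FALSE, super = FALSE, perm = TRUE)
  f@perm + 1L
}

#' Symbolic Cholesky factorisation of a symmetric pattern
#'
#' Computes the nonzero pattern of the Cholesky factor of `C[perm, perm]`
#' using the elimination-tree recursion: the structure of column `j` of `L`
#' is the structure of column `j` of the permuted matrix united with the
#' structures of all children columns in the elimination tree.
#'
#' @param C symmetric sparse matrix or pattern.
#' @param perm 1-based permutation (default: natural order).
#' @return list with `nnz_L` (including the diagonal), `fill_in`
#'   (`nnz_L - nnz_C`), `parent` (elimination tree), and `cols` (list of
#'   row index vectors of each factor column, in permuted indices).
#' @export
symbolic_factor <- function(C, perm = seq_len(nrow(C))) {
  C <- methods::as(methods::as(C, "CsparseMatrix"), "symmetricMatrix")
  n <- nrow(C)
  stopifnot(length(perm) == n, !anyDuplicated(perm))
  Tm <- methods::as(methods::as(C, "generalMatrix"), "TsparseMatrix")
  ip <- integer(n); ip[perm] <- seq_len(n)
  i <- ip[Tm@i + 1L]
  j <- ip[Tm@j + 1L]
  low <- i > j
  adj <- split(i[low], factor(j[low], levels = seq_len(n)))
  cols <- vector("list", n)
  parent <- integer(n)
  children <- vector("list", n)
  nnz_low <- sum(low)
  for (jj in seq_len(n)) {
    s <- adj[[jj]]
    for (ch in children[[jj]]) {
      sc <- cols[[ch]]
      s <- c(s, sc[sc != jj])
    }
    s <- sort(unique(s))
    cols[[jj]] <- s
    if (length(s)) {
      p <- s[1L]
      parent[jj] <- p
      children[[p]] <- c(children[[p]], jj)
    }
  }
  nnz_L <- n + sum(lengths(cols))
  list(nnz_L = nnz_L, fill_in = nnz_L - (n + nnz_low),
       parent = parent, cols = cols)
}

#' Sparse Cholesky factorisation
#'
#' Factors a symmetric positive definite sparse matrix as
#' `C[perm, perm] = L L'` using a simplicial CHOLMOD factorisation with a
#' fill-reducing ordering (or the natural order when `perm = FALSE`).
#'
#' @param C symmetric positive definite sparse matrix (`dsCMatrix` or
#'   coercible).
#' @param perm logical; use a fill-reducing ordering (default `TRUE`).
#' @param eqmap optional data frame describing the equations (used to name
#'   the offending equation if the matrix is found indefinite).
#' @return an object of class `chol_factor`: list with the CHOLMOD factor
#'   `f`, the lower-triangular factor `L` (`dtCMatrix`), 1-based permutation
#'   `perm`, `logdet` (log-determinant of `C`), `nnz_L`, and `n`.
#' @export
chol_factor <- function(C, perm = TRUE, eqmap = NULL) {
  C <- methods::as(methods::as(C, "CsparseMatrix"), "symmetricMatrix")
  f <- tryCatch(
    Matrix::Cholesky(C, LDL = FALSE, super = FALSE, perm = perm),
    error = function(e) e
  )
  if (inherits(f, "error")) {
    piv <- .find_bad_pivot(C)
    lab <- if (!is.null(eqmap) && !is.na(piv) && piv <= nrow(eqmap)) {
      paste0(" (equation ", piv, ": ",
             paste(unlist(eqmap[piv, ]), collapse = "/"), ")")
    } else if (!is.na(piv)) paste0(" (equation ", piv, ")") else ""
    stop("matrix is not positive definite", lab, call. = FALSE)
  }
  L <- methods::as(f, "Matrix")
  structure(
    list(f = f, L = L, perm = f@perm + 1L,
         logdet = 2 * sum(log(Matrix::diag(L))),
         nnz_L = length(L@x), n = nrow(C)),
    class = "chol_factor"
  )
}

## locate the first non-positive pivot by dense factorisation (small systems)
.find_bad_pivot <- function(C) {
  n <- nrow(C)
  if (n > 2000L) return(NA_integer_)
  M <- as.matrix(C)
  r <- tryCatch(chol(M), error = function(e) conditionMessage(e))
  if (is.character(r)) {
    k <- suppressWarnings(as.integer(sub(".*order (\\d+).*", "\\1", r)))
    return(k)
  }
  NA_integer_
}

#' Solve a linear system from a sparse Cholesky factor
#'
#' @param fct a `chol_factor`.
#' @param b right-hand side vector or matrix.
#' @return the solution of `C x = b` as a base vector or matrix.
#' @export
chol_solve <- function(fct, b) {
  x <- Matrix::solve(fct$f, b, system = "A")
  if (is.null(dim(b))) drop(as.matrix(x)) else as.matrix(x)
}

#' Log-determinant from a sparse Cholesky factor
#'
#' @param fct a `chol_factor`.
#' @return `log det C` as a scalar.
#' @export
chol_logdet <- function(fct) fct$logdet

#' Sparse inverse subset (Takahashi recursion)
#'
#' Computes the elements of `C^{-1}` at all positions of the Cholesky-factor
#' pattern (which contains the pattern of `C`) by the Takahashi
#' (Erisman-Tinney) backward recursion over the factor.  Only these selected
#' elements are computed; the full inverse is never formed.
#'
#' @param fct a `chol_factor`.
#' @return an object of class `inv_subset` supporting [cinv_elements()] and
#'   [trace_cinv()].
#' @export
inverse_subset <- function(fct) {
  L <- fct$L
  Sx <- .takahashi_inverse(L@p, L@i, L@x, fct$n)
  invperm <- integer(fct$n)
  invperm[fct$perm] <- seq_len(fct$n) - 1L  # 0-based permuted position
  structure(
    list(Lp = L@p, Li = L@i, Sx = Sx, invperm = invperm, n = fct$n),
    class = "inv_subset"
  )
}

#' Extract selected elements of the inverse
#'
#' @param inv an `inv_subset`.
#' @param rows,cols integer vectors of equal length; 1-based positions in the
#'   original (unpermuted) ordering.  Every requested position must lie in
#'   the factor pattern.
#' @return numeric vector of `C^{-1}[rows, cols]` elementwise.
#' @export
cinv_elements <- function(inv, rows, cols) {
  .cinv_gather(inv$Lp, inv$Li, inv$Sx, inv$invperm,
               as.integer(rows), as.integer(cols))
}

#' Trace of `C^{-1} M` from an inverse subset
#'
#' Computes `tr(C^{-1} M)` for a sparse matrix `M` whose pattern is contained
#' in the factor pattern of `C` (which always holds when the pattern of `M`
#' is contained in the pattern of `C`).  Positions of `M` outside the factor
#' pattern raise an error rather than being treated as zero.
#'
#' @param inv an `inv_subset`.
#' @param M sparse (symmetric or general) matrix.
#' @return scalar trace.
#' @export
trace_cinv <- function(inv, M) {
  Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  if (length(Tm@x) == 0L) return(0)
  s <- cinv_elements(inv, Tm@i + 1L, Tm@j + 1L)
  sum(s * Tm@x)
}
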