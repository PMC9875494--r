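## Pedigree handling and pedigree-based relationship structures:
## topological validation, exact inbreeding coefficients (Meuwissen-Luo),
## the sparse inverse numerator relationship matrix by Henderson's rules,
## and the A22 submatrix for a genotyped subset (via sparse solves).

#' Construct and validate a pedigree
#'
#' Takes a data frame whose first three columns are animal, sire and dam
#' identifiers (`0` or `NA` denoting an unknown parent), remaps identifiers
#' to consecutive integers `1..N`, and verifies that the pedigree is
#' topologically ordered (or can be reordered) with no animal its own
#' ancestor.
#'
#' @param df data frame with columns animal, sire, dam (further columns are
#'   retained).
#' @return a `pedigree` object: a tibble with integer columns `id`, `sire`,
#'   `dam` (0 = unknown) and a `label` column holding the original
#'   identifiers.
#' @export
as_pedigree <- function(df) {
  if (inherits(df, "pedigree")) return(df)
  stopifnot(is.data.frame(df), ncol(df) >= 3L)
  an <- df[[1L]]
  si <- df[[2L]]
  da <- df[[3L]]
  norm_id <- function(x) {
    x <- as.vector(x)
    x[is.na(x)] <- 0L
    x[x %in% c("0", "NA", "")] <- 0L
    x
  }
  an <- norm_id(an); si <- norm_id(si); da <- norm_id(da)
  if (anyDuplicated(an)) {
    stop("duplicated animal id in pedigree: ", an[duplicated(an)][1L])
  }
  if (length(an) < 1L) stop("pedigree must contain at least one animal")
  known <- function(p) !(p %in% c(0L, "0"))
  miss <- setdiff(c(si[known(si)], da[known(da)]), an)
  if (length(miss)) {
    stop("parent id(s) not present as animals: ", paste(utils::head(miss, 5L),
                                                        collapse = ", "))
  }
  n <- length(an)
  ord <- .topo_order(an, si, da)
  an <- an[ord]; si <- si[ord]; da <- da[ord]
  idx <- stats::setNames(seq_len(n), as.character(an))
  map <- function(p) {
    out <- integer(length(p))
    k <- known(p)
    out[k] <- idx[as.character(p[k])]
    out
  }
  ped <- tibble::tibble(
    id = seq_len(n), sire = map(si), dam = map(da),
    label = an
  )
  extra <- df[ord, -(1:3), drop = FALSE]
  if (ncol(extra)) ped <- dplyr::bind_cols(ped, tibble::as_tibble(extra))
  if (any(ped$sire >= ped$id) || any(ped$dam >= ped$id)) {
    bad <- ped$label[which(ped$sire >= ped$id | ped$dam >= ped$id)[1L]]
    stop("pedigree cannot be topologically ordered at animal ", bad)
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

## Kahn-style topological sort over the parent relation; errors on cycles
.topo_order <- function(an, si, da) {
  n <- length(an)
  idx <- stats::setNames(seq_len(n), as.character(an))
  get <- function(p) {
    out <- rep(0L, n)
    k <- !(p %in% c(0L, "0"))
    out[k] <- idx[as.character(p[k])]
    out
  }
  s <- get(si); d <- get(da)
  if (all(s < seq_len(n)) && all(d < seq_len(n))) return(seq_len(n))
  indeg <- integer(n)
  ch <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        ch[[p]] <- c(ch[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in ch[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    bad <- setdiff(seq_len(n), out)[1L]
    stop("cyclic pedigree: animal ", an[bad], " is its own ancestor")
  }
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes exact inbreeding coefficients `F` for every animal by
#' accumulating the diagonal of the numerator relationship matrix,
#' `a_ii = sum_j x_j^2 d_j`, over each animal's ancestors, where `x` is the
#' row of the gametic-flow matrix and `d_j` the Mendelian sampling variance.
#'
#' @param ped a `pedigree` (or data frame coercible with [as_pedigree()]).
#' @return numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  sire <- ped$sire; dam <- ped$dam
  Fi <- numeric(n)
  dmv <- numeric(n)  # Mendelian sampling variance, with F(unknown) = -1
  x <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (sire[i] > 0L) Fi[sire[i]] else -1
    fd <- if (dam[i] > 0L) Fi[dam[i]] else -1
    dmv[i] <- 0.5 - 0.25 * (fs + fd)
    if (sire[i] == 0L || dam[i] == 0L) {
      Fi[i] <- 0
      next
    }
    touched <- i
    x[i] <- 1
    aii <- 0
    active <- i  # unprocessed ancestors; processed in decreasing id order
    while (length(active)) {
      j <- max(active)
      active <- active[active != j]
      xj <- x[j]
      for (p in c(sire[j], dam[j])) {
        if (p > 0L) {
          if (x[p] == 0) {
            touched <- c(touched, p)
            active <- c(active, p)
          }
          x[p] <- x[p] + 0.5 * xj
        }
      }
      aii <- aii + xj * xj * dmv[j]
    }
    Fi[i] <- aii - 1
    x[touched] <- 0
  }
  Fi
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Builds the sparse inverse of the tabular numerator relationship matrix
#' `A`, accounting exactly for inbreeding via the Meuwissen-Luo recursion.
#' Only diagonal, parent-offspring and mate-pair positions are nonzero.
#'
#' @param ped a `pedigree`.
#' @return a [rel_factor] of kind `"pedigree-inverse"`.
#' @export
build_A_inverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  sire <- ped$sire; dam <- ped$dam
  Fi <- inbreeding(ped)
  fs <- rep(-1, n); fs[sire > 0L] <- Fi[sire[sire > 0L]]
  fd <- rep(-1, n); fd[dam > 0L] <- Fi[dam[dam > 0L]]
  alpha <- 1 / (0.5 - 0.25 * (fs + fd))
  anim <- seq_len(n)
  ii <- anim; jj <- anim; xx <- alpha
  hs <- sire > 0L; hd <- dam > 0L
  add <- function(i, j, x) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    ii <<- c(ii, hi); jj <<- c(jj, lo); xx <<- c(xx, x)
  }
  add(sire[hs], anim[hs], -alpha[hs] / 2)
  add(sire[hs], sire[hs], alpha[hs] / 4)
  add(dam[hd], anim[hd], -alpha[hd] / 2)
  add(dam[hd], dam[hd], alpha[hd] / 4)
  hb <- hs & hd
  add(sire[hb], dam[hb], alpha[hb] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = TRUE)
  rel_factor(M, kind = "pedigree-inverse", labels = ped$label)
}

#' Relationship submatrix for a genotyped subset (A22)
#'
#' Extracts the submatrix of the tabular numerator relationship matrix for a
#' set of (genotyped) animals without forming the full dense `A`: columns of
#' `A` are obtained by sparse solves with `A^{-1}`.
#'
#' @param ped a `pedigree`.
#' @param geno_ids identifiers (labels) of the genotyped animals.
#' @return dense symmetric matrix with `dimnames` equal to `geno_ids`.
#' @export
build_A22 <- function(ped, geno_ids) {
  ped <- as_pedigree(ped)
  rows <- match(geno_ids, ped$label)
  if (anyNA(rows)) {
    stop("genotyped id(s) not in pedigree: ",
         paste(utils::head(geno_ids[is.na(rows)], 5L), collapse = ", "))
  }
  Ainv <- build_A_inverse(ped)
  fct <- chol_factor(Ainv$mat)
  m <- length(rows)
  S <- Matrix::sparseMatrix(i = rows, j = seq_len(m), x = 1,
                            dims = c(nrow(ped), m))
  Y <- chol_solve(fct, S)
  A22 <- as.matrix(Y[rows, , drop = FALSE])
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(as.character(geno_ids), as.character(geno_ids))
  A22
}

#' Tabular numerator relationship matrix (dense oracle)
#'
#' Direct recursive (tabular-method) construction of `A`; quadratic in the
#' number of animals, intended for verification on small pedigrees.
#'
#' @param ped a `pedigree`.
#' @return dense symmetric `N x N` matrix.
#' @export
tabular_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  dimnames(A) <- list(ped$label, ped$label)
  A
}

#' Sparse symmetric relationship-factor container
#'
#' Light container for (inverses of) relationship matrices used in the mixed
#' model: the pedigree-based `A^{-1}`, the single-step `H^{-1}`, or an
#' identity (e.g. for permanent environmental effects).  Stores the matrix as
#' a symmetric sparse `dsCMatrix` plus the level labels, and caches
#' `log|K| = -log|K^{-1}|` on demand.
#'
#' @param mat symmetric sparse matrix (the *inverse* relationship matrix).
#' @param kind one of `"pedigree-inverse"`, `"joint-inverse"`, `"identity"`.
#' @param labels level labels (animal identifiers).
#' @return an object of class `rel_factor`.
#' @export
rel_factor <- function(mat, kind = c("pedigree-inverse", "joint-inverse",
                                     "identity"),
                       labels = NULL) {
  kind <- match.arg(kind)
  mat <- methods::as(methods::as(mat, "CsparseMatrix"), "symmetricMatrix")
  if (is.null(labels)) labels <- seq_len(nrow(mat))
  stopifnot(length(labels) == nrow(mat))
  cache <- new.env(parent = emptyenv())
  structure(list(mat = mat, kind = kind, labels = labels,
                 n = nrow(mat), cache = cache),
            class = "rel_factor")
}

#' Identity relationship factor
#'
#' @param labels level labels.
#' @return a `rel_factor` of kind `"identity"`.
#' @export
rel_identity <- function(labels) {
  n <- length(labels)
  rel_factor(Matrix::Diagonal(n, 1), kind = "identity", labels = labels)
}

#' Log-determinant of the relationship matrix `K`
#'
#' Returns `log|K|` for the relationship matrix whose inverse is stored in a
#' [rel_factor], computed once via sparse Cholesky of `K^{-1}` and cached.
#'
#' @param rf a `rel_factor`.
#' @return scalar `log|K|`.
#' @export
rel_logdet_K <- function(rf) {
  if (rf$kind == "identity") return(0)
  if (is.null(rf$cache$logdetK)) {
    rf$cache$logdetK <- -chol_logdet(chol_factor(rf$mat))
  }
  rf$cache$logdetK
}

#' @export
print.rel_factor <- function(x, ...) {
  cat("<rel_factor> kind:", x$kind, " n:", x$n,
      " nnz (lower):", length(x$mat@x), "\n")
  invisible(x)
}
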