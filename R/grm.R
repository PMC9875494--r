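## Genomic relationship structures: VanRaden Method 1 GRM, alignment of G
## with the pedigree-based A22 (Vitezica-style regression on means), and
## assembly of the single-step joint inverse H^{-1}.

#' Construct a genotype container
#'
#' @param counts integer matrix of allele counts in \{0, 1, 2\},
#'   individuals in rows (rownames = identifiers), SNPs in columns; or a data
#'   frame whose first column holds identifiers.  Missing calls are rejected.
#' @param ids optional identifier vector overriding rownames.
#' @return an object of class `genotypes`: list with `ids`, integer matrix
#'   `counts`, and per-SNP observed allele frequencies `freq`.
#' @export
as_genotypes <- function(counts, ids = NULL) {
  if (inherits(counts, "genotypes")) return(counts)
  if (is.data.frame(counts)) {
    ids <- counts[[1L]]
    counts <- as.matrix(counts[, -1L, drop = FALSE])
  }
  if (is.null(ids)) ids <- rownames(counts)
  if (is.null(ids)) stop("genotype ids missing (no rownames / id column)")
  storage.mode(counts) <- "integer"
  if (anyNA(counts)) {
    stop("missing genotype calls are not supported; impute or drop them first")
  }
  if (length(counts) && (min(counts) < 0L || max(counts) > 2L)) {
    stop("allele counts must lie in {0, 1, 2}")
  }
  rownames(counts) <- as.character(ids)
  freq <- if (nrow(counts)) colMeans(counts) / 2 else numeric(0)
  structure(list(ids = ids, counts = counts, freq = freq),
            class = "genotypes")
}

#' Genomic relationship matrix (VanRaden Method 1)
#'
#' Builds `G = M M' / (2 * sum_i p_i (1 - p_i))` where `M` holds allele
#' counts centred by twice the observed allele frequency, summing over the
#' SNPs retained by the minor-allele-frequency filter.  Frequencies are
#' computed on all SNPs first, then SNPs with MAF strictly below `maf_min`
#' are excluded from both `M` and the denominator.
#'
#' @param geno a `genotypes` object (or coercible).
#' @param maf_min minimum minor allele frequency; SNPs with MAF `< maf_min`
#'   are excluded (a SNP at exactly `maf_min` is retained).
#' @return dense symmetric matrix with identifiers as dimnames.
#' @export
build_grm <- function(geno, maf_min = 0.02) {
  geno <- as_genotypes(geno)
  p <- geno$freq
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  if (!any(keep)) stop("no SNPs pass the MAF filter (maf_min = ", maf_min, ")")
  M <- sweep(geno$counts[, keep, drop = FALSE], 2L, 2 * p[keep])
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(as.character(geno$ids), as.character(geno$ids))
  G
}

#' Align a genomic relationship matrix with A22
#'
#' Rescales `G` as `G* = a + b G` with the scalars chosen so that the mean
#' diagonal and the overall mean of `G*` equal those of `A22`, putting the
#' genomic and pedigree relationships on a compatible base.
#'
#' @param G dense symmetric genomic relationship matrix.
#' @param A22 pedigree relationship submatrix of matching dimension.
#' @return aligned dense symmetric matrix `G*`.
#' @export
align_grm <- function(G, A22) {
  stopifnot(all(dim(G) == dim(A22)))
  md_g <- mean(diag(G)); m_g <- mean(G)
  md_a <- mean(diag(A22)); m_a <- mean(A22)
  det2 <- md_g - m_g
  if (abs(det2) < 1e-12 * max(1, abs(md_g))) {
    stop("alignment system is degenerate (G has equal mean diagonal and mean)")
  }
  b <- (md_a - m_a) / det2
  a <- md_a - b * md_g
  Gs <- a + b * G
  dimnames(Gs) <- dimnames(G)
  Gs
}

#' Single-step joint inverse relationship matrix H^{-1}
#'
#' Assembles `H^{-1} = A^{-1} + D` where `D` is zero outside the genotyped
#' block, which equals `G*^{-1} - A22^{-1}`.  If `G*` is not positive
#' definite it is blended once with `A22` (`G* <- (1 - blend) G* + blend
#' A22`) and refactored.
#'
#' @param ped a `pedigree`.
#' @param Gstar aligned genomic relationship matrix for the genotyped
#'   animals (see [align_grm()]).
#' @param geno_ids identifiers of the genotyped animals (pedigree labels),
#'   in the row order of `Gstar`.
#' @param blend blending weight applied to `A22` on factorisation failure.
#' @param A22 optionally the precomputed pedigree submatrix.
#' @return a [rel_factor] of kind `"joint-inverse"` over all pedigree
#'   animals.
#' @export
build_H_inverse <- function(ped, Gstar, geno_ids, blend = 0.01, A22 = NULL) {
  ped <- as_pedigree(ped)
  Ainv <- build_A_inverse(ped)
  if (length(geno_ids) == 0L) {
    return(rel_factor(Ainv$mat, kind = "joint-inverse", labels = ped$label))
  }
  rows <- match(geno_ids, ped$label)
  if (anyNA(rows)) stop("genotyped id(s) not in pedigree")
  if (is.null(A22)) A22 <- build_A22(ped, geno_ids)
  inv_pd <- function(M, what) {
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      stop(what, " is not positive definite (reciprocal condition estimate ",
           format(rcond(M), digits = 3), ")")
    }
    chol2inv(ch)
  }
  Gi <- tryCatch(chol2inv(chol(Gstar)), error = function(e) NULL)
  if (is.null(Gi)) {
    Gstar <- (1 - blend) * Gstar + blend * A22
    Gi <- inv_pd(Gstar, "blended G*")
  }
  A22i <- inv_pd(A22, "A22")
  D <- Gi - A22i
  m <- length(rows)
  idx <- cbind(rep(rows, times = m), rep(rows, each = m))
  lower <- idx[, 1L] >= idx[, 2L]
  Dmat <- Matrix::sparseMatrix(
    i = idx[lower, 1L], j = idx[lower, 2L], x = as.vector(D)[lower],
    dims = c(nrow(ped), nrow(ped)), symmetric = TRUE
  )
  rel_factor(Ainv$mat + Dmat, kind = "joint-inverse", labels = ped$label)
}

#' Dense joint relationship matrix H (oracle)
#'
#' Direct dense construction of the joint pedigree-genomic relationship
#' matrix from its conditional-distribution form:
#' `H11 = A11 + A12 A22^{-1} (G* - A22) A22^{-1} A21`,
#' `H12 = A12 A22^{-1} G*`, `H22 = G*`.  Quadratic in pedigree size; used to
#' verify [build_H_inverse()] on small instances.
#'
#' @inheritParams build_H_inverse
#' @return dense symmetric matrix over all pedigree animals, pedigree order.
#' @export
dense_H <- function(ped, Gstar, geno_ids) {
  ped <- as_pedigree(ped)
  A <- tabular_A(ped)
  if (length(geno_ids) == 0L) return(A)
  g <- match(geno_ids, ped$label)
  ng <- setdiff(seq_len(nrow(ped)), g)
  A22i <- solve(A[g, g])
  B <- A[ng, g, drop = FALSE] %*% A22i
  H <- A
  H[ng, ng] <- A[ng, ng] + B %*% (Gstar - A[g, g]) %*% t(B)
  H[ng, g] <- B %*% Gstar
  H[g, ng] <- t(H[ng, g])
  H[g, g] <- Gstar
  (H + t(H)) / 2
}
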