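## Plain-text readers and writers for the external interfaces: three-column
## pedigrees, genotype count tables (PLINK .raw-style layouts accepted),
## phenotype CSVs, coordinate-format exports of sparse relationship
## factors, and the structured REML result file.

#' Read a pedigree file
#'
#' Whitespace- or comma-separated text with three leading columns animal,
#' sire, dam; a header line is detected automatically; `0` or `NA` denote
#' unknown parents.
#'
#' @param path file path.
#' @return a [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  header <- any(is.na(suppressWarnings(as.numeric(
    gsub("NA", "0", as.character(unlist(probe[1, 1:3])))))))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped a pedigree.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- data.frame(
    id = ped$label,
    sire = ifelse(ped$sire > 0L, ped$label[pmax(ped$sire, 1L)], 0L),
    dam = ifelse(ped$dam > 0L, ped$label[pmax(ped$dam, 1L)], 0L)
  )
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype count table
#'
#' Text table whose first column is the individual identifier and remaining
#' columns are allele counts 0/1/2.  PLINK `.raw`-style metadata columns
#' (`FID`, `IID`, `PAT`, `MAT`, `SEX`, `PHENOTYPE`) are recognised and
#' dropped, with `IID` used as the identifier.
#'
#' @param path file path.
#' @return a [as_genotypes()] object.
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(df))
  if (length(meta)) {
    ids <- if ("IID" %in% meta) df[["IID"]] else df[[1L]]
    df <- df[, setdiff(names(df), meta), drop = FALSE]
    as_genotypes(as.matrix(df), ids = ids)
  } else {
    as_genotypes(df)
  }
}

#' Write a genotype count table
#'
#' @param geno a `genotypes` object.
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  geno <- as_genotypes(geno)
  df <- data.frame(id = geno$ids, geno$counts, check.names = FALSE)
  colnames(df) <- c("id", paste0("snp", seq_len(ncol(geno$counts))))
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Columns: `id`, optionally `dam`, one column per fixed factor, one column
#' per trait with `NA` for missing values.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a phenotype CSV
#'
#' @param data phenotype tibble.
#' @param path file path.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a sparse symmetric matrix in coordinate format
#'
#' Writes the lower triangle as `i j value` lines with 1-based indices.
#'
#' @param rf a [rel_factor] (or any symmetric sparse matrix).
#' @param path file path.
#' @export
write_relfactor <- function(rf, path) {
  M <- if (inherits(rf, "rel_factor")) rf$mat else rf
  Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  keep <- Tm@i >= Tm@j
  df <- data.frame(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L,
                   value = Tm@x[keep])
  df <- df[order(df$j, df$i), ]
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate-format sparse symmetric matrix
#'
#' @param path file path (as written by [write_relfactor()]).
#' @param kind relationship kind for the returned [rel_factor].
#' @param labels optional level labels.
#' @return a [rel_factor].
#' @export
read_relfactor <- function(path, kind = "joint-inverse", labels = NULL) {
  df <- utils::read.table(path, header = TRUE)
  n <- max(df$i, df$j)
  M <- Matrix::sparseMatrix(i = pmax(df$i, df$j), j = pmin(df$i, df$j),
                            x = df$value, dims = c(n, n), symmetric = TRUE)
  rel_factor(M, kind = kind, labels = labels)
}

#' Write the structured REML result file
#'
#' Estimates on the covariance and correlation scales with AI-based
#' standard errors, the likelihood trajectory, and iterate diagnostics.
#'
#' @param fit a [reml_fit()] object.
#' @param path file path.
#' @param header optional named character vector written as `# key: value`
#'   lines (e.g. a reproducibility header).
#' @export
write_reml_results <- function(fit, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  for (nm in names(header)) wl("# ", nm, ": ", header[[nm]])
  wl("# parameterisation: ", fit$param)
  wl("# converged: ", fit$converged, "  iterates: ", fit$niter)
  wl("# -2logL: ", format(fit$m2ll, digits = 12))
  wl("# neq: ", fit$neq, "  nnz_C: ", fit$nnz$total, "  nnz_L: ", fit$nnz_L)
  wl("")
  wl("[estimates_covariance]")
  utils::write.csv(tidy(fit), con, row.names = FALSE, quote = FALSE)
  wl("")
  wl("[estimates_correlation]")
  utils::write.csv(tidy(fit, scale = "correlation"), con,
                   row.names = FALSE, quote = FALSE)
  wl("")
  wl("[trajectory]")
  utils::write.csv(fit$trajectory, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
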