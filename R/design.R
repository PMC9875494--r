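## Translation of a model specification plus phenotype records into the
## structural objects the assembler and the REML engine work from: the
## observation vector ordered traits-within-records, fixed-effect columns
## with the identifiability constraint applied, random-term level maps, and
## record groups sharing a common design signature (missing pattern, fixed
## entry pattern, term presence).  Groups are the unit over which the
## derivative bookkeeping is vectorised.

#' Build the design structures for a model on a data set
#'
#' @param spec a [model_spec()].
#' @param data phenotype data: one row per animal with an `id` column (and a
#'   `dam` column for maternal terms), one column per fixed factor, one
#'   column per trait with `NA` for missing records.
#' @param rels named list of [rel_factor] objects referenced by the random
#'   terms of `spec` (terms with `rel = "identity"` get an identity built
#'   over the levels present in the data).
#' @param param parameterisation the design is built for: `"mv"` (standard
#'   multivariate) or `"pc"` (principal components / Cholesky loadings in the
#'   design matrix).
#' @param quiet suppress the dropped-record message.
#' @return an object of class `mme_design`.
#' @export
build_design <- function(spec, data, rels = list(),
                         param = c("mv", "pc"), quiet = FALSE) {
  param <- match.arg(param)
  stopifnot(inherits(spec, "model_spec"))
  data <- tibble::as_tibble(data)
  q <- spec$q
  miss <- setdiff(spec$traits, names(data))
  if (length(miss)) stop("trait column(s) missing from data: ",
                         paste(miss, collapse = ", "))
  Y <- as.matrix(data[spec$traits])
  storage.mode(Y) <- "double"
  keep <- rowSums(!is.na(Y)) > 0L
  if (any(!keep)) {
    if (!quiet) message(sum(!keep), " record(s) with no observed trait dropped")
    data <- data[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  R <- nrow(data)
  if (R == 0L) stop("no usable records")
  M <- !is.na(Y)
  nobs_rec <- rowSums(M)
  obs_lin <- which(t(M))
  obs_trait <- ((obs_lin - 1L) %% q) + 1L
  obs_rec <- ((obs_lin - 1L) %/% q) + 1L
  nobs <- length(obs_rec)
  yv <- Y[cbind(obs_rec, obs_trait)]
  obs_start <- c(0L, cumsum(nobs_rec))[seq_len(R)] + 1L

  ## ---- fixed effects -------------------------------------------------
  maxfac <- max(lengths(spec$fixed))
  fxmat <- matrix(NA_integer_, nobs, maxfac)  # obs row x factor position
  ncol_fix <- 0L
  eqmap_fix <- list()
  for (j in seq_len(q)) {
    facs <- spec$fixed[[j]]
    oj <- which(obs_trait == j)
    recj <- obs_rec[oj]
    for (fpos in seq_along(facs)) {
      f <- facs[fpos]
      v <- if (f == "1") rep("(Intercept)", R) else {
        if (is.null(data[[f]])) stop("fixed factor column '", f, "' not in data")
        as.character(data[[f]])
      }
      lv <- sort(unique(v[recj]))
      lv_use <- if (fpos >= 2L && length(lv) > 1L) lv[-1L] else lv
      cmap <- stats::setNames(ncol_fix + seq_along(lv_use), lv_use)
      fxmat[oj, fpos] <- cmap[v[recj]]
      eqmap_fix[[length(eqmap_fix) + 1L]] <- tibble::tibble(
        eq = unname(cmap), block = "fixed",
        term = paste0(spec$traits[j], ":", f),
        level = lv_use, comp = spec$traits[j]
      )
      ncol_fix <- ncol_fix + length(lv_use)
    }
  }

  ## ---- random terms --------------------------------------------------
  terms <- vector("list", length(spec$random))
  off <- ncol_fix
  for (t in seq_along(spec$random)) {
    tr <- spec$random[[t]]
    v <- data[[tr$id_col]]
    if (is.null(v)) stop("id column '", tr$id_col, "' for term '", tr$name,
                         "' not in data")
    v <- as.vector(v)
    pres <- !is.na(v) & v != 0
    if (identical(tr$rel, "identity")) {
      labels <- sort(unique(v[pres]))
      rf <- rel_identity(labels)
    } else {
      rf <- rels[[tr$rel]]
      if (is.null(rf)) stop("relationship factor '", tr$rel, "' not supplied")
      labels <- rf$labels
    }
    lvl <- rep(NA_integer_, R)
    lvl[pres] <- match(v[pres], labels)
    if (anyNA(lvl[pres])) {
      stop("term '", tr$name, "': id(s) not among relationship levels: ",
           paste(utils::head(unique(v[pres][is.na(lvl[pres])]), 5L),
                 collapse = ", "))
    }
    terms[[t]] <- list(name = tr$name, rel = rf, labels = labels,
                       N = length(labels), lvl = lvl, offset = off)
    off <- off + length(labels) * q
  }
  names(terms) <- names(spec$random)
  neq <- off

  eqmap <- dplyr::bind_rows(
    dplyr::bind_rows(eqmap_fix),
    dplyr::bind_rows(lapply(terms, function(tt) tibble::tibble(
      eq = tt$offset + seq_len(tt$N * q),
      block = tt$name,
      term = tt$name,
      level = as.character(rep(tt$labels, each = q)),
      comp = rep(spec$traits, tt$N)
    )))
  )

  ## ---- record groups -------------------------------------------------
  okey <- vapply(seq_len(R), function(r) paste(which(M[r, ]), collapse = ","), "")
  fkey <- vapply(seq_len(R), function(r) {
    rows <- obs_start[r] + seq_len(nobs_rec[r]) - 1L
    paste(as.integer(!is.na(fxmat[rows, , drop = FALSE])), collapse = "")
  }, "")
  tkey <- vapply(seq_len(R), function(r) {
    paste(as.integer(vapply(terms, function(tt) !is.na(tt$lvl[r]), TRUE)),
          collapse = "")
  }, "")
  sig <- paste(okey, fkey, tkey, sep = "|")

  groups <- lapply(split(seq_len(R), sig), function(recs) {
    r0 <- recs[1L]
    o <- which(M[r0, ])
    npos <- length(o)
    n_g <- length(recs)
    obsmat <- outer(obs_start[recs], seq_len(npos) - 1L, `+`)
    storage.mode(obsmat) <- "integer"
    rows0 <- obs_start[r0] + seq_len(npos) - 1L
    fpres <- which(!is.na(fxmat[rows0, , drop = FALSE]), arr.ind = TRUE)
    m_fix <- nrow(fpres)
    tpres <- vapply(terms, function(tt) !is.na(tt$lvl[r0]), TRUE)
    slot_t <- integer(0); slot_k <- integer(0)
    for (t in which(tpres)) {
      comps <- if (param == "mv") o else seq_len(max(o))
      slot_t <- c(slot_t, rep(t, length(comps)))
      slot_k <- c(slot_k, comps)
    }
    m <- m_fix + length(slot_t)
    ## column index matrix: records x slots
    colmat <- matrix(NA_integer_, n_g, m)
    if (m_fix) {
      for (s in seq_len(m_fix)) {
        colmat[, s] <- fxmat[obsmat[, fpres[s, 1L]], fpres[s, 2L]]
      }
    }
    for (s in seq_along(slot_t)) {
      tt <- terms[[slot_t[s]]]
      colmat[, m_fix + s] <- tt$offset + (tt$lvl[recs] - 1L) * q + slot_k[s]
    }
    ## template coordinates: fixed entries and term entries
    tc <- list(p = integer(0), slot = integer(0), tidx = integer(0),
               j = integer(0), k = integer(0))
    for (s in seq_along(slot_t)) {
      t <- slot_t[s]; k <- slot_k[s]
      jset <- if (param == "mv") k else o[o >= k]
      for (j in jset) {
        tc$p <- c(tc$p, match(j, o))
        tc$slot <- c(tc$slot, m_fix + s)
        tc$tidx <- c(tc$tidx, t)
        tc$j <- c(tc$j, j)
        tc$k <- c(tc$k, k)
      }
    }
    list(recs = recs, n_g = n_g, o = o, npos = npos, obsmat = obsmat,
         m = m, m_fix = m_fix,
         fix_p = fpres[, 1L], fix_slot = seq_len(m_fix),
         term_p = tc$p, term_slot = tc$slot, term_tidx = tc$tidx,
         term_j = tc$j, term_k = tc$k,
         slot_t = slot_t, slot_k = slot_k,
         colmat = colmat)
  })

  d <- structure(list(
    spec = spec, param = param, q = q, traits = spec$traits,
    data = data, Y = Y, M = M, nrec = R, nobs = nobs,
    obs_rec = obs_rec, obs_trait = obs_trait, obs_start = obs_start,
    y = yv, fxmat = fxmat, nfix = ncol_fix,
    terms = terms, neq = neq, eqmap = eqmap, groups = groups,
    cache = new.env(parent = emptyenv())
  ), class = "mme_design")
  d
}

#' @export
print.mme_design <- function(x, ...) {
  cat("<mme_design> param:", x$param, " traits:", x$q,
      " records:", x$nrec, " observations:", x$nobs,
      " equations:", x$neq, "\n")
  invisible(x)
}

## Numeric per-group design template A (npos x m): rows are the record's
## observed traits, columns the group's equation slots.  For MV the genetic
## coefficients are 1; for PC they are rows of the Cholesky loading Q.
.group_template <- function(g, Qlist, param) {
  A <- matrix(0, g$npos, g$m)
  if (g$m_fix) A[cbind(g$fix_p, g$fix_slot)] <- 1
  if (length(g$term_p)) {
    if (param == "mv") {
      A[cbind(g$term_p, g$term_slot)] <- 1
    } else {
      A[cbind(g$term_p, g$term_slot)] <-
        mapply(function(t, j, k) Qlist[[t]][j, k],
               g$term_tidx, g$term_j, g$term_k)
    }
  }
  A
}
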