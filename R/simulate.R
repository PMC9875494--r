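## Synthetic data generator: generation-structured pedigrees, gene-dropped
## unlinked SNP genotypes with per-generation genotyping proportions, and
## multivariate phenotypes simulated under the infinitesimal model
## y = Xb + Zu + e with Var(u) = A (x) Sigma_u built by generation-recursive
## Mendelian sampling.  The "dataset1" preset emulates a livestock structure
## of 21,000 recorded individuals in eight generations with 301 contemporary
## groups per generation and partial genotyping (10/30/40/50%) in the last
## four generations.

#' Simulation configuration
#'
#' @param n_gen number of progeny generations (founders form generation 0).
#' @param n_sires,n_dams,n_progeny per-generation counts (scalars are
#'   recycled); parents of generation `g` are sampled from generation
#'   `g - 1`.
#' @param n_snp number of unlinked SNPs.
#' @param Sigma_u,Sigma_e true genetic and residual covariance matrices
#'   (`q x q`).
#' @param n_cg number of contemporary groups per generation (0 = none;
#'   records then carry only an overall mean).
#' @param sd_cg standard deviation of the contemporary-group effects.
#' @param geno_prop per-generation proportion of genotyped individuals
#'   (recycled over generations 1..n_gen; founders are never genotyped).
#' @param missing_rate per-trait probability that a record's trait value is
#'   missing.
#' @param exact_mendelian use the exact Mendelian-sampling variance
#'   `(1/2 - 1/4 (F_s + F_d)) Sigma_u` instead of `Sigma_u / 2`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_gen = 2, n_sires = 5, n_dams = 20, n_progeny = 60,
                       n_snp = 200,
                       Sigma_u = default_sigma_u(2),
                       Sigma_e = default_sigma_e(2),
                       n_cg = 4, sd_cg = 0.5,
                       geno_prop = 0, missing_rate = 0,
                       exact_mendelian = FALSE) {
  q <- nrow(as.matrix(Sigma_u))
  cfg <- list(
    n_gen = as.integer(n_gen),
    n_sires = rep_len(as.integer(n_sires), n_gen),
    n_dams = rep_len(as.integer(n_dams), n_gen),
    n_progeny = rep_len(as.integer(n_progeny), n_gen),
    n_snp = as.integer(n_snp),
    Sigma_u = .check_spd(Sigma_u), Sigma_e = .check_spd(Sigma_e), q = q,
    n_cg = as.integer(n_cg), sd_cg = sd_cg,
    geno_prop = rep_len(geno_prop, n_gen),
    missing_rate = rep_len(missing_rate, q),
    exact_mendelian = isTRUE(exact_mendelian)
  )
  stopifnot(all(cfg$n_sires > 0), all(cfg$n_dams > 0), all(cfg$n_progeny > 0),
            cfg$n_gen >= 1L, all(cfg$geno_prop >= 0 & cfg$geno_prop <= 1),
            all(cfg$missing_rate >= 0 & cfg$missing_rate < 1))
  structure(cfg, class = "sim_config")
}

#' Default trait covariance matrices for simulations
#'
#' Unit phenotypic variances split into heritability `h2`, with genetic and
#' residual correlations decaying as `rho^|i-j|`.
#'
#' @param q number of traits.
#' @param h2 heritability (genetic variance share).
#' @param rho base correlation.
#' @return `q x q` covariance matrix.
#' @export
default_sigma_u <- function(q, h2 = 0.3, rho = 0.5) {
  h2 * rho^abs(outer(seq_len(q), seq_len(q), "-"))
}

#' @rdname default_sigma_u
#' @export
default_sigma_e <- function(q, h2 = 0.3, rho = 0.3) {
  (1 - h2) * rho^abs(outer(seq_len(q), seq_len(q), "-"))
}

#' Preset simulation scenarios
#'
#' `"dataset1"`: eight generations of 2,100/3,150 recorded progeny from
#' 100/150 sires and 1,000/1,500 dams, five traits, 301 contemporary groups
#' per generation, 32,000 SNPs with genotyping proportions
#' 0/0/0/0/0.1/0.3/0.4/0.5.  `"tiny"`: a two-generation toy with two traits,
#' suitable for tests and examples.
#'
#' @param name preset name.
#' @param n_snp optionally override the SNP count (the full 32,000 of the
#'   large preset is rarely needed to exercise model structure).
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("tiny", "dataset1"), n_snp = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(
      n_gen = 2, n_sires = 6, n_dams = 24, n_progeny = 60, n_snp = 100,
      Sigma_u = default_sigma_u(2), Sigma_e = default_sigma_e(2),
      n_cg = 3, geno_prop = c(0, 0.5)
    ),
    dataset1 = sim_config(
      n_gen = 8,
      n_sires = c(rep(100L, 4), rep(150L, 4)),
      n_dams = c(rep(1000L, 4), rep(1500L, 4)),
      n_progeny = c(rep(2100L, 4), rep(3150L, 4)),
      n_snp = 32000L,
      Sigma_u = default_sigma_u(5), Sigma_e = default_sigma_e(5),
      n_cg = 301L,
      geno_prop = c(0, 0, 0, 0, 0.1, 0.3, 0.4, 0.5)
    )
  )
  if (!is.null(n_snp)) cfg$n_snp <- as.integer(n_snp)
  cfg
}

#' Simulate a generation-structured pedigree
#'
#' Founders (generation 0) are the sires and dams needed for generation 1
#' and have unknown parents; each progeny of generation `g >= 1` receives a
#' sire and a dam sampled from the designated parents of generation
#' `g - 1`.
#'
#' @param cfg a [sim_config()].
#' @return a [as_pedigree()] object with a `generation` column.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_found <- cfg$n_sires[1] + cfg$n_dams[1]
  id <- seq_len(n_found)
  sire <- dam <- rep(0L, n_found)
  gen <- rep(0L, n_found)
  pool <- id  # candidates for parenthood of the next generation
  nxt <- n_found + 1L
  for (g in seq_len(cfg$n_gen)) {
    ns <- cfg$n_sires[g]; nd <- cfg$n_dams[g]; np <- cfg$n_progeny[g]
    stopifnot(length(pool) >= ns + nd)
    par <- sample(pool, ns + nd)
    sires <- par[seq_len(ns)]
    dams <- par[ns + seq_len(nd)]
    ids <- nxt:(nxt + np - 1L)
    id <- c(id, ids)
    sire <- c(sire, sample(sires, np, replace = TRUE))
    dam <- c(dam, sample(dams, np, replace = TRUE))
    gen <- c(gen, rep(g, np))
    pool <- ids
    nxt <- nxt + np
  }
  as_pedigree(tibble::tibble(id = id, sire = sire, dam = dam,
                             generation = gen))
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Founder haplotypes are drawn per SNP as Bernoulli with allele frequency
#' `p ~ Uniform(0.05, 0.95)`; each descendant inherits one allele per parent
#' per locus (unlinked loci).  The genotyping mask retains the configured
#' proportion of randomly chosen individuals per generation.
#'
#' @param ped a pedigree from [simulate_pedigree()] (needs `generation`).
#' @param cfg a [sim_config()].
#' @return a [as_genotypes()] object over the genotyped individuals (may be
#'   empty).
#' @export
simulate_genotypes <- function(ped, cfg) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  ns <- cfg$n_snp
  p <- stats::runif(ns, 0.05, 0.95)
  H1 <- matrix(0L, n, ns)  # paternal haplotype
  H2 <- matrix(0L, n, ns)  # maternal haplotype
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    H1[i, ] <- if (s == 0L) stats::rbinom(ns, 1L, p) else
      ifelse(stats::runif(ns) < 0.5, H1[s, ], H2[s, ])
    H2[i, ] <- if (d == 0L) stats::rbinom(ns, 1L, p) else
      ifelse(stats::runif(ns) < 0.5, H1[d, ], H2[d, ])
  }
  gen <- ped$generation
  if (is.null(gen)) gen <- rep(1L, n)
  keep <- logical(n)
  for (g in seq_len(cfg$n_gen)) {
    ig <- which(gen == g)
    ng <- round(cfg$geno_prop[g] * length(ig))
    if (ng > 0) keep[sample(ig, ng)] <- TRUE
  }
  counts <- (H1 + H2)[keep, , drop = FALSE]
  rownames(counts) <- as.character(ped$label[keep])
  as_genotypes(counts, ids = ped$label[keep])
}

#' Simulate multivariate phenotypes under the infinitesimal model
#'
#' Breeding values follow `Var(u) = A (x) Sigma_u` by generation-recursive
#' Mendelian sampling (founder draws plus within-family deviations);
#' residuals are iid `N(0, Sigma_e)` per animal; contemporary-group effects
#' are iid normal.  Records are generated for non-founders only, with the
#' configured per-trait missing rate applied.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return list with `data` (tibble: id, dam, cg, traits `t1..tq`), the true
#'   breeding values `u` (matrix `N x q` over all pedigree animals), and the
#'   true values used (`Sigma_u`, `Sigma_e`).
#' @export
simulate_phenotypes <- function(ped, cfg) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  q <- cfg$q
  Lu <- t(chol(cfg$Sigma_u))
  u <- matrix(0, n, q)
  Fi <- if (cfg$exact_mendelian) inbreeding(ped) else numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L && d == 0L) {
      u[i, ] <- Lu %*% stats::rnorm(q)
    } else if (s > 0L && d > 0L) {
      w <- if (cfg$exact_mendelian) 0.5 - 0.25 * (Fi[s] + Fi[d]) else 0.5
      u[i, ] <- 0.5 * (u[s, ] + u[d, ]) + sqrt(w) * (Lu %*% stats::rnorm(q))
    } else {
      pp <- max(s, d)
      w <- if (cfg$exact_mendelian) 0.75 - 0.25 * Fi[pp] else 0.5
      u[i, ] <- 0.5 * u[pp, ] + sqrt(w) * (Lu %*% stats::rnorm(q))
    }
  }
  gen <- ped$generation
  rec <- if (is.null(gen)) seq_len(n) else which(gen > 0L)
  nr <- length(rec)
  Le <- t(chol(cfg$Sigma_e))
  e <- matrix(stats::rnorm(nr * q), nr, q) %*% t(Le)
  Y <- u[rec, , drop = FALSE] + e
  if (cfg$n_cg > 0) {
    gvec <- if (is.null(gen)) rep(1L, nr) else gen[rec]
    cg <- paste0("g", gvec, "c",
                 sample.int(cfg$n_cg, nr, replace = TRUE))
    cg_eff <- stats::rnorm(length(unique(cg)), 0, cfg$sd_cg)
    names(cg_eff) <- unique(cg)
    Y <- Y + cg_eff[cg]
  } else {
    cg <- rep("all", nr)
  }
  for (j in seq_len(q)) {
    if (cfg$missing_rate[j] > 0) {
      Y[stats::runif(nr) < cfg$missing_rate[j], j] <- NA
    }
  }
  colnames(Y) <- paste0("t", seq_len(q))
  data <- tibble::tibble(
    id = ped$label[rec],
    dam = ifelse(ped$dam[rec] > 0L, ped$label[ped$dam[rec]], 0L),
    cg = cg
  )
  data <- dplyr::bind_cols(data, tibble::as_tibble(Y))
  list(data = data, u = u, Sigma_u = cfg$Sigma_u, Sigma_e = cfg$Sigma_e)
}

#' Simulate a complete data set
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `ped`, `geno`, `pheno` (see the individual
#'   generators) and the configuration.
#' @export
simulate_dataset <- function(cfg = sim_preset("tiny"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  pheno <- simulate_phenotypes(ped, cfg)
  list(ped = ped, geno = geno, pheno = pheno, cfg = cfg)
}
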