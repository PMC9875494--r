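# shared fixtures: small random pedigrees and simulated model instances

# random topologically ordered pedigree with a founder block
random_pedigree <- function(n, n_founder = max(3L, n %/% 5L)) {
  sire <- dam <- integer(n)
  for (i in (n_founder + 1L):n) {
    par <- sample(seq_len(i - 1L), 2L)
    sire[i] <- par[1L]
    dam[i] <- par[2L]
  }
  as_pedigree(data.frame(id = seq_len(n), sire = sire, dam = dam))
}

# small simulated instance with design, rels and true covariances
small_instance <- function(seed = 1, q = 2, n_progeny = 30, geno = FALSE,
                           missing_rate = 0, n_cg = 3, fixed = "cg",
                           param = "mv", n_gen = 2, n_sires = 3,
                           n_dams = 8) {
  cfg <- sim_config(
    n_gen = n_gen, n_sires = n_sires, n_dams = n_dams,
    n_progeny = n_progeny,
    n_snp = 60, Sigma_u = default_sigma_u(q), Sigma_e = default_sigma_e(q),
    n_cg = n_cg, geno_prop = if (geno) c(rep(0, n_gen - 1), 0.4) else 0,
    missing_rate = missing_rate
  )
  ds <- simulate_dataset(cfg, seed = seed)
  rels <- if (geno && length(ds$geno$ids)) {
    G <- build_grm(ds$geno)
    A22 <- build_A22(ds$ped, ds$geno$ids)
    list(animal = build_H_inverse(ds$ped, align_grm(G, A22), ds$geno$ids,
                                  A22 = A22))
  } else {
    list(animal = build_A_inverse(ds$ped))
  }
  spec <- model_spec(paste0("t", seq_len(q)), fixed = fixed)
  design <- build_design(spec, ds$pheno$data, rels, param = param,
                         quiet = TRUE)
  covs <- cov_params(list(direct = 1.2 * default_sigma_u(q)),
                     0.9 * default_sigma_e(q))
  list(ds = ds, rels = rels, spec = spec, design = design, covs = covs)
}

# dense symmetric sparse matrix from a dense seed, for sparsela tests
as_sym_sparse <- function(M) {
  Matrix::forceSymmetric(Matrix::Matrix(M, sparse = TRUE), "L")
}
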