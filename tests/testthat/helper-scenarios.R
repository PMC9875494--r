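# scenario builders shared by the equivalence and recovery checks:
# a ~200-record two-generation design and a ~2000-record four-generation
# design, each with or without a genomic (single-step) relationship matrix

scenario_data <- function(q, size = c("small", "large"), geno = FALSE,
                          seed = 1) {
  size <- match.arg(size)
  cfg <- if (size == "small") {
    sim_config(n_gen = 2, n_sires = 20, n_dams = 60, n_progeny = 100,
               n_snp = 150, Sigma_u = default_sigma_u(q),
               Sigma_e = default_sigma_e(q), n_cg = 4,
               geno_prop = if (geno) c(0, 0.3) else 0)
  } else {
    sim_config(n_gen = 4, n_sires = 10, n_dams = 60, n_progeny = 500,
               n_snp = 300, Sigma_u = default_sigma_u(q),
               Sigma_e = default_sigma_e(q), n_cg = 8,
               geno_prop = if (geno) c(0, 0, 0.05, 0.05) else 0)
  }
  ds <- simulate_dataset(cfg, seed = seed)
  rels <- if (geno && length(ds$geno$ids)) {
    G <- build_grm(ds$geno)
    A22 <- build_A22(ds$ped, ds$geno$ids)
    list(animal = build_H_inverse(ds$ped, align_grm(G, A22), ds$geno$ids,
                                  A22 = A22))
  } else {
    list(animal = build_A_inverse(ds$ped))
  }
  spec <- model_spec(paste0("t", seq_len(q)), fixed = "cg")
  list(ds = ds, rels = rels, spec = spec, cfg = cfg)
}
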