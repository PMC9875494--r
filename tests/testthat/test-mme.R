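# MME assembly: equation/parameter counting, GLS equivalence, missing
# traits, MV/PC solution mapping, and nonzero accounting

test_that("equation counts match assembled dimension and structural formula", {
  # trivial: 1 trait, 1 animal, 1 mean -> 2 equations
  expect_equal(count_equations(q = 1, fixed_levels = 1, random_levels = 1), 2L)
  set.seed(1)
  for (rep in 1:6) {
    q <- sample(1:3, 1)
    inst <- small_instance(seed = rep, q = q, n_progeny = 20,
                           missing_rate = if (rep %% 2) 0.15 else 0)
    d <- inst$design
    sys <- assemble_mme(d, inst$covs)
    expect_equal(d$neq, nrow(sys$C))
    expect_equal(d$neq, count_equations(inst$spec, inst$ds$pheno$data,
                                        inst$rels))
    # structural formula: fixed levels + q per relationship level
    nlev <- length(unique(inst$ds$pheno$data$cg))
    expect_equal(d$neq, count_equations(
      q = q, fixed_levels = rep(nlev, q),
      random_levels = nrow(inst$ds$ped)))
  }
})

test_that("parameter counts are (n_matrices) q(q+1)/2", {
  expect_equal(count_parameters(model_spec("t1")), 2L)
  expect_equal(count_parameters(model_spec(paste0("t", 1:4))), 20L)
  maternal <- model_spec(paste0("t", 1:4), random = list(
    random_term("direct", "id"), random_term("maternal", "dam"),
    random_term("mpe", "dam", "identity")))
  expect_equal(count_parameters(maternal), 40L)
})

test_that("MME solutions equal dense GLS/BLUP solutions", {
  for (seed in 1:3) {
    inst <- small_instance(seed = seed, q = 2, n_progeny = 25,
                           missing_rate = 0.1, geno = seed == 2)
    sys <- assemble_mme(inst$design, inst$covs)
    x <- solve_mme(sys)$x
    o <- oracle_gls(inst$design, inst$covs)
    expect_equal(x[seq_len(inst$design$nfix)], o$beta, tolerance = 1e-6,
                 ignore_attr = TRUE)
    off <- inst$design$terms$direct$offset
    expect_equal(x[off + seq_along(o$u$direct)], o$u$direct,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a record with a missing trait contributes only at observed positions", {
  # two animals, unrelated; animal 2 misses trait 2
  ped <- as_pedigree(data.frame(id = 1:2, sire = 0, dam = 0))
  dat <- tibble::tibble(id = 1:2, t1 = c(1.2, 0.4), t2 = c(0.3, NA))
  spec <- model_spec(c("t1", "t2"), fixed = "1")
  rels <- list(animal = build_A_inverse(ped))
  covs <- cov_params(list(direct = default_sigma_u(2)), default_sigma_e(2))
  d <- build_design(spec, dat, rels, param = "mv", quiet = TRUE)
  sys <- assemble_mme(d, covs)
  # residual weight for the incomplete record is the scalar 1/Sigma_e[1,1]
  r2 <- which(d$obs_rec == 2)
  expect_length(r2, 1L)
  expect_equal(as.matrix(sys$Rinv)[r2, r2], 1 / covs$E[1, 1])
  # trait-2 genetic equation of animal 2 has no data contribution
  off <- d$terms$direct$offset
  expect_equal(sys$rhs[off + 4L], 0)
})

test_that("MV and PC systems give identical fixed effects and mapped BLUPs", {
  for (seed in 1:3) {
    q <- c(1, 2, 3)[seed]
    inst_mv <- small_instance(seed = seed + 3, q = q, n_progeny = 25,
                              missing_rate = 0.1)
    d_pc <- build_design(inst_mv$spec, inst_mv$ds$pheno$data, inst_mv$rels,
                         param = "pc", quiet = TRUE)
    covs <- inst_mv$covs
    x_mv <- solve_mme(assemble_mme(inst_mv$design, covs))$x
    x_pc <- solve_mme(assemble_mme(d_pc, covs))$x
    nfix <- inst_mv$design$nfix
    expect_equal(x_mv[1:nfix], x_pc[1:nfix], tolerance = 1e-8)
    # u = (I (x) Q) u*
    Q <- pc_transform(covs$G$direct)
    N <- inst_mv$design$terms$direct$N
    U_star <- matrix(x_pc[-(1:nfix)], nrow = q)
    U_mv <- matrix(x_mv[-(1:nfix)], nrow = q)
    expect_equal(U_mv, Q %*% U_star, tolerance = 1e-8)
  }
  # scalar case: sigma_u^2 = 4 gives u = 2 u*
  inst <- small_instance(seed = 9, q = 1, n_progeny = 20)
  covs <- cov_params(list(direct = matrix(4)), matrix(1))
  d_pc <- build_design(inst$spec, inst$ds$pheno$data, inst$rels,
                       param = "pc", quiet = TRUE)
  x_mv <- solve_mme(assemble_mme(inst$design, covs))$x
  x_pc <- solve_mme(assemble_mme(d_pc, covs))$x
  nfix <- inst$design$nfix
  expect_equal(x_mv[-(1:nfix)], 2 * x_pc[-(1:nfix)], tolerance = 1e-8)
})

test_that("identity genetic covariance makes the PC system equal the MV system", {
  inst <- small_instance(seed = 12, q = 3, n_progeny = 20)
  covs <- cov_params(list(direct = diag(3)), default_sigma_e(3))
  d_pc <- build_design(inst$spec, inst$ds$pheno$data, inst$rels,
                       param = "pc", quiet = TRUE)
  C_mv <- assemble_mme(inst$design, covs)$C
  C_pc <- assemble_mme(d_pc, covs)$C
  expect_lt(max(abs(C_mv - C_pc)), 1e-12)
})

test_that("relationship-part nonzeros follow the q vs q^2 rule", {
  set.seed(30)
  ped <- random_pedigree(15)
  rels <- list(animal = build_A_inverse(ped))
  K <- rels$animal$mat
  Tm <- methods::as(methods::as(K, "generalMatrix"), "TsparseMatrix")
  n_off <- sum(Tm@i > Tm@j)   # strictly-lower nonzeros of the inverse
  n <- nrow(ped)
  for (q in c(2L, 5L)) {
    dat <- tibble::tibble(id = ped$label)
    for (j in seq_len(q)) dat[[paste0("t", j)]] <- rnorm(n)
    spec <- model_spec(paste0("t", seq_len(q)), fixed = "1")
    covs <- cov_params(list(direct = default_sigma_u(q)),
                       default_sigma_e(q))
    nz <- sapply(c("mv", "pc"), function(p) {
      d <- build_design(spec, dat, rels, param = p, quiet = TRUE)
      sys <- assemble_mme(d, covs)
      c(rel = sys$nnz$uu_rel, tot = sys$nnz$total)
    })
    # each off-diagonal element contributes q^2 (MV) vs q (PC);
    # each diagonal element q(q+1)/2 vs q
    expect_equal(nz["rel", "mv"], n * q * (q + 1) / 2 + n_off * q^2)
    expect_equal(nz["rel", "pc"], n * q + n_off * q)
    expect_lte(nz["tot", "pc"], nz["tot", "mv"])
  }
})

test_that("PC data part of C*_uu is block-diagonal with animal blocks <= q x q", {
  inst <- small_instance(seed = 15, q = 3, n_progeny = 20, param = "pc")
  d <- inst$design
  sys <- assemble_mme(d, inst$covs)
  # zero the relationship part: remaining uu block must be animal-diagonal
  q <- d$q
  relp <- pcreml:::.rel_part(d, inst$covs)
  Duu <- sys$C - relp
  Tm <- methods::as(methods::as(Duu, "generalMatrix"), "TsparseMatrix")
  uu <- Tm@i + 1L > d$nfix & Tm@j + 1L > d$nfix & abs(Tm@x) > 0
  blk_i <- (Tm@i[uu] + 1L - d$nfix - 1L) %/% q
  blk_j <- (Tm@j[uu] + 1L - d$nfix - 1L) %/% q
  expect_true(all(blk_i == blk_j))
})

test_that("coefficient matrices stay PD and symmetric for PD inputs", {
  for (seed in 1:4) {
    inst <- small_instance(seed = seed, q = 2, n_progeny = 15,
                           param = if (seed %% 2) "mv" else "pc")
    sys <- assemble_mme(inst$design, inst$covs)
    expect_s4_class(sys$C, "dsCMatrix")
    expect_no_error(chol_factor(sys$C))
  }
})
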