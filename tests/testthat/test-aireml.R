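# the AI-REML engine: likelihood, gradient, average information, Newton
# loop, and parameterisation equivalence on small instances

test_that("sparse-path likelihood equals the dense V-form evaluation", {
  for (seed in 1:4) {
    q <- c(1, 2, 2, 3)[seed]
    inst <- small_instance(seed = seed, q = q, n_progeny = 25,
                           missing_rate = c(0, 0.15, 0, 0.1)[seed],
                           geno = seed %in% c(2, 4),
                           param = if (seed %% 2) "mv" else "pc")
    ev <- loglik_mme(inst$design, inst$covs)
    o <- oracle_loglik(inst$design, inst$covs)
    expect_equal(ev$m2ll, o, tolerance = 1e-8)
    # y'Py from MME byproducts equals the dense quadratic
    P <- oracle_P(inst$design, inst$covs)
    expect_equal(ev$yPy, as.numeric(t(inst$design$y) %*% P %*%
                                      inst$design$y), tolerance = 1e-6)
  }
})

test_that("P-matrix identities hold on oracle instances", {
  inst <- small_instance(seed = 2, q = 2, n_progeny = 20)
  ctx <- oracle_context(inst$design)
  P <- oracle_P(inst$design, inst$covs, ctx)
  V <- pcreml:::.oracle_V(inst$design, inst$covs, ctx)
  expect_lt(max(abs(P %*% V %*% P - P)), 1e-8)
  expect_lt(max(abs(P %*% ctx$X)), 1e-8)
})

test_that("H built from an empty genotype set gives the pedigree likelihood", {
  inst <- small_instance(seed = 3, q = 2, n_progeny = 20)
  H0 <- build_H_inverse(inst$ds$ped, matrix(0, 0, 0), integer(0))
  d2 <- build_design(inst$spec, inst$ds$pheno$data, list(animal = H0),
                     param = "mv", quiet = TRUE)
  expect_equal(loglik_mme(inst$design, inst$covs)$m2ll,
               loglik_mme(d2, inst$covs)$m2ll, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:3) {
    q <- c(1, 2, 3)[seed]
    inst <- small_instance(seed = seed + 5, q = q, n_progeny = 20,
                           missing_rate = if (seed == 2) 0.1 else 0,
                           geno = seed == 3,
                           param = if (seed %% 2) "mv" else "pc")
    ev <- loglik_mme(inst$design, inst$covs)
    der <- reml_derivatives(inst$design, inst$covs, ev)
    fd <- oracle_gradient_fd(inst$design, inst$covs)
    expect_lt(max(abs(der$grad - fd) / pmax(abs(fd), 1e-3)), 1e-4)
  }
})

test_that("average information matches the dense evaluation and is PSD", {
  for (seed in 1:2) {
    inst <- small_instance(seed = seed + 7, q = 2, n_progeny = 20,
                           geno = seed == 1,
                           param = if (seed %% 2) "mv" else "pc")
    ev <- loglik_mme(inst$design, inst$covs)
    der <- reml_derivatives(inst$design, inst$covs, ev)
    ai_dense <- oracle_ai(inst$design, inst$covs)
    expect_equal(der$AI, ai_dense, tolerance = 1e-6, ignore_attr = TRUE)
    expect_gt(min(eigen(der$AI, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
})

test_that("MV and PC engines agree on likelihood, gradient and AI", {
  inst <- small_instance(seed = 13, q = 2, n_progeny = 30, geno = TRUE,
                         missing_rate = 0.1)
  d_pc <- build_design(inst$spec, inst$ds$pheno$data, inst$rels,
                       param = "pc", quiet = TRUE)
  ev_mv <- loglik_mme(inst$design, inst$covs)
  ev_pc <- loglik_mme(d_pc, inst$covs)
  expect_equal(ev_mv$m2ll, ev_pc$m2ll, tolerance = 1e-10)
  der_mv <- reml_derivatives(inst$design, inst$covs, ev_mv)
  der_pc <- reml_derivatives(d_pc, inst$covs, ev_pc)
  expect_lt(max(abs(der_mv$grad - der_pc$grad)), 1e-6)
  expect_lt(max(abs(der_mv$AI - der_pc$AI)), 1e-6)
})

test_that("damped Newton iterates never decrease the likelihood", {
  inst <- small_instance(seed = 17, q = 2, n_progeny = 80, n_gen = 3,
                         n_sires = 6, n_dams = 18)
  fit <- reml_fit(inst$ds$pheno$data, inst$spec, inst$rels, param = "mv")
  expect_true(all(fit$trajectory$dL >= 0))
  expect_true(fit$converged)
  # at the maximum the gradient is inside the convergence tolerance
  expect_lt(max(abs(fit$grad)), 1e-3)
  # an iterate started at the maximum stays there
  st <- reml_iterate(pcreml:::build_design(inst$spec, inst$ds$pheno$data,
                                           inst$rels, param = "mv",
                                           quiet = TRUE),
                     fit$estimates)
  expect_lt(st$dL, 1e-4)
  # standard errors from the inverse AI are positive
  expect_true(all(fit$se_theta > 0))
  expect_true(all(fit$se_cov$se > 0))
})

test_that("reml_fit recovers the balanced half-sib ANOVA estimate (q = 1)", {
  set.seed(31)
  s <- 30; nper <- 12
  sig_s <- 0.2; sig_e <- 0.8
  sire <- rep(seq_len(s), each = nper)
  y <- rnorm(s)[sire] * sqrt(sig_s) + rnorm(s * nper, 0, sqrt(sig_e))
  dat <- tibble::tibble(id = seq_along(y), sire = sire, t1 = y)
  # one-way random ANOVA estimators (REML equals ANOVA when balanced)
  ybar_s <- tapply(y, sire, mean)
  msb <- nper * sum((ybar_s - mean(y))^2) / (s - 1)
  msw <- sum((y - ybar_s[sire])^2) / (s * (nper - 1))
  sig_s_hat <- (msb - msw) / nper
  spec <- model_spec("t1", fixed = "1", random = list(
    random_term("sire", "sire", "identity")))
  fit <- reml_fit(dat, spec, param = "mv", tol_L = 1e-8, tol_g = 1e-6)
  expect_equal(unname(fit$estimates$G$sire[1, 1]), sig_s_hat,
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates$E[1, 1]), msw, tolerance = 1e-4)
})

test_that("theta transform round-trips and PC loading satisfies its contract", {
  set.seed(41)
  for (q in c(1, 3, 5)) {
    S <- crossprod(matrix(rnorm(q * q), q)) + diag(q)
    E <- crossprod(matrix(rnorm(q * q), q)) + diag(q)
    covs <- cov_params(list(direct = S), E)
    th <- theta_pack(covs)
    covs2 <- theta_unpack(th, q, "direct")
    expect_equal(covs2$G$direct, S, tolerance = 1e-12)
    expect_equal(covs2$E, E, tolerance = 1e-12)
    expect_equal(theta_pack(covs2), th, tolerance = 1e-12)
    Q <- pc_transform(S)
    expect_equal(Q %*% t(Q), S, tolerance = 1e-12)
    expect_lt(max(abs(solve(Q) %*% S %*% solve(t(Q)) - diag(q))), 1e-10)
    expect_true(all(diag(Q) > 0))
  }
  expect_equal(length(theta_pack(cov_params(list(a = diag(3)), diag(3)))),
               count_parameters(model_spec(paste0("t", 1:3))))
})

test_that("maternal-effects models evaluate and differentiate correctly", {
  set.seed(51)
  cfg <- sim_config(n_gen = 3, n_sires = 4, n_dams = 15, n_progeny = 50,
                    Sigma_u = default_sigma_u(2),
                    Sigma_e = default_sigma_e(2), n_cg = 3)
  ds <- simulate_dataset(cfg, seed = 6)
  rels <- list(animal = build_A_inverse(ds$ped))
  spec <- model_spec(c("t1", "t2"), fixed = "cg", random = list(
    random_term("direct", "id", "animal"),
    random_term("maternal", "dam", "animal"),
    random_term("mpe", "dam", "identity")))
  covs <- cov_params(list(direct = default_sigma_u(2),
                          maternal = 0.5 * default_sigma_u(2),
                          mpe = 0.3 * diag(2)),
                     default_sigma_e(2))
  res <- lapply(c("mv", "pc"), function(p) {
    d <- build_design(spec, ds$pheno$data, rels, param = p, quiet = TRUE)
    ev <- loglik_mme(d, covs)
    list(ev = ev, der = reml_derivatives(d, covs, ev), d = d)
  })
  expect_equal(res[[1]]$ev$m2ll, res[[2]]$ev$m2ll, tolerance = 1e-10)
  expect_lt(max(abs(res[[1]]$der$grad - res[[2]]$der$grad)), 1e-6)
  fd <- oracle_gradient_fd(res[[1]]$d, covs)
  expect_lt(max(abs(res[[1]]$der$grad - fd) / pmax(abs(fd), 1e-3)), 1e-4)
  expect_equal(res[[1]]$ev$m2ll, oracle_loglik(res[[1]]$d, covs),
               tolerance = 1e-8)
})
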