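# command-line interface: simulate -> fit -> profile-structure round trips
# on a tiny scenario, plus IO round trips

test_that("text IO round-trips pedigree, genotypes and phenotypes", {
  td <- withr::local_tempdir()
  ds <- simulate_dataset(sim_preset("tiny"), seed = 3)
  pp <- file.path(td, "ped.txt")
  write_pedigree(ds$ped, pp)
  ped2 <- read_pedigree(pp)
  expect_equal(ped2$sire, ds$ped$sire)
  expect_equal(ped2$dam, ds$ped$dam)
  gp <- file.path(td, "geno.txt")
  write_genotypes(ds$geno, gp)
  g2 <- read_genotypes(gp)
  expect_equal(unname(g2$counts), unname(ds$geno$counts))
  expect_equal(as.character(g2$ids), as.character(ds$geno$ids))
  fp <- file.path(td, "pheno.csv")
  write_phenotypes(ds$pheno$data, fp)
  d2 <- read_phenotypes(fp)
  expect_equal(d2$t1, ds$pheno$data$t1, tolerance = 1e-10)
  # relationship factor coordinate export round trip
  rf <- build_A_inverse(ds$ped)
  rp <- file.path(td, "ainv.txt")
  write_relfactor(rf, rp)
  rf2 <- read_relfactor(rp, kind = "pedigree-inverse")
  expect_lt(max(abs(rf$mat - rf2$mat)), 1e-12)
})

test_that("cmd_fit produces equivalent MV and PC results", {
  td <- withr::local_tempdir()
  set.seed(2)
  ds <- simulate_dataset(sim_preset("tiny"), seed = 8)
  write_pedigree(ds$ped, file.path(td, "ped.txt"))
  write_genotypes(ds$geno, file.path(td, "geno.txt"))
  write_phenotypes(ds$pheno$data, file.path(td, "pheno.csv"))
  cfgf <- file.path(td, "model.yaml")
  yaml::write_yaml(list(
    pedigree = file.path(td, "ped.txt"),
    genotypes = file.path(td, "geno.txt"),
    phenotypes = file.path(td, "pheno.csv"),
    traits = c("t1", "t2"), fixed = "cg"
  ), cfgf)
  fit_mv <- run_cli(c("fit", "--config", cfgf, "--param", "mv",
                      "--out-dir", td, "--seed", "1"))
  fit_pc <- run_cli(c("fit", "--config", cfgf, "--param", "pc",
                      "--out-dir", td, "--seed", "1"))
  expect_true(file.exists(file.path(td, "results_mv.txt")))
  expect_true(file.exists(file.path(td, "results_pc.txt")))
  expect_lt(max(abs(fit_mv$estimates$G$direct - fit_pc$estimates$G$direct)),
            1e-5)
  expect_lt(max(abs(fit_mv$estimates$E - fit_pc$estimates$E)), 1e-5)
  # result files carry a reproducibility header
  head_mv <- readLines(file.path(td, "results_mv.txt"), n = 8)
  expect_true(any(grepl("config_md5", head_mv)))
  expect_true(any(grepl("seed: 1", head_mv)))
})

test_that("cmd_fit fails cleanly on a missing input file", {
  td <- withr::local_tempdir()
  cfgf <- file.path(td, "bad.yaml")
  yaml::write_yaml(list(pedigree = file.path(td, "absent.txt"),
                        phenotypes = file.path(td, "absent.csv"),
                        traits = "t1"), cfgf)
  expect_error(suppressWarnings(
    run_cli(c("fit", "--config", cfgf, "--out-dir", td))))
  expect_error(run_cli(c("fit", "--out-dir", td)), "--config")
  expect_error(run_cli(c("nonsense")), "unknown command")
})

test_that("profile-structure reports both parameterisations deterministically", {
  td <- withr::local_tempdir()
  ds <- simulate_dataset(sim_preset("tiny"), seed = 4)
  write_pedigree(ds$ped, file.path(td, "ped.txt"))
  write_genotypes(ds$geno, file.path(td, "geno.txt"))
  write_phenotypes(ds$pheno$data, file.path(td, "pheno.csv"))
  cfgf <- file.path(td, "model.yaml")
  yaml::write_yaml(list(
    pedigree = file.path(td, "ped.txt"),
    genotypes = file.path(td, "geno.txt"),
    phenotypes = file.path(td, "pheno.csv"),
    traits = c("t1", "t2"), fixed = "cg"
  ), cfgf)
  rep1 <- run_cli(c("profile-structure", "--config", cfgf, "--out-dir", td,
                    "--seed", "2"))
  f1 <- readLines(file.path(td, "structure.csv"))
  rep2 <- run_cli(c("profile-structure", "--config", cfgf, "--out-dir", td,
                    "--seed", "2"))
  f2 <- readLines(file.path(td, "structure.csv"))
  expect_identical(f1, f2)                  # byte-identical report
  expect_equal(rep1$neq[1], rep1$neq[2])    # same dimension, both params
  expect_lte(rep1$nnz_C[rep1$param == "pc"],
             rep1$nnz_C[rep1$param == "mv"])
})

test_that("cmd_simulate writes the text data set a fit can consume", {
  td <- withr::local_tempdir()
  cfgf <- file.path(td, "sim.yaml")
  yaml::write_yaml(list(preset = "tiny"), cfgf)
  ds <- run_cli(c("simulate", "--config", cfgf, "--out-dir", td,
                  "--seed", "9"))
  expect_true(file.exists(file.path(td, "pedigree.txt")))
  expect_true(file.exists(file.path(td, "phenotypes.csv")))
  expect_true(file.exists(file.path(td, "simulate.log")))
  rf <- run_cli(c("build-relmat", "--config",
                  { yaml::write_yaml(list(pedigree = file.path(td, "pedigree.txt")),
                                     file.path(td, "rm.yaml"))
                    file.path(td, "rm.yaml") },
                  "--out-dir", td))
  expect_true(file.exists(file.path(td, "Ainv.txt")))
})
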