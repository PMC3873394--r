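test_that("MME solutions equal direct GLS on explicit-V instances", {
  for (s in 1:20) {
    inst <- random_instance(s)
    var_a <- 0.4; var_e <- 0.8
    A <- additive_relationship_matrix(inst$ped)
    Ai <- inverse_relationship_matrix(inst$ped)
    fit <- solve_mme(inst$y, inst$X, Ai, var_e / var_a, inst$rel,
                     var_e = var_e, obs_index = inst$obs_index)
    ref <- gls_oracle(inst$y, inst$X, A, var_a, var_e, inst$rel,
                      inst$obs_index)
    expect_lt(max(abs(fit$fixed - ref$fixed)), 1e-8)
    expect_lt(max(abs(fit$cov_fixed - ref$cov_fixed)), 1e-8)
  }
})

test_that("large lambda collapses the fit to weighted least squares", {
  inst <- random_instance(101)
  Ai <- inverse_relationship_matrix(inst$ped)
  fit <- solve_mme(inst$y, inst$X, Ai, 1e8, inst$rel,
                   obs_index = inst$obs_index)
  wls <- stats::lm.wfit(inst$X, inst$y, inst$rel)
  expect_lt(max(abs(fit$fixed - wls$coefficients)), 1e-6)
})

test_that("solve_mme rejects invalid inputs", {
  inst <- random_instance(7)
  Ai <- inverse_relationship_matrix(inst$ped)
  expect_error(solve_mme(inst$y, inst$X, Ai, -1, inst$rel,
                         obs_index = inst$obs_index), "lambda")
  expect_error(solve_mme(inst$y, cbind(inst$X, inst$X[, 2]), Ai, 1,
                         inst$rel, obs_index = inst$obs_index),
               "rank-deficient")
  expect_error(solve_mme(inst$y, inst$X, Ai, 1, inst$rel * 2,
                         obs_index = inst$obs_index), "reliabilit")
})

test_that("Wald p-values are invariant to dosage recoding", {
  sim <- default_sim()
  vc <- vc_default()
  Ai <- inverse_relationship_matrix(sim$ped)
  scan <- single_snp_scan(sim$geno, sim$phenotypes, sim$ped, vc, "FP",
                          A_inv = Ai)
  flipped <- sim$geno
  flipped$codes <- 2L - flipped$codes
  scan2 <- single_snp_scan(flipped, sim$phenotypes, sim$ped, vc, "FP",
                           A_inv = Ai)
  expect_equal(scan2$p_raw, scan$p_raw, tolerance = 1e-9)
  expect_equal(scan2$effect, -scan$effect, tolerance = 1e-9)
})

test_that("variance explained follows 2p(1-p)alpha^2 / var_p", {
  expect_equal(variance_explained(0.5, 1, 1), 0.5)
  expect_equal(variance_explained(0.38, 0.2, 4), 2 * 0.38 * 0.62 * 0.04 / 4)
  expect_equal(variance_explained(0.3, 0, 1), 0)
  # scan output is internally consistent
  sim <- default_sim()
  scan <- single_snp_scan(sim$geno, sim$phenotypes, sim$ped, vc_default(),
                          "MY")
  expect_equal(scan$var_explained,
               2 * scan$maf * (1 - scan$maf) * scan$effect^2 / 1,
               tolerance = 1e-12)
})

test_that("monomorphic SNPs yield p = 1 with a warning, not an error", {
  sim <- default_sim()
  mono <- sim$geno
  mono$codes[, 2] <- 0L
  expect_warning(
    scan <- single_snp_scan(mono, sim$phenotypes, sim$ped, vc_default(),
                            "MY", snps = 2),
    "monomorphic")
  expect_equal(scan$p_raw, 1)
  expect_false(scan$significant)
})

test_that("genotype-class LSMs are monotone for a strong additive SNP", {
  cfg <- default_sim_config(alpha_true = 1.5, traits = "MY",
                            causal_snp = "SNP13")
  sim <- simulate_dataset(cfg, seed = 31)
  fit <- genotype_class_lsm(sim$geno, sim$phenotypes, sim$ped, vc_default(),
                            "MY", "SNP13")
  expect_equal(nrow(fit$lsm), 3L)
  # minor allele is alt here, so LSM increases with dosage
  expect_true(all(diff(fit$lsm$lsm) > 0))
  # extreme classes separated at the 0.01 level: different letters
  l01 <- fit$lsm$letters_01
  expect_false(grepl(substr(l01[1], 1, 1), l01[3], fixed = TRUE))
  # single-class SNP errors
  mono <- sim$geno; mono$codes[, 1] <- 1L
  expect_error(genotype_class_lsm(mono, sim$phenotypes, sim$ped,
                                  vc_default(), "MY", 1), "classes")
})

test_that("EM-REML recovers synthetic variance components roughly", {
  cfg <- default_sim_config(traits = "MY", alpha_true = 0)
  sim <- simulate_dataset(cfg, seed = 17)
  ph <- sim$phenotypes[sim$phenotypes$trait == "MY", ]
  est <- reml_em(ph$ebv, cbind(rep(1, nrow(ph))), sim$ped, ph$reliability,
                 obs_index = match(ph$id, sim$ped$id),
                 init = list(var_a = 0.5, var_e = 0.5))
  expect_gt(est$var_a, 0.1)
  expect_lt(est$var_a, 0.6)
  expect_gt(est$var_e, 0.4)
  expect_lt(est$var_e, 1.1)
})
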