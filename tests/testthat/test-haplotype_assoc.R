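test_that("HTR design rows are haplotype dosages summing to two", {
  sim <- default_sim()
  hs <- pool_rare_haplotypes(em_haplotype_frequencies(sim$geno, 4:9,
                                                      seed = 1))
  X <- htr_design_matrix(hs)
  expect_true(all(abs(rowSums(X) - 2) < 1e-9))
  # phase-certain individuals have integer rows
  hom <- which(apply(sim$geno$codes[, 4:9], 1, function(x) sum(x == 1L)) <= 1)
  expect_true(all(abs(unclass(X)[hom, ] - round(unclass(X)[hom, ])) < 1e-6))
  # k >= 2 is enforced
  hs1 <- haplotype_set("AAA", 1, dosage = matrix(2, 5, 1,
                       dimnames = list(paste0("I", 1:5), NULL)))
  expect_error(htr_design_matrix(hs1), "k >= 2")
})

test_that("a two-haplotype block test equals the single-SNP dosage test", {
  sim <- default_sim()
  vc <- vc_default()
  Ai <- inverse_relationship_matrix(sim$ped)
  # a one-SNP window has exactly two haplotypes: the minor-allele dosage
  hs <- em_haplotype_frequencies(sim$geno, 13, seed = 1)
  expect_equal(length(hs$haplotypes), 2L)
  X <- htr_design_matrix(hs)
  bt <- block_association_test(X, sim$phenotypes, sim$ped, vc, "MY",
                               A_inv = Ai)
  scan <- single_snp_scan(sim$geno, sim$phenotypes, sim$ped, vc, "MY",
                          snps = 13, A_inv = Ai)
  expect_equal(bt$result$p_raw, scan$p_raw, tolerance = 1e-9)
  expect_equal(bt$result$df, 1L)
})

test_that("the joint Wald statistic does not depend on the reference", {
  sim <- default_sim()
  vc <- vc_default()
  Ai <- inverse_relationship_matrix(sim$ped)
  hs <- pool_rare_haplotypes(em_haplotype_frequencies(sim$geno, 11:12,
                                                      seed = 1))
  X <- htr_design_matrix(hs)
  stats <- vapply(seq_len(ncol(X)), function(r) {
    block_association_test(X, sim$phenotypes, sim$ped, vc, "FP",
                           reference = r, A_inv = Ai)$result$wald_chisq
  }, numeric(1))
  expect_lt(max(stats) - min(stats), 1e-6)
  expect_equal(
    block_association_test(X, sim$phenotypes, sim$ped, vc, "FP",
                           A_inv = Ai)$result$df, ncol(X) - 1L)
})

test_that("EM posterior dosages reproduce true-phase results when phase is certain", {
  # the 2-SNP block pool has three haplotypes, so the double-het pairing is
  # resolved by the data (the fourth haplotype gets frequency ~ 0)
  sim <- default_sim()
  vc <- vc_default()
  Ai <- inverse_relationship_matrix(sim$ped)
  hs <- em_haplotype_frequencies(sim$geno, 11:12, seed = 1)
  X_em <- htr_design_matrix(hs)

  # true dosages from the generator's phases
  cfg <- sim$config
  b <- cfg$block_specs[[2]]
  stopifnot(identical(b$snp_ids, c("SNP11", "SNP12")))
  ph <- sim$phases[[2]]
  true_dos <- sapply(seq_along(b$haplotypes), function(h) {
    (ph[, 1] == h) + (ph[, 2] == h)
  })
  colnames(true_dos) <- b$haplotypes
  common <- intersect(hs$haplotypes, b$haplotypes)
  expect_setequal(hs$haplotypes, b$haplotypes)
  expect_lt(max(abs(unclass(X_em)[, common] - true_dos[, common])), 1e-6)

  hs_true <- haplotype_set(b$haplotypes,
                           colSums(true_dos) / (2 * nrow(true_dos)),
                           dosage = true_dos)
  bt_true <- block_association_test(htr_design_matrix(hs_true),
                                    sim$phenotypes, sim$ped, vc, "MY",
                                    A_inv = Ai)
  bt_em <- block_association_test(X_em, sim$phenotypes, sim$ped, vc, "MY",
                                  A_inv = Ai)
  expect_equal(bt_em$result$p_raw, bt_true$result$p_raw, tolerance = 1e-6)
})
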