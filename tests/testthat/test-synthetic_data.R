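test_that("simulated pedigrees have the half-sib daughter structure", {
  ped <- simulate_pedigree(1, 2)
  expect_equal(nrow(ped), 3L)
  A <- additive_relationship_matrix(ped)
  expect_equal(A["D0001", "D0002"], 0.25)   # half-sibs

  expect_equal(nrow(simulate_pedigree(14, 45)), 644L)
  expect_equal(nrow(simulate_pedigree(14, c(rep(46, 8), rep(45, 6)))), 652L)
  expect_identical(simulate_pedigree(3, 5, seed = 2),
                   simulate_pedigree(3, 5, seed = 2))
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  cfg <- default_sim_config()
  sim1 <- simulate_dataset(cfg, seed = 3)
  sim2 <- simulate_dataset(cfg, seed = 3)
  expect_identical(sim1$geno$codes, sim2$geno$codes)
  expect_identical(sim1$phenotypes, sim2$phenotypes)

  # every daughter carries exactly one sire allele at every SNP
  ped <- sim1$ped
  codes <- sim1$geno$codes
  for (sirename in ped$id[is_founder(ped)]) {
    dtr <- ped$id[!is.na(ped$sire) & ped$sire == sirename]
    for (j in seq_len(ncol(codes))) {
      sg <- codes[sirename, j]
      if (sg == 0L) expect_true(all(codes[dtr, j] <= 1L))
      if (sg == 2L) expect_true(all(codes[dtr, j] >= 1L))
    }
  }

  # single-haplotype pool: everyone homozygous everywhere
  cfg1 <- default_sim_config(
    map = data.frame(snp_id = "S1", chrom = "1", pos = 100L, ref = "A",
                     alt = "C", stringsAsFactors = FALSE),
    block_specs = list(list(snp_ids = "S1", haplotypes = "C", freq = 1)),
    causal_snp = "S1")
  g1 <- simulate_genotypes(simulate_pedigree(2, 3), cfg1, seed = 1)
  expect_true(all(g1$geno$codes %in% c(0L, 2L)))
})

test_that("founder haplotype frequencies recover the generating pool", {
  cfg <- default_sim_config(
    map = data.frame(snp_id = "S1", chrom = "1", pos = 100L, ref = "T",
                     alt = "G", stringsAsFactors = FALSE),
    block_specs = list(list(snp_ids = "S1", haplotypes = c("T", "G"),
                            freq = c(0.5, 0.5))),
    causal_snp = "S1")
  ped <- founder_pedigree(10000)
  g <- simulate_genotypes(ped, cfg, seed = 4)
  freq_G <- mean(g$geno$codes[, 1]) / 2
  se <- sqrt(0.25 / (2 * 10000))
  expect_lt(abs(freq_G - 0.5), 3 * se)
})

test_that("polygenic gene drop has the right moments", {
  cfg <- default_sim_config(traits = "MY")
  ped2 <- simulate_pedigree(2000, 2)
  sg2 <- simulate_genotypes(ped2, cfg, seed = 5)
  sp2 <- simulate_ebv_phenotypes(ped2, sg2, cfg, seed = 5)
  a <- sp2$truth$polygenic[, "MY"]
  sires <- ped2$id[is_founder(ped2)]
  va <- stats::var(a[sires])
  se_va <- cfg$var_a * sqrt(2 / (length(sires) - 1))
  expect_lt(abs(va - cfg$var_a), 3 * se_va)

  # half-sib covariance ~ var_a / 4
  d1 <- a[ped2$id[!is.na(ped2$sire)][c(TRUE, FALSE)]]
  d2 <- a[ped2$id[!is.na(ped2$sire)][c(FALSE, TRUE)]]
  cv <- stats::cov(d1, d2)
  expect_lt(abs(cv - cfg$var_a / 4), 0.03)
})

test_that("EBV noise follows the reliability-weighted residual model", {
  # alpha = 0 and (numerically) no polygenic signal: var(y | REL) ~ var_e/REL
  cfg <- default_sim_config(traits = "MY", alpha_true = 0, var_a = 1e-8)
  ped <- simulate_pedigree(10, 400)
  sg <- simulate_genotypes(ped, cfg, seed = 6)
  sp <- simulate_ebv_phenotypes(ped, sg, cfg, seed = 6)
  ph <- sp$phenotypes
  z <- ph$ebv * sqrt(ph$reliability / cfg$var_e)   # should be ~ N(0, 1)
  expect_lt(abs(stats::var(z) - 1), 3 * sqrt(2 / (nrow(ph) - 1)))
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(ph)))
})

test_that("expression generator hits requested group means", {
  gg <- data.frame(group = c("TT", "TG"), mean = c(0.496, 0.008),
                   sd = c(0, 0), n = c(4, 4))
  ex <- simulate_expression(gg, seed = 1)
  res <- genotype_expression_test(ex, "TT", "TG")
  expect_equal(res$fold_change, 0.496 / 0.008, tolerance = 1e-12)

  same <- data.frame(group = c("A", "B"), mean = c(1, 1), sd = c(0, 0),
                     n = c(3, 3))
  ex2 <- simulate_expression(same, seed = 2)
  expect_equal(genotype_expression_test(ex2, "A", "B")$fold_change, 1)

  expect_identical(simulate_expression(gg, seed = 9),
                   simulate_expression(gg, seed = 9))
})
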