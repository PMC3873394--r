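test_that("EM phasing is exact when there is no phase ambiguity", {
  # all individuals homozygous: haplotype frequencies are direct counts
  codes <- rbind(c(0L, 0L), c(2L, 2L), c(2L, 2L), c(0L, 0L), c(2L, 2L))
  g <- make_geno(codes)
  hs <- em_haplotype_frequencies(g, 1:2, seed = 1)
  expect_equal(sort(unname(hs$freq), decreasing = TRUE), c(0.6, 0.4))
  expect_true(all(abs(rowSums(hs$dosage) - 2) < 1e-9))
  expect_true(all(hs$dosage %in% c(0, 2)))
})

test_that("EM matches the grid-search oracle on the double-heterozygote family", {
  # all individuals double-het: 1-parameter likelihood family over
  # t = f(coupling haplotype); maximum sits on the boundary
  n <- 12
  g <- make_geno(matrix(1L, n, 2))
  hs <- em_haplotype_frequencies(g, 1:2, seed = 3)
  grid <- seq(0, 0.5, by = 1e-4)
  ll_grid <- vapply(grid, function(t) {
    n * log(2 * (t^2 + (0.5 - t)^2))
  }, numeric(1))
  expect_equal(hs$loglik, max(ll_grid), tolerance = 1e-6)
  expect_true(all(diff(hs$loglik_trace) > -1e-9))
})

test_that("general EM agrees with the two-locus count EM", {
  sim <- default_sim()
  for (pair in list(c(4L, 5L), c(11L, 12L), c(1L, 10L))) {
    hs <- em_haplotype_frequencies(sim$geno, pair, seed = 2)
    pl <- pairwise_ld(sim$geno, pair[1], pair[2])
    # match haplotype strings to AB/Ab/aB/ab minor-allele labels
    map <- sim$geno$map
    mk <- function(b1, b2) {
      al <- function(j, bit) {
        minor <- map$minor_allele[j]
        major <- if (minor == map$alt[j]) map$ref[j] else map$alt[j]
        if (bit) minor else major
      }
      paste0(al(pair[1], b1), al(pair[2], b2))
    }
    lab <- c(AB = mk(TRUE, TRUE), Ab = mk(TRUE, FALSE),
             aB = mk(FALSE, TRUE), ab = mk(FALSE, FALSE))
    for (h in names(lab)) {
      f_em <- if (lab[h] %in% hs$haplotypes) unname(hs$freq[lab[h]]) else 0
      expect_equal(f_em, unname(pl$hap_freq[h]), tolerance = 1e-5)
    }
  }
})

test_that("D-prime and r2 match hand computation on phase-certain data", {
  # gamete counts 4 AB, 1 Ab, 1 aB, 4 ab arranged phase-certainly
  codes <- rbind(c(2L, 2L),   # AB/AB
                 c(2L, 1L),   # AB/Ab
                 c(1L, 2L),   # AB/aB
                 c(0L, 0L),   # ab/ab
                 c(0L, 0L))   # ab/ab
  g <- make_geno(codes)
  pl <- pairwise_ld(g, 1, 2)
  # pA = pB = 0.5, D = 0.4 - 0.25 = 0.15, Dmax = 0.25
  expect_equal(pl$dprime, 0.6, tolerance = 1e-9)
  expect_equal(pl$r2, 0.36, tolerance = 1e-9)

  # complete coupling
  cc <- make_geno(rbind(c(2L, 2L), c(2L, 2L), c(0L, 0L), c(1L, 1L)))
  plc <- pairwise_ld(cc, 1, 2)
  expect_equal(plc$dprime, 1)
  expect_equal(plc$r2, 1, tolerance = 1e-6)

  # independent loci drift near zero at large n
  set.seed(8)
  ind <- make_geno(cbind(rbinom(4000, 2, 0.4), rbinom(4000, 2, 0.3)))
  expect_lt(pairwise_ld(ind, 1, 2)$dprime, 0.1)

  expect_error(pairwise_ld(make_geno(cbind(rep(0L, 5), c(0:2, 1L, 1L))), 1, 2),
               "monomorphic")
})

test_that("D-prime confidence intervals behave like likelihood intervals", {
  # perfect LD at n = 500: lower bound essentially at 1
  set.seed(11)
  h <- rbinom(1000, 1, 0.4)
  codes <- cbind(h[1:500] + h[501:1000], h[1:500] + h[501:1000])
  g <- make_geno(codes)
  ci <- dprime_confidence_interval(g, 1, 2)
  expect_gte(ci$lower, 0.98)

  # point estimate always inside; width shrinks with n
  sim <- default_sim()
  ci2 <- dprime_confidence_interval(sim$geno, 4, 5)
  expect_true(ci2$lower <= ci2$dprime && ci2$dprime <= ci2$upper)

  mk_ld <- function(n, seed) {
    set.seed(seed)
    hap <- sample(1:3, 2 * n, replace = TRUE, prob = c(0.45, 0.35, 0.2))
    al <- rbind(c(1L, 1L), c(0L, 0L), c(0L, 1L))
    make_geno(cbind(al[hap[1:n], 1] + al[hap[(n + 1):(2 * n)], 1],
                    al[hap[1:n], 2] + al[hap[(n + 1):(2 * n)], 2]))
  }
  ci_small <- dprime_confidence_interval(mk_ld(10, 13), 1, 2)
  ci_big <- dprime_confidence_interval(mk_ld(1000, 13), 1, 2)
  expect_gt(ci_small$upper - ci_small$lower, ci_big$upper - ci_big$lower)
})

test_that("block detection handles the degenerate panels", {
  # independent SNPs: no blocks
  set.seed(21)
  g <- make_geno(cbind(rbinom(800, 2, 0.4), rbinom(800, 2, 0.35),
                       rbinom(800, 2, 0.3)))
  expect_equal(nrow(detect_blocks(ld_scan(g), g$map)), 0L)

  # one pair in perfect LD: a single 2-SNP block
  set.seed(22)
  h <- rbinom(1600, 1, 0.45)
  gp <- make_geno(cbind(h[1:800] + h[801:1600], h[1:800] + h[801:1600]))
  bl <- detect_blocks(ld_scan(gp), gp$map)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$n_snps, 2L)
})

test_that("rare-haplotype pooling conserves mass and respects the threshold", {
  hs <- haplotype_set(c("AA", "AB", "BA", "BB"), c(0.6, 0.3, 0.06, 0.04),
                      dosage = NULL)
  pooled <- pool_rare_haplotypes(hs, 0.05)
  expect_setequal(pooled$haplotypes, c("AA", "AB", "BA", "pooled"))
  expect_equal(unname(pooled$freq["pooled"]), 0.04)  # 0.06 kept at boundary
  expect_equal(sum(pooled$freq), 1)

  # none rare: identity
  hs2 <- haplotype_set(c("AA", "BB"), c(0.7, 0.3))
  expect_identical(pool_rare_haplotypes(hs2, 0.05), hs2)

  # all rare: error
  hs3 <- haplotype_set(paste0("H", 1:25), rep(0.04, 25))
  expect_error(pool_rare_haplotypes(hs3, 0.05), "below the pooling threshold")

  # dosage columns are summed and rows still sum to 2
  sim <- default_sim()
  hs4 <- em_haplotype_frequencies(sim$geno, 4:9, seed = 1)
  p4 <- pool_rare_haplotypes(hs4, 0.05)
  expect_true(all(abs(rowSums(p4$dosage) - 2) < 1e-9))
  expect_equal(sum(p4$freq), 1, tolerance = 1e-9)
  expect_equal(unname(p4$freq["pooled"]),
               sum(hs4$freq[hs4$freq < 0.05]), tolerance = 1e-12)
})

test_that("oversized EM windows are rejected with guidance", {
  sim <- default_sim()
  expect_error(em_haplotype_frequencies(sim$geno, 1:13, seed = 1),
               "split the region")
})
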