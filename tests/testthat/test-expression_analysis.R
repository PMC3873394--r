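test_that("relative quantification follows the Livak construction", {
  tab <- data.frame(
    sample_id = c("h1", "h2", "m1", "m2"),
    group = c("heart", "heart", "mammary", "mammary"),
    ct_target = c(25, 25, 22, 23),
    ct_reference = c(20, 20, 20, 20))
  rq <- relative_quantification(tab, "heart")
  expect_equal(rq$per_group$mean_rq[rq$per_group$group == "heart"], 1)
  # ddCt = -1 doubles expression relative to a ddCt = 0 sample
  one_less <- rq$per_sample$rq[rq$per_sample$sample_id == "m2"]
  expect_equal(one_less, 2^-(23 - 20 - 5))

  # invariance to a constant added to every Ct value
  tab2 <- tab
  tab2$ct_target <- tab2$ct_target + 3
  tab2$ct_reference <- tab2$ct_reference + 3
  rq2 <- relative_quantification(tab2, "heart")
  expect_equal(rq2$per_sample$rq, rq$per_sample$rq)

  # technical replicates are averaged on the Ct scale first
  tab$replicate <- 1
  tab3 <- rbind(tab, within(tab, { ct_target <- ct_target + 0.2
                                   replicate <- 2 }))
  rq3 <- relative_quantification(tab3, "heart")
  expect_equal(rq3$per_sample$dct[order(rq3$per_sample$sample_id)],
               (tab$ct_target + 0.1 - tab$ct_reference)[order(tab$sample_id)])

  # a many-tissue table keeps the calibrator mean at exactly 1
  set.seed(4)
  tissues <- rep(c("heart", "liver", "lung", "kidney", "mammary", "ovary",
                   "uterus", "muscle"), each = 3)
  big <- data.frame(sample_id = paste0(tissues, rep(1:3, 8)),
                    group = tissues,
                    ct_target = rnorm(24, 24, 2),
                    ct_reference = rnorm(24, 20, 0.5))
  rqb <- relative_quantification(big, "heart")
  expect_equal(rqb$per_group$geo_mean_rq[rqb$per_group$group == "heart"], 1)
  heart_rq <- rqb$per_sample$rq[rqb$per_sample$group == "heart"]
  expect_equal(exp(mean(log(heart_rq))), 1)

  expect_error(relative_quantification(tab, "spleen"), "calibrator")
  tabna <- tab; tabna$ct_reference[2] <- NA
  expect_error(relative_quantification(tabna, "heart"), "reference")
})

test_that("genotype comparisons report fold change and a Welch t-test", {
  tab <- data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("TT", "TG"), each = 4),
    ct_target = c(21, 21.2, 20.8, 21.1, 27, 27.3, 26.8, 27.2),
    ct_reference = 20)
  res <- genotype_expression_test(tab, "TT", "TG")
  expect_gt(res$fold_change, 1)
  expect_lt(res$p, 0.01)
  # a group against itself is fold change 1
  self <- genotype_expression_test(tab, "TT", "TT")
  expect_equal(self$fold_change, 1)
  # pooled-variance variant is exposed
  res_pooled <- genotype_expression_test(tab, "TT", "TG", var_equal = TRUE)
  expect_false(identical(res$p, res_pooled$p))
})
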