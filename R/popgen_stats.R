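# Descriptive and screening statistics: genotype/allele frequencies, the
# Pearson Hardy-Weinberg test, and Bonferroni thresholds.

#' Per-SNP genotype summary
#'
#' Genotype counts and frequencies over non-missing individuals, minor
#' allele frequency, call rate and the Hardy-Weinberg chi-square test.
#' MAF equals half the heterozygote frequency plus the minor-homozygote
#' frequency.
#'
#' @param geno a `genotype_data` object.
#' @param snp SNP index or id; NULL summarises every SNP.
#' @return data frame, one row per summarised SNP.
#' @export
snp_summary <- function(geno, snp = NULL) {
  if (!inherits(geno, "genotype_data")) stop("expected `genotype_data`")
  idx <- if (is.null(snp)) seq_len(ncol(geno$codes)) else {
    if (is.character(snp)) match(snp, geno$map$snp_id) else as.integer(snp)
  }
  if (anyNA(idx) || any(idx < 1L | idx > ncol(geno$codes))) {
    stop("unknown SNP requested")
  }
  out <- lapply(idx, function(j) {
    x <- geno$codes[, j]
    n_called <- sum(!is.na(x))
    if (n_called == 0L) stop("all genotypes missing at SNP ", geno$map$snp_id[j])
    counts <- c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                sum(x == 2L, na.rm = TRUE))
    freqs <- counts / n_called
    maf <- freqs[2] / 2 + freqs[3]
    hwe <- hwe_test(counts)
    data.frame(snp_id = geno$map$snp_id[j], chrom = geno$map$chrom[j],
               pos = geno$map$pos[j], n_called = n_called,
               call_rate = n_called / nrow(geno$codes),
               n_major_hom = counts[1], n_het = counts[2],
               n_minor_hom = counts[3],
               f_major_hom = freqs[1], f_het = freqs[2], f_minor_hom = freqs[3],
               minor_allele = geno$map$minor_allele[j], maf = maf,
               hwe_chisq = hwe$chisq, hwe_p = hwe$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Observed genotype counts (n11, n12, n22) against expectations from the
#' sample allele frequencies; 1 degree of freedom, no continuity
#' correction. A monomorphic locus returns chisq = 0, p = 1.
#'
#' @param genotype_counts length-3 vector of genotype counts.
#' @return list with `chisq`, `df`, `p`.
#' @export
hwe_test <- function(genotype_counts) {
  cnt <- as.numeric(genotype_counts)
  if (length(cnt) != 3L || any(cnt < 0) || any(!is.finite(cnt))) {
    stop("genotype_counts must be three non-negative counts")
  }
  n <- sum(cnt)
  if (n < 1) stop("need at least one genotyped individual")
  p <- (2 * cnt[1] + cnt[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(chisq = 0, df = 1L, p = 1))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((cnt - expd)^2 / expd)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return per-test raw p-value threshold alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}
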