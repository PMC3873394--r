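# Haplotype trend regression with a pedigree polygenic random effect:
# phenotypes regressed on per-individual expected haplotype dosages, with
# a joint Wald chi-square on the k - 1 non-reference haplotype effects.

#' Haplotype trend regression design matrix
#'
#' Expected haplotype dosages per individual for the retained
#' (post-pooling) haplotypes of one block; rows sum to 2. Integer 0/1/2
#' entries when phase is certain, fractional posterior counts otherwise.
#'
#' @param hs a pooled `haplotype_set` with dosages.
#' @return An `htr_design` matrix (columns labelled by haplotype strings,
#'   with a `freq` attribute).
#' @export
htr_design_matrix <- function(hs) {
  if (!inherits(hs, "haplotype_set")) stop("expected `haplotype_set`")
  if (is.null(hs$dosage)) stop("haplotype set carries no dosages")
  k <- length(hs$haplotypes)
  if (k < 2L) stop("need at least 2 haplotypes (k >= 2)")
  X <- hs$dosage
  attr(X, "freq") <- hs$freq
  class(X) <- c("htr_design", class(X))
  X
}

#' Block-level haplotype association test
#'
#' Fits y = 1 mu + X h + a + e by the weighted mixed model equations, with
#' the most frequent haplotype's column dropped as the reference (its
#' dosage is collinear with the intercept through the row-sum constraint),
#' then tests the k - 1 retained haplotype effects jointly with a Wald
#' chi-square on k - 1 degrees of freedom.
#'
#' @param design an `htr_design` matrix (rownames = individual ids).
#' @param phenotypes a `phenotype_table`.
#' @param ped a `pedigree`.
#' @param vc a `variance_components` object for the trait.
#' @param trait trait name.
#' @param n_blocks number of blocks tested (Bonferroni denominator).
#' @param alpha family-wise significance level.
#' @param block_id label for the output row.
#' @param reference haplotype column used as the reference (default: the
#'   most frequent); the joint Wald statistic does not depend on it.
#' @param A_inv optional precomputed inverse relationship matrix.
#' @return list with a one-row `result` data frame (joint test) and an
#'   `effects` data frame of per-haplotype estimates (reference = 0).
#' @export
block_association_test <- function(design, phenotypes, ped, vc, trait,
                                   n_blocks = 1L, alpha = 0.05,
                                   block_id = "block1", reference = NULL,
                                   A_inv = NULL) {
  ph <- .pheno_for_trait(phenotypes, trait)
  freq <- attr(design, "freq")
  if (is.null(freq)) stop("design lacks haplotype frequencies; build it with htr_design_matrix()")
  k <- ncol(design)
  ref <- if (is.null(reference)) which.max(freq) else as.integer(reference)
  rows <- match(ph$id, rownames(design))
  if (anyNA(rows)) stop("phenotyped individual absent from haplotype design")
  Xh <- unclass(design)[rows, -ref, drop = FALSE]
  if (is.null(A_inv)) A_inv <- inverse_relationship_matrix(ped)
  idx_all <- match(ph$id, ped$id)
  if (anyNA(idx_all)) stop("phenotyped individual absent from pedigree")
  X <- cbind(mu = 1, Xh)
  fit <- tryCatch(
    solve_mme(ph$ebv, X, A_inv, vc$var_e / vc$var_a, ph$reliability,
              var_e = vc$var_e, obs_index = idx_all),
    error = function(e) {
      stop("singular haplotype design (collinear haplotypes: ",
           paste(colnames(Xh), collapse = ", "), ")")
    })
  h <- fit$fixed[-1L]
  Vh <- fit$cov_fixed[-1L, -1L, drop = FALSE]
  Vh_inv <- tryCatch(solve(Vh), error = function(e) {
    stop("singular sampling covariance of haplotype effects (",
         paste(colnames(Xh), collapse = ", "), ")")
  })
  wald <- drop(t(h) %*% Vh_inv %*% h)
  df <- k - 1L
  p_raw <- stats::pchisq(wald, df = df, lower.tail = FALSE)
  thr <- bonferroni_threshold(alpha, n_blocks)
  result <- data.frame(id = block_id, effect = NA_real_, se = NA_real_,
                       wald_chisq = wald, df = df, p_raw = p_raw,
                       p_threshold = thr, significant = p_raw < thr,
                       var_explained = NA_real_, trait = trait,
                       stringsAsFactors = FALSE)
  effects <- data.frame(haplotype = colnames(design),
                        frequency = unname(freq),
                        effect = replace(rep(0, k), seq_len(k)[-ref],
                                         unname(h)),
                        se = replace(rep(0, k), seq_len(k)[-ref],
                                     sqrt(diag(Vh))),
                        reference = seq_len(k) == ref,
                        stringsAsFactors = FALSE)
  list(result = result, effects = effects, fit = fit)
}
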