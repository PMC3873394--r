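# Reliability-weighted mixed-model machinery: Henderson's mixed model
# equations with a pedigree polygenic effect, single-SNP Wald scans on EBV
# phenotypes, variance explained by the allele-substitution effect, and
# genotype-class least-squares means.
#
# Model: y = X beta + Z a + e, a ~ N(0, A var_a), e ~ N(0, W var_e) with
# W = diag(1/REL). The MME are built with residual precision diag(REL) and
# polygenic penalty lambda * A^{-1}, lambda = var_e / var_a.

#' Variance components container
#'
#' @param var_a additive polygenic variance.
#' @param var_e residual variance (scaled per individual by 1/reliability).
#' @param var_p phenotypic variance used to scale variance explained.
#' @return A `variance_components` list.
#' @export
variance_components <- function(var_a, var_e, var_p) {
  if (any(c(var_a, var_e, var_p) <= 0)) stop("variance components must be > 0")
  structure(list(var_a = var_a, var_e = var_e, var_p = var_p),
            class = "variance_components")
}

#' Solve Henderson's mixed model equations
#'
#' Fixed effects are estimated jointly with BLUPs of the polygenic effect;
#' the sampling covariance of the fixed effects is the fixed block of the
#' inverse coefficient matrix scaled by `var_e` (equal to (X' V^{-1} X)^{-1}
#' with V = Z A Z' var_a + diag(1/REL) var_e).
#'
#' @param y response vector (EBVs of the phenotyped individuals).
#' @param fixed_design n x p full-column-rank fixed-effect design matrix.
#' @param A_inv inverse additive relationship matrix over all pedigree
#'   individuals.
#' @param lambda variance ratio var_e / var_a (> 0).
#' @param weights per-observation reliabilities in (0, 1].
#' @param var_e residual variance used to scale the sampling covariance.
#' @param obs_index mapping from observations to rows of `A_inv`
#'   (default: identity, requiring length(y) == nrow(A_inv)).
#' @return A `mme_fit` list with elements `fixed`, `cov_fixed`, `blup`,
#'   `n_obs`, `n_random`.
#' @export
solve_mme <- function(y, fixed_design, A_inv, lambda, weights,
                      var_e = 1, obs_index = NULL) {
  X <- as.matrix(fixed_design)
  n <- length(y); p <- ncol(X); q <- nrow(A_inv)
  if (nrow(X) != n || length(weights) != n) stop("dimension mismatch")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (any(weights <= 0 | weights > 1)) stop("reliabilities must lie in (0, 1]")
  if (is.null(obs_index)) {
    if (n != q) stop("length(y) != nrow(A_inv); supply obs_index")
    obs_index <- seq_len(n)
  }
  if (qr(X)$rank < p) stop("rank-deficient fixed-effect design")
  D <- weights
  DX <- X * D
  Cff <- crossprod(X, DX)
  Cfr <- matrix(0, p, q)
  agg <- rowsum(DX, obs_index)
  Cfr[, as.integer(rownames(agg))] <- t(agg)
  rdiag <- numeric(q)
  rd <- rowsum(D, obs_index)
  rdiag[as.integer(rownames(rd))] <- rd
  Crr <- lambda * A_inv
  diag(Crr) <- diag(Crr) + rdiag
  C <- rbind(cbind(Cff, Cfr), cbind(t(Cfr), Crr))
  rhs_f <- crossprod(X, D * y)
  rhs_r <- numeric(q)
  ry <- rowsum(D * y, obs_index)
  rhs_r[as.integer(rownames(ry))] <- ry
  rhs <- c(rhs_f, rhs_r)
  # single factorisation: solutions plus the first p columns of C^{-1}
  Ip <- rbind(diag(p), matrix(0, q, p))
  ch <- tryCatch(chol(C), error = function(e) {
    stop("mixed model equations are numerically singular")
  })
  sol <- backsolve(ch, forwardsolve(t(ch), cbind(rhs, Ip)))
  est <- sol[, 1L]
  Cinv_f <- sol[seq_len(p), -1L, drop = FALSE]
  cov_fixed <- var_e * (Cinv_f + t(Cinv_f)) / 2
  structure(list(fixed = est[seq_len(p)], cov_fixed = cov_fixed,
                 blup = est[p + seq_len(q)], n_obs = n, n_random = q,
                 lambda = lambda, var_e = var_e),
            class = "mme_fit")
}

#' Proportion of phenotypic variance explained by a SNP
#'
#' 2 p (1 - p) alpha^2 / var_p, with p the allele frequency and alpha the
#' average allele-substitution effect (the 0/1/2 dosage regression
#' coefficient).
#'
#' @param maf allele frequency in (0, 1).
#' @param alpha_hat allele-substitution effect estimate (trait units).
#' @param var_p phenotypic variance of the trait.
#' @return fraction of variance explained.
#' @export
variance_explained <- function(maf, alpha_hat, var_p) {
  if (maf <= 0 || maf >= 1) stop("allele frequency must be in (0, 1)")
  if (var_p <= 0) stop("var_p must be > 0")
  2 * maf * (1 - maf) * alpha_hat^2 / var_p
}

.pheno_for_trait <- function(phenotypes, trait) {
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!nrow(ph)) stop("no phenotypes for trait ", trait)
  ph
}

#' Single-SNP mixed-model association scan
#'
#' For each SNP, regresses the EBVs on the minor-allele dosage (0/1/2) with
#' an overall mean, a pedigree polygenic random effect and reliability
#' weights, then tests b = 0 with a Wald chi-square on 1 df. Individuals
#' missing that SNP are dropped for that SNP only. Bonferroni significance
#' is flagged at alpha / (number of SNPs scanned).
#'
#' @param geno a `genotype_data` object.
#' @param phenotypes a `phenotype_table`.
#' @param ped a `pedigree` covering all individuals.
#' @param vc a `variance_components` object for the trait.
#' @param trait trait name to analyse.
#' @param alpha family-wise significance level for the Bonferroni flag.
#' @param snps optional subset of SNP indices/ids (default: all).
#' @param A_inv optional precomputed inverse relationship matrix (must
#'   match the pedigree order).
#' @return data frame of class `association_result`, one row per SNP, with
#'   effect, se, Wald chi-square, p, Bonferroni flag and variance explained.
#' @export
single_snp_scan <- function(geno, phenotypes, ped, vc, trait, alpha = 0.05,
                            snps = NULL, A_inv = NULL) {
  ph <- .pheno_for_trait(phenotypes, trait)
  if (is.null(A_inv)) A_inv <- inverse_relationship_matrix(ped)
  idx_all <- match(ph$id, ped$id)
  if (anyNA(idx_all)) stop("phenotyped individual absent from pedigree")
  gi <- match(ph$id, rownames(geno$codes))
  if (anyNA(gi)) stop("phenotyped individual absent from genotype matrix")
  snp_idx <- if (is.null(snps)) seq_len(ncol(geno$codes)) else {
    if (is.character(snps)) match(snps, geno$map$snp_id) else as.integer(snps)
  }
  n_tests <- length(snp_idx)
  thr <- bonferroni_threshold(alpha, n_tests)
  lambda <- vc$var_e / vc$var_a
  rows <- lapply(snp_idx, function(j) {
    x <- geno$codes[gi, j]
    ok <- !is.na(x)
    xs <- x[ok]
    if (length(unique(xs)) < 2L) {
      warning("monomorphic SNP in analysed individuals: ", geno$map$snp_id[j])
      return(data.frame(id = geno$map$snp_id[j], effect = 0, se = NA_real_,
                        wald_chisq = 0, df = 1L, p_raw = 1, p_threshold = thr,
                        significant = FALSE, var_explained = 0,
                        maf = mean(xs) / 2, n = sum(ok),
                        stringsAsFactors = FALSE))
    }
    fit <- solve_mme(ph$ebv[ok], cbind(mu = 1, dosage = xs), A_inv, lambda,
                     ph$reliability[ok], var_e = vc$var_e,
                     obs_index = idx_all[ok])
    b <- unname(fit$fixed[2L]); v <- fit$cov_fixed[2L, 2L]
    wald <- b^2 / v
    p_raw <- stats::pchisq(wald, df = 1L, lower.tail = FALSE)
    maf <- mean(xs) / 2
    data.frame(id = geno$map$snp_id[j], effect = b, se = sqrt(v),
               wald_chisq = wald, df = 1L, p_raw = p_raw, p_threshold = thr,
               significant = p_raw < thr,
               var_explained = variance_explained(maf, b, vc$var_p),
               maf = maf, n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trait <- trait
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

# maximal cliques of an undirected adjacency matrix (tiny k); Bron-Kerbosch
.max_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nv <- setdiff(which(adj[v, ] > 0), v)
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

# compact letter display: classes in `ord` (display order); nsd = logical
# adjacency of "not significantly different"
.letter_groups <- function(nsd, ord, letters_pool) {
  cl <- .max_cliques(nsd)
  # order cliques by the best-ranked member
  rank_of <- match(seq_len(nrow(nsd)), ord)
  cl <- cl[order(vapply(cl, function(x) min(rank_of[x]), numeric(1)))]
  lab <- rep("", nrow(nsd))
  for (i in seq_along(cl)) {
    lab[cl[[i]]] <- paste0(lab[cl[[i]]], letters_pool[i])
  }
  lab
}

#' Genotype-class least-squares means
#'
#' Refits the mixed model with the SNP genotype as a class effect
#' (cell-means coding), returning each class's estimable mean with its
#' standard error, all pairwise Wald z-tests, and letter groupings at the
#' 0.05 (lower-case) and 0.01 (upper-case) levels. Classes with fewer than
#' two individuals are reported but excluded from the letter display.
#'
#' @inheritParams single_snp_scan
#' @param snp SNP index or id.
#' @return list with `lsm` (per-class means) and `pairwise` (z-tests).
#' @export
genotype_class_lsm <- function(geno, phenotypes, ped, vc, trait, snp,
                               A_inv = NULL) {
  ph <- .pheno_for_trait(phenotypes, trait)
  if (is.null(A_inv)) A_inv <- inverse_relationship_matrix(ped)
  idx_all <- match(ph$id, ped$id)
  j <- if (is.character(snp)) match(snp, geno$map$snp_id) else as.integer(snp)
  x <- geno$codes[match(ph$id, rownames(geno$codes)), j]
  ok <- !is.na(x)
  xs <- x[ok]
  classes <- sort(unique(xs))
  if (length(classes) < 2L) stop("fewer than two genotype classes at SNP ",
                                 geno$map$snp_id[j])
  X <- sapply(classes, function(cl) as.numeric(xs == cl))
  colnames(X) <- paste0("g", classes)
  fit <- solve_mme(ph$ebv[ok], X, A_inv, vc$var_e / vc$var_a,
                   ph$reliability[ok], var_e = vc$var_e,
                   obs_index = idx_all[ok])
  est <- fit$fixed; V <- fit$cov_fixed
  nclass <- vapply(classes, function(cl) sum(xs == cl), numeric(1))
  small <- nclass < 2
  if (any(small)) {
    warning("genotype class(es) with < 2 individuals excluded from letters")
  }
  k <- length(classes)
  pw <- list()
  pmat05 <- matrix(FALSE, k, k); pmat01 <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      se <- sqrt(V[a, a] + V[b, b] - 2 * V[a, b])
      z <- (est[a] - est[b]) / se
      p <- 2 * stats::pnorm(-abs(z))
      pw[[length(pw) + 1L]] <- data.frame(class_a = colnames(X)[a],
                                          class_b = colnames(X)[b],
                                          diff = est[a] - est[b], se = se,
                                          z = z, p = p,
                                          stringsAsFactors = FALSE)
      pmat05[a, b] <- pmat05[b, a] <- p >= 0.05
      pmat01[a, b] <- pmat01[b, a] <- p >= 0.01
    }
  }
  diag(pmat05) <- diag(pmat01) <- TRUE
  use <- which(!small)
  ord <- order(-est)
  lab05 <- rep("", k); lab01 <- rep("", k)
  if (length(use) >= 2L) {
    sub05 <- pmat05[use, use, drop = FALSE]
    sub01 <- pmat01[use, use, drop = FALSE]
    ord_use <- order(-est[use])
    lab05[use] <- .letter_groups(sub05, ord_use, letters)
    lab01[use] <- .letter_groups(sub01, ord_use, LETTERS)
  }
  lsm <- data.frame(genotype_class = classes, n = nclass, lsm = unname(est),
                    se = sqrt(diag(V)), letters_05 = lab05,
                    letters_01 = lab01, stringsAsFactors = FALSE)
  list(snp_id = geno$map$snp_id[j], trait = trait, lsm = lsm,
       pairwise = do.call(rbind, pw))
}

#' EM-REML variance-component estimation for the weighted animal model
#'
#' Iterates Henderson's EM-REML updates on the mixed model equations:
#' var_a <- (a' A^{-1} a + var_e tr(A^{-1} C^{aa})) / q and
#' var_e <- y' D (y - X b - Z a) / (n - p), with D = diag(REL).
#' Intended for synthetic-data checks; routine analyses take variance
#' components from the national evaluation as inputs.
#'
#' @param y response vector.
#' @param fixed_design fixed-effect design matrix.
#' @param ped a `pedigree`.
#' @param weights per-observation reliabilities.
#' @param obs_index observation-to-pedigree mapping.
#' @param init list(var_a, var_e) starting values.
#' @param max_iter,tol iteration controls.
#' @return list with `var_a`, `var_e`, `n_iter`, `converged`.
#' @export
reml_em <- function(y, fixed_design, ped, weights, obs_index = NULL,
                    init = list(var_a = 1, var_e = 1), max_iter = 200L,
                    tol = 1e-6) {
  X <- as.matrix(fixed_design)
  A_inv <- inverse_relationship_matrix(ped)
  q <- nrow(A_inv); n <- length(y); p <- ncol(X)
  if (is.null(obs_index)) obs_index <- seq_len(n)
  va <- init$var_a; ve <- init$var_e
  D <- weights
  Z <- matrix(0, n, q); Z[cbind(seq_len(n), obs_index)] <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- ve / va
    fit <- solve_mme(y, X, A_inv, lambda, D, var_e = ve,
                     obs_index = obs_index)
    a <- fit$blup; b <- fit$fixed
    # random-effect block of the inverse coefficient matrix
    DX <- X * D
    Cff <- crossprod(X, DX)
    Cfr <- matrix(0, p, q)
    agg <- rowsum(DX, obs_index)
    Cfr[, as.integer(rownames(agg))] <- t(agg)
    rdiag <- numeric(q)
    rd <- rowsum(D, obs_index)
    rdiag[as.integer(rownames(rd))] <- rd
    Crr <- lambda * A_inv
    diag(Crr) <- diag(Crr) + rdiag
    C <- rbind(cbind(Cff, Cfr), cbind(t(Cfr), Crr))
    Cinv <- chol2inv(chol(C))
    Caa <- Cinv[p + seq_len(q), p + seq_len(q)]
    va_new <- (sum(a * (A_inv %*% a)) + ve * sum(A_inv * Caa)) / q
    resid <- y - X %*% b - Z %*% a
    ve_new <- sum(D * y * resid) / (n - p)
    if (ve_new <= 0) ve_new <- ve / 2
    if (abs(va_new - va) < tol * (1 + va) &&
        abs(ve_new - ve) < tol * (1 + ve)) {
      va <- va_new; ve <- ve_new; converged <- TRUE; break
    }
    va <- va_new; ve <- ve_new
  }
  list(var_a = va, var_e = ve, n_iter = it, converged = converged)
}
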