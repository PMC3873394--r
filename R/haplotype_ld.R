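# Haplotype-frequency estimation by EM over diplotype expansions, pairwise
# D'/r2 linkage disequilibrium, grid-likelihood D' confidence intervals,
# Gabriel-style block detection, and rare-haplotype pooling. Windows are
# small (candidate-gene scale), so the EM enumerates compatible haplotype
# pairs exactly.

.MAX_EM_WINDOW <- 12L

#' Construct a haplotype set
#'
#' @param haplotypes character vector of allele strings (map order).
#' @param freq frequencies summing to 1.
#' @param dosage optional n x k matrix of per-individual expected haplotype
#'   dosages (rows sum to 2).
#' @param snp_indices optional SNP indices of the window.
#' @param loglik optional EM log-likelihood.
#' @return A `haplotype_set` object.
#' @export
haplotype_set <- function(haplotypes, freq, dosage = NULL,
                          snp_indices = NULL, loglik = NA_real_) {
  freq <- as.numeric(freq)
  if (length(freq) != length(haplotypes)) stop("haplotypes/freq length mismatch")
  if (any(freq < -1e-12)) stop("negative haplotype frequency")
  if (abs(sum(freq) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  names(freq) <- haplotypes
  if (!is.null(dosage)) {
    dosage <- as.matrix(dosage)
    if (ncol(dosage) != length(haplotypes)) stop("dosage/haplotype mismatch")
    colnames(dosage) <- haplotypes
    if (any(abs(rowSums(dosage) - 2) > 1e-9)) {
      stop("each dosage row must sum to 2")
    }
  }
  structure(list(haplotypes = haplotypes, freq = freq, dosage = dosage,
                 snp_indices = snp_indices, loglik = loglik),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$haplotypes), "haplotypes\n")
  print(round(x$freq, 4))
  invisible(x)
}

# ordered compatible haplotype pairs for one genotype pattern; haplotypes
# encoded as integers with bit j-1 = minor allele at window SNP j
.pattern_pairs <- function(g) {
  choices <- lapply(g, function(x) {
    if (is.na(x)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    else if (x == 0L) list(c(0L, 0L))
    else if (x == 2L) list(c(1L, 1L))
    else list(c(0L, 1L), c(1L, 0L))
  })
  combo <- expand.grid(lapply(choices, seq_along), KEEP.OUT.ATTRS = FALSE)
  h1 <- integer(nrow(combo)); h2 <- integer(nrow(combo))
  for (j in seq_along(g)) {
    picks <- choices[[j]][combo[[j]]]
    h1 <- h1 + vapply(picks, `[`, integer(1), 1L) * 2L^(j - 1L)
    h2 <- h2 + vapply(picks, `[`, integer(1), 2L) * 2L^(j - 1L)
  }
  cbind(h1, h2)
}

.accum <- function(idx, w, n) {
  out <- numeric(n)
  r <- rowsum(w, idx)
  out[as.integer(rownames(r))] <- r
  out
}

.hap_code_to_string <- function(code, major, minor) {
  k <- length(major)
  bits <- (code %/% 2L^(seq_len(k) - 1L)) %% 2L
  paste(ifelse(bits == 1L, minor, major), collapse = "")
}

#' EM haplotype-frequency estimation on unphased genotypes
#'
#' Exact EM over the enumeration of haplotype pairs compatible with each
#' individual's multi-SNP genotype; missing genotypes are marginalised over
#' both alleles. Returns maximum-likelihood haplotype frequencies, each
#' individual's posterior expected haplotype dosages (rows sum to 2) and a
#' monotone non-decreasing log-likelihood trace. Multiple seeded restarts
#' guard against saddle points of the likelihood.
#'
#' @param geno a `genotype_data` object.
#' @param snp_indices SNP indices (or ids) of the window; at most 12 SNPs.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @param n_restarts number of seeded restarts (first is uniform).
#' @param seed RNG seed for restart jitter.
#' @param min_freq haplotypes whose estimated frequency falls below this
#'   (numerical zeros of the EM) are dropped from the returned set.
#' @return A `haplotype_set` with `loglik_trace` and `converged` fields.
#' @export
em_haplotype_frequencies <- function(geno, snp_indices, max_iter = 1000L,
                                     tol = 1e-8, n_restarts = 5L, seed = 1L,
                                     min_freq = 1e-8) {
  if (!inherits(geno, "genotype_data")) stop("expected `genotype_data`")
  if (is.character(snp_indices)) snp_indices <- match(snp_indices, geno$map$snp_id)
  snp_indices <- as.integer(snp_indices)
  k <- length(snp_indices)
  if (k > .MAX_EM_WINDOW) {
    stop("window of ", k, " SNPs exceeds the enumeration limit (",
         .MAX_EM_WINDOW, "); split the region into blocks first")
  }
  G <- geno$codes[, snp_indices, drop = FALSE]
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 individuals")
  keys <- apply(G, 1L, paste, collapse = ",")
  upat <- unique(keys)
  pat_rows <- match(keys, upat)
  pat_count <- tabulate(pat_rows, nbins = length(upat))
  pat_pairs <- lapply(upat, function(kk) {
    g <- suppressWarnings(as.integer(strsplit(kk, ",", fixed = TRUE)[[1L]]))
    .pattern_pairs(g)
  })
  cand <- sort(unique(unlist(pat_pairs)))
  nh <- length(cand)
  pat_ia <- lapply(pat_pairs, function(m) match(m[, 1L], cand))
  pat_ib <- lapply(pat_pairs, function(m) match(m[, 2L], cand))

  run_em <- function(f) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ll <- 0
      ec <- numeric(nh)
      for (p in seq_along(upat)) {
        ia <- pat_ia[[p]]; ib <- pat_ib[[p]]
        w <- f[ia] * f[ib]
        s <- sum(w)
        if (s <= 0) { ll <- -Inf; break }
        ll <- ll + pat_count[p] * log(s)
        add <- pat_count[p] * (w / s)
        ec <- ec + .accum(c(ia, ib), c(add, add), nh)
      }
      if (!is.finite(ll)) return(list(ll = -Inf, f = f, trace = trace,
                                      converged = FALSE))
      if (length(trace) && ll < trace[length(trace)] - 1e-9) {
        stop("EM log-likelihood decreased; this is a bug")
      }
      trace <- c(trace, ll)
      f <- ec / (2 * n)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(ll = trace[length(trace)], f = f, trace = trace, converged = converged)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      f0 <- rep(1 / nh, nh)
    } else {
      set.seed((as.integer(seed) + 131L * r) %% .Machine$integer.max)
      f0 <- stats::runif(nh, 0.5, 1.5)
      f0 <- f0 / sum(f0)
    }
    fit <- run_em(f0)
    if (is.null(best) || fit$ll > best$ll + 1e-12) best <- fit
  }
  f <- best$f

  # posterior dosages at the final frequencies
  dosage <- matrix(0, n, nh)
  pat_dos <- lapply(seq_along(upat), function(p) {
    ia <- pat_ia[[p]]; ib <- pat_ib[[p]]
    w <- f[ia] * f[ib]
    w <- w / sum(w)
    .accum(c(ia, ib), c(w, w), nh)
  })
  for (i in seq_len(n)) dosage[i, ] <- pat_dos[[pat_rows[i]]]
  rownames(dosage) <- rownames(G)

  minor <- geno$map$minor_allele[snp_indices]
  major <- ifelse(minor == geno$map$alt[snp_indices],
                  geno$map$ref[snp_indices], geno$map$alt[snp_indices])
  haps <- vapply(cand, .hap_code_to_string, character(1), major = major,
                 minor = minor)
  # drop numerical zeros of the EM, then restore the exact invariants
  keep <- which(f >= min_freq)
  f <- f[keep]; haps <- haps[keep]
  dosage <- dosage[, keep, drop = FALSE]
  dosage <- dosage * (2 / rowSums(dosage))
  ord <- order(-f, haps)
  hs <- haplotype_set(haps[ord], f[ord] / sum(f),
                      dosage = dosage[, ord, drop = FALSE],
                      snp_indices = snp_indices, loglik = best$ll)
  hs$loglik_trace <- best$trace
  hs$converged <- best$converged
  hs
}

# 3x3 two-locus genotype count table (minor-allele dosages), complete pairs
.two_locus_counts <- function(geno, snp_i, snp_j) {
  xi <- geno$codes[, snp_i]; xj <- geno$codes[, snp_j]
  ok <- !is.na(xi) & !is.na(xj)
  cnt <- matrix(0, 3L, 3L)
  for (a in 0:2) for (b in 0:2) cnt[a + 1L, b + 1L] <- sum(xi[ok] == a & xj[ok] == b)
  cnt
}

# EM for two-locus haplotype frequencies from a 3x3 count table; alleles
# A/B are the minor alleles at the two SNPs. Returns c(AB, Ab, aB, ab).
.two_locus_em <- function(cnt, max_iter = 1000L, tol = 1e-12) {
  n <- sum(cnt)
  pA <- sum(cnt * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(cnt * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  # known (phase-certain) haplotype counts
  known <- c(AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
             Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
             aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
             ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  ndh <- cnt[2, 2]
  for (it in seq_len(max_iter)) {
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    pcoup <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    e <- known + ndh * c(pcoup, 1 - pcoup, 1 - pcoup, pcoup)
    fn <- e / (2 * n)
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  f
}

.dprime_from_freqs <- function(f) {
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  list(D = D, dprime = min(dprime, 1), r2 = min(r2, 1),
       p_i = unname(pA), p_j = unname(pB))
}

#' Pairwise linkage disequilibrium (D', r2)
#'
#' Two-locus haplotype frequencies from the exact 2-SNP EM, then
#' D = p_AB - p_A p_B, D' = |D| / D_max and r2 = D^2 / (p_A p_a p_B p_b).
#' Alleles are the minor alleles of the two SNPs.
#'
#' @param geno a `genotype_data` object.
#' @param snp_i,snp_j SNP indices or ids.
#' @return list with `dprime`, `r2`, `D`, `hap_freq`, `p_i`, `p_j`, `n`.
#' @export
pairwise_ld <- function(geno, snp_i, snp_j) {
  if (is.character(snp_i)) snp_i <- match(snp_i, geno$map$snp_id)
  if (is.character(snp_j)) snp_j <- match(snp_j, geno$map$snp_id)
  cnt <- .two_locus_counts(geno, snp_i, snp_j)
  n <- sum(cnt)
  pA <- sum(cnt * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(cnt * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) {
    stop("monomorphic SNP in LD computation")
  }
  f <- .two_locus_em(cnt)
  stats <- .dprime_from_freqs(f)
  c(stats, list(hap_freq = f, n = n))
}

# genotype class probabilities from two-locus haplotype frequencies
.two_locus_geno_probs <- function(f) {
  AB <- f[1]; Ab <- f[2]; aB <- f[3]; ab <- f[4]
  m <- matrix(0, 3, 3)
  m[1, 1] <- ab^2;        m[1, 2] <- 2 * aB * ab;          m[1, 3] <- aB^2
  m[2, 1] <- 2 * Ab * ab; m[2, 2] <- 2 * (AB * ab + Ab * aB); m[2, 3] <- 2 * AB * aB
  m[3, 1] <- Ab^2;        m[3, 2] <- 2 * AB * Ab;          m[3, 3] <- AB^2
  m
}

#' Likelihood-profile confidence interval for D'
#'
#' Evaluates the two-locus multinomial likelihood on a D' grid with allele
#' frequencies held at their MLEs and the sign of D fixed at the point
#' estimate, then takes the (1 - coverage) and coverage percentiles of the
#' normalised cumulative likelihood (the Haploview/Gabriel convention).
#'
#' @param geno a `genotype_data` object.
#' @param snp_i,snp_j SNP indices or ids.
#' @param coverage percentile used for the upper bound (default 0.95).
#' @param grid_step D' grid resolution.
#' @return list with `lower`, `upper`, `dprime`.
#' @export
dprime_confidence_interval <- function(geno, snp_i, snp_j, coverage = 0.95,
                                       grid_step = 0.001) {
  if (is.character(snp_i)) snp_i <- match(snp_i, geno$map$snp_id)
  if (is.character(snp_j)) snp_j <- match(snp_j, geno$map$snp_id)
  cnt <- .two_locus_counts(geno, snp_i, snp_j)
  point <- pairwise_ld(geno, snp_i, snp_j)
  sgn <- if (point$D >= 0) 1 else -1
  pA <- point$p_i; pB <- point$p_j
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    f <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    f <- pmax(f, 0)
    pr <- .two_locus_geno_probs(f)
    use <- cnt > 0
    if (any(pr[use] <= 0)) return(-Inf)
    sum(cnt[use] * log(pr[use]))
  }, numeric(1))
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  lower <- grid[min(which(cdf >= 1 - coverage))]
  upper <- grid[min(which(cdf >= coverage))]
  list(lower = min(lower, point$dprime), upper = max(upper, point$dprime),
       dprime = point$dprime)
}

#' Pairwise LD scan over a SNP panel
#'
#' Computes D', r2 and the D' confidence interval for every SNP pair;
#' monomorphic SNPs yield NA rows.
#'
#' @param geno a `genotype_data` object.
#' @param coverage CI percentile (see [dprime_confidence_interval()]).
#' @return data frame with one row per SNP pair.
#' @export
ld_scan <- function(geno, coverage = 0.95) {
  m <- ncol(geno$codes)
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      res <- tryCatch({
        ci <- dprime_confidence_interval(geno, i, j, coverage = coverage)
        pt <- pairwise_ld(geno, i, j)
        data.frame(i = i, j = j, snp_i = geno$map$snp_id[i],
                   snp_j = geno$map$snp_id[j], dprime = pt$dprime,
                   r2 = pt$r2, ci_lower = ci$lower, ci_upper = ci$upper,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(i = i, j = j, snp_i = geno$map$snp_id[i],
                   snp_j = geno$map$snp_id[j], dprime = NA_real_,
                   r2 = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ld_result", "data.frame")
  out
}

#' Detect haplotype blocks from D' confidence intervals
#'
#' Gabriel-style rule: a pair is in "strong LD" when its CI lower bound is
#' at least `strong_lower` and upper bound at least `strong_upper`; it shows
#' "strong recombination" when the upper bound falls below `recomb_upper`.
#' A contiguous SNP range is a candidate block when at least `min_frac` of
#' its informative pairs are in strong LD; non-overlapping blocks are picked
#' greedily from longest to shortest.
#'
#' @param ld output of [ld_scan()].
#' @param map SNP map (for chromosome contiguity).
#' @param strong_lower,strong_upper,recomb_upper,min_frac Gabriel thresholds.
#' @return A `block_partition` data frame (columns start, end, n_snps).
#' @export
detect_blocks <- function(ld, map, strong_lower = 0.70, strong_upper = 0.98,
                          recomb_upper = 0.90, min_frac = 0.95) {
  m <- nrow(map)
  strong <- !is.na(ld$ci_lower) & ld$ci_lower >= strong_lower &
    ld$ci_upper >= strong_upper
  recomb <- !is.na(ld$ci_upper) & ld$ci_upper < recomb_upper
  informative <- strong | recomb
  cand <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (length(unique(map$chrom[i:j])) > 1L) next
      sel <- ld$i >= i & ld$j <= j
      n_inf <- sum(informative[sel])
      if (n_inf < 1L) next
      if (sum(strong[sel]) / n_inf >= min_frac) {
        cand[[length(cand) + 1L]] <- c(start = i, end = j)
      }
    }
  }
  if (!length(cand)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0))
    class(out) <- c("block_partition", "data.frame")
    return(out)
  }
  cm <- do.call(rbind, cand)
  cm <- cm[order(-(cm[, "end"] - cm[, "start"]), cm[, "start"]), ,
           drop = FALSE]
  taken <- logical(m)
  keep <- list()
  for (r in seq_len(nrow(cm))) {
    rng <- cm[r, "start"]:cm[r, "end"]
    if (!any(taken[rng])) {
      taken[rng] <- TRUE
      keep[[length(keep) + 1L]] <- cm[r, ]
    }
  }
  km <- do.call(rbind, keep)
  out <- data.frame(start = km[, "start"], end = km[, "end"])
  out <- out[order(out$start), , drop = FALSE]
  out$n_snps <- out$end - out$start + 1L
  rownames(out) <- NULL
  class(out) <- c("block_partition", "data.frame")
  out
}

#' Pool rare haplotypes into a single class
#'
#' Haplotypes with frequency below `threshold` are merged into one "pooled"
#' pseudo-haplotype whose frequency and dosage column are the sums of its
#' members.
#'
#' @param hs a `haplotype_set`.
#' @param threshold relative-frequency cutoff (default 0.05).
#' @return A `haplotype_set` with the pooled class appended (if any).
#' @export
pool_rare_haplotypes <- function(hs, threshold = 0.05) {
  if (!inherits(hs, "haplotype_set")) stop("expected `haplotype_set`")
  rare <- hs$freq < threshold
  if (all(rare)) stop("all haplotypes are below the pooling threshold")
  if (!any(rare)) return(hs)
  keep <- which(!rare)
  haps <- c(hs$haplotypes[keep], "pooled")
  freq <- c(hs$freq[keep], sum(hs$freq[rare]))
  dosage <- NULL
  if (!is.null(hs$dosage)) {
    dosage <- cbind(hs$dosage[, keep, drop = FALSE],
                    pooled = rowSums(hs$dosage[, rare, drop = FALSE]))
  }
  out <- haplotype_set(haps, freq, dosage = dosage,
                       snp_indices = hs$snp_indices, loglik = hs$loglik)
  out$pooled_members <- hs$haplotypes[rare]
  out
}
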