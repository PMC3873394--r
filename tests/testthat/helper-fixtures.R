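# Shared fixtures and independent oracles used across the suite.

# cached default simulated dataset (study-scale: 14 sires, 638 daughters)
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(default_sim_config(), seed = seed)
  }
  .sim_cache[[key]]
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# build a genotype_data object directly from minor-allele codes
make_geno <- function(codes, minor_is_alt = TRUE) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("I%03d", seq_len(nrow(codes)))
  }
  map <- data.frame(snp_id = paste0("S", seq_len(m)), chrom = "1",
                    pos = seq_len(m) * 1000L, ref = "A", alt = "C",
                    minor_allele = if (minor_is_alt) "C" else "A",
                    stringsAsFactors = FALSE)
  genotype_data(codes, map)
}

# random valid pedigree of n individuals (parents drawn among predecessors)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("P%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 2 && stats::runif(1) < 0.7) {
      sire[i] <- id[sample.int(i - 1L, 1L)]
    }
    if (i >= 2 && stats::runif(1) < 0.7) {
      dam[i] <- id[sample.int(i - 1L, 1L)]
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                         stringsAsFactors = FALSE))
}

# Wright path-counting oracle for the additive relationship matrix:
# A_xy = sum over common ancestors and pairs of descent paths that meet
# only at the ancestor of (1/2)^(L1 + L2 - 1) * (1 + F_ancestor).
# Independent of the tabular recursion used by the package.
oracle_A <- function(ped) {
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  up_paths <- function(i) {
    out <- list(i)
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) for (pp in up_paths(p)) out <- c(out, list(c(i, pp)))
    }
    out
  }
  paths <- lapply(seq_len(n), up_paths)
  memoF <- rep(NA_real_, n)
  kinship <- function(x, y) {
    tot <- 0
    for (a in paths[[x]]) {
      for (b in paths[[y]]) {
        anc <- a[length(a)]
        if (anc != b[length(b)]) next
        ia <- a[-length(a)]; ib <- b[-length(b)]
        if (length(intersect(ia, ib))) next
        tot <- tot + 0.5^(length(a) + length(b) - 1) * (1 + Fcoef(anc))
      }
    }
    tot
  }
  Fcoef <- function(i) {
    if (!is.na(memoF[i])) return(memoF[i])
    f <- if (is.na(sire[i]) || is.na(dam[i])) 0 else kinship(sire[i], dam[i])
    memoF[i] <<- f
    f
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (x in seq_len(n)) for (y in x:n) A[x, y] <- A[y, x] <- 2 * kinship(x, y)
  A
}

# direct generalised least squares with V = Z A Z' var_a + diag(1/REL) var_e
gls_oracle <- function(y, X, A, var_a, var_e, rel, obs_index) {
  n <- length(y)
  Z <- matrix(0, n, nrow(A))
  Z[cbind(seq_len(n), obs_index)] <- 1
  V <- Z %*% A %*% t(Z) * var_a + diag(var_e / rel, n)
  Vi <- solve(V)
  covb <- solve(t(X) %*% Vi %*% X)
  list(fixed = drop(covb %*% t(X) %*% Vi %*% y), cov_fixed = covb)
}

# small variance-components object shared by model tests
vc_default <- function() variance_components(0.3, 0.7, 1)

# random small mixed-model instance with a half-sib pedigree
random_instance <- function(seed, n_max = 50) {
  set.seed(seed)
  n_s <- sample(2:5, 1)
  per <- sample(2:8, 1)
  ped <- simulate_pedigree(n_s, per)
  n_obs <- min(nrow(ped) - n_s, n_max)
  daughters <- ped$id[!is_founder(ped)][seq_len(n_obs)]
  obs_index <- match(daughters, ped$id)
  x <- stats::rbinom(n_obs, 2, 0.3)
  while (length(unique(x)) < 2L) x <- stats::rbinom(n_obs, 2, 0.3)
  X <- cbind(1, x)
  rel <- stats::runif(n_obs, 0.4, 1)
  y <- stats::rnorm(n_obs, X %*% c(1, 0.5), 1)
  list(ped = ped, X = X, y = y, rel = rel, obs_index = obs_index)
}

# founders-only pedigree (unrelated panel) of n individuals
founder_pedigree <- function(n) {
  as_pedigree(data.frame(id = sprintf("F%04d", seq_len(n)),
                         sire = NA_character_, dam = NA_character_,
                         stringsAsFactors = FALSE))
}
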