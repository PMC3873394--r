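# Synthetic daughter-design generator. Emulates the analysed study
# conditions: a half-sib design of 14 sires and 638 daughters, a 13-SNP
# candidate-gene panel organised in two high-LD haplotype blocks plus
# unlinked SNPs, EBV phenotypes generated under the weighted animal model
# (residual variance inversely proportional to reliability), and
# genotype-dependent qPCR expression data. Every stage is deterministic
# given (config, seed) via derived sub-seeds.

.substream <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

#' Default simulation configuration
#'
#' The defaults mirror the daughter design the package analyses: 14 sire
#' half-sib families totalling 638 daughters; a 13-SNP candidate-gene panel
#' on chromosome 14 with a 6-SNP block (three common haplotypes at 33.5 /
#' 33.1 / 25.6 % plus six rare ones totalling 7.8 %), a 2-SNP block
#' (44.0 / 38.8 / 17.2 %) and five unlinked SNPs with minor-allele
#' frequencies between 0.013 and 0.469; a causal SNP with an
#' allele-substitution effect of 0.1 phenotypic SD; variance components
#' var_a = 0.3, var_e = 0.7, var_p = 1; and EBV reliabilities uniform on
#' (0.5, 0.99).
#'
#' @param ... named overrides of any configuration field.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(...) {
  map <- data.frame(
    snp_id = paste0("SNP", 1:13),
    chrom = "14",
    pos = c(3895208L, 3916050L, 3916093L, 3934715L, 3968605L, 4012367L,
            4014815L, 4024010L, 4025639L, 4028294L, 4046579L, 4059863L,
            4061098L),
    ref = c("T", "T", "G", "C", "G", "T", "A", "A", "T", "C", "C", "A", "T"),
    alt = c("G", "C", "A", "T", "A", "C", "G", "G", "C", "T", "A", "C", "G"),
    stringsAsFactors = FALSE)
  block_specs <- list(
    list(snp_ids = paste0("SNP", 4:9),
         haplotypes = c("TGTAAT", "CGTAAT", "TATGAC", "CGCAGT", "CGCAAT",
                        "CATGAC", "TATAAC", "TATGAT", "TGCAAT"),
         freq = c(0.335, 0.331, 0.256, 0.013, 0.013, 0.013, 0.013, 0.013,
                  0.013)),
    list(snp_ids = c("SNP11", "SNP12"),
         haplotypes = c("CC", "AC", "CA"),
         freq = c(0.440, 0.388, 0.172)),
    list(snp_ids = "SNP1", haplotypes = c("T", "G"), freq = c(0.620, 0.380)),
    list(snp_ids = "SNP2", haplotypes = c("T", "C"), freq = c(0.987, 0.013)),
    list(snp_ids = "SNP3", haplotypes = c("G", "A"), freq = c(0.531, 0.469)),
    list(snp_ids = "SNP10", haplotypes = c("C", "T"), freq = c(0.618, 0.382)),
    list(snp_ids = "SNP13", haplotypes = c("T", "G"), freq = c(0.723, 0.277)))
  cfg <- list(
    n_sires = 14L,
    daughters_per_sire = c(rep(46L, 8L), rep(45L, 6L)),
    map = map,
    block_specs = block_specs,
    causal_snp = "SNP13",
    alpha_true = 0.1,
    var_a = 0.3,
    var_e = 0.7,
    var_p = 1.0,
    reliability_range = c(0.5, 0.99),
    traits = c("MY", "FY", "PY", "FP", "PP"),
    mu = 0,
    seed = 42L)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg a simulation configuration list.
#' @return The validated `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sires >= 1L, all(cfg$daughters_per_sire >= 1L))
  if (cfg$var_a <= 0 || cfg$var_e <= 0) stop("var_a and var_e must be > 0")
  rr <- cfg$reliability_range
  if (rr[1] <= 0 || rr[2] > 1 || rr[1] > rr[2]) {
    stop("reliability_range must lie within (0, 1]")
  }
  covered <- character(0)
  for (b in cfg$block_specs) {
    if (abs(sum(b$freq) - 1) > 1e-9) {
      stop("haplotype pool frequencies must sum to 1")
    }
    if (any(nchar(b$haplotypes) != length(b$snp_ids))) {
      stop("haplotype string length must match block SNP count")
    }
    covered <- c(covered, b$snp_ids)
  }
  if (!setequal(covered, cfg$map$snp_id) || anyDuplicated(covered)) {
    stop("block specs must cover each mapped SNP exactly once")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a half-sib daughter-design pedigree
#'
#' Each daughter has a known sire and an unknown dam (dams are treated as
#' unrelated founders). Sires are founders.
#'
#' @param n_sires number of sires.
#' @param daughters_per_sire scalar, or vector of per-sire family sizes.
#' @param seed RNG seed (kept for interface symmetry; the layout is
#'   deterministic).
#' @return A `pedigree` with sires first.
#' @export
simulate_pedigree <- function(n_sires, daughters_per_sire, seed = 1L) {
  stopifnot(n_sires >= 1L, all(daughters_per_sire >= 1L))
  fam <- if (length(daughters_per_sire) == 1L) {
    rep(as.integer(daughters_per_sire), n_sires)
  } else {
    if (length(daughters_per_sire) != n_sires) {
      stop("daughters_per_sire must be scalar or length n_sires")
    }
    as.integer(daughters_per_sire)
  }
  sires <- sprintf("S%02d", seq_len(n_sires))
  d_id <- sprintf("D%04d", seq_len(sum(fam)))
  d_sire <- rep(sires, fam)
  as_pedigree(data.frame(
    id = c(sires, d_id),
    sire = c(rep(NA_character_, n_sires), d_sire),
    dam = NA_character_, stringsAsFactors = FALSE))
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders draw two haplotypes per block from the configured pool;
#' non-founders inherit one haplotype from each parent (a random one of the
#' parent's two), with unknown parents drawing from the pool. Blocks are
#' transmitted without internal recombination and independently of each
#' other. Genotype codes count copies of the minor allele determined from
#' the realised sample (ties toward alt).
#'
#' @param ped a `pedigree`.
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return list with `geno` (a `genotype_data`) and `phases` (per block, an
#'   n x 2 matrix of haplotype-pool indices).
#' @export
simulate_genotypes <- function(ped, config, seed = config$seed) {
  config <- validate_sim_config(unclass(config))
  n <- nrow(ped)
  s_idx <- match(ped$sire, ped$id)
  d_idx <- match(ped$dam, ped$id)
  phases <- vector("list", length(config$block_specs))
  set.seed(.substream(seed, 1L))
  for (bi in seq_along(config$block_specs)) {
    b <- config$block_specs[[bi]]
    nh <- length(b$haplotypes)
    hp <- matrix(0L, n, 2L)
    draw <- function(k) sample.int(nh, k, replace = TRUE, prob = b$freq)
    for (i in seq_len(n)) {
      for (side in 1:2) {
        p <- if (side == 1L) s_idx[i] else d_idx[i]
        hp[i, side] <- if (is.na(p)) draw(1L) else hp[p, sample.int(2L, 1L)]
      }
    }
    rownames(hp) <- ped$id
    phases[[bi]] <- hp
  }
  # alt-allele dosages in map order
  alt_dose <- matrix(NA_integer_, n, nrow(config$map),
                     dimnames = list(ped$id, config$map$snp_id))
  for (bi in seq_along(config$block_specs)) {
    b <- config$block_specs[[bi]]
    cols <- match(b$snp_ids, config$map$snp_id)
    for (w in seq_along(cols)) {
      al <- substr(b$haplotypes, w, w)
      is_alt <- as.integer(al == config$map$alt[cols[w]])
      alt_dose[, cols[w]] <- is_alt[phases[[bi]][, 1L]] +
        is_alt[phases[[bi]][, 2L]]
    }
  }
  list(geno = .finish_genotypes(alt_dose, config$map), phases = phases)
}

# polygenic gene-dropping: founder a ~ N(0, var_a); offspring
# a = (a_s + a_d)/2 + Mendelian sampling with variance var_a * (1 - k/4)
# per unknown parent replaced by 0 (parents non-inbred by construction)
.gene_drop_polygenic <- function(ped, var_a) {
  n <- nrow(ped)
  s_idx <- match(ped$sire, ped$id)
  d_idx <- match(ped$dam, ped$id)
  a <- numeric(n)
  for (i in seq_len(n)) {
    ks <- !is.na(s_idx[i]); kd <- !is.na(d_idx[i])
    par_mean <- 0.5 * ((if (ks) a[s_idx[i]] else 0) +
                       (if (kd) a[d_idx[i]] else 0))
    v_ms <- var_a * (1 - 0.25 * ks - 0.25 * kd)
    a[i] <- par_mean + stats::rnorm(1L, 0, sqrt(v_ms))
  }
  names(a) <- ped$id
  a
}

#' Simulate EBV phenotypes under the weighted animal model
#'
#' For each trait independently: y_i = mu + x_i alpha_true + a_i + e_i with
#' the polygenic value a gene-dropped down the pedigree and
#' e_i ~ N(0, var_e / REL_i), REL_i uniform on the configured range (drawn
#' once per individual and shared across traits). Phenotypes are generated
#' for daughters (non-founders); x is the alt-allele dosage of the causal
#' SNP, so alpha_true is the substitution effect of the alt allele.
#'
#' @param ped a `pedigree`.
#' @param sim_geno output of [simulate_genotypes()].
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return list with `phenotypes` (a `phenotype_table`) and `truth`
#'   (alpha_true, causal SNP, per-trait polygenic values, realised
#'   variance explained).
#' @export
simulate_ebv_phenotypes <- function(ped, sim_geno, config,
                                    seed = config$seed) {
  config <- validate_sim_config(unclass(config))
  geno <- sim_geno$geno
  cj <- match(config$causal_snp, geno$map$snp_id)
  if (is.na(cj)) stop("causal SNP not in map: ", config$causal_snp)
  # effect attaches to the alt allele; recover alt dosage from minor codes
  x <- geno$codes[, cj]
  if (geno$map$minor_allele[cj] != geno$map$alt[cj]) x <- 2L - x
  daughters <- ped$id[!is_founder(ped)]
  set.seed(.substream(seed, 2L))
  rel <- stats::runif(length(daughters), config$reliability_range[1],
                      config$reliability_range[2])
  names(rel) <- daughters
  a_mat <- matrix(0, nrow(ped), length(config$traits),
                  dimnames = list(ped$id, config$traits))
  rows <- list()
  for (t in seq_along(config$traits)) {
    set.seed(.substream(seed, 10L + t))
    a <- .gene_drop_polygenic(ped, config$var_a)
    a_mat[, t] <- a
    e <- stats::rnorm(length(daughters), 0,
                      sqrt(config$var_e / rel))
    y <- config$mu + x[daughters] * config$alpha_true + a[daughters] + e
    rows[[t]] <- data.frame(id = daughters, trait = config$traits[t],
                            ebv = y, reliability = unname(rel),
                            stringsAsFactors = FALSE)
  }
  pheno <- as_phenotype_table(do.call(rbind, rows), pedigree = ped)
  p_alt <- mean(x[daughters]) / 2
  truth <- list(alpha_true = config$alpha_true,
                causal_snp = config$causal_snp,
                polygenic = a_mat,
                reliability = rel,
                realized_var_explained =
                  2 * p_alt * (1 - p_alt) * config$alpha_true^2 / config$var_p)
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete daughter-design dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_ebv_phenotypes()].
#'
#' @param config a `sim_config` (default [default_sim_config()]).
#' @param seed RNG seed (default from config).
#' @return list with `ped`, `geno`, `phases`, `phenotypes`, `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config = default_sim_config(),
                             seed = config$seed) {
  ped <- simulate_pedigree(config$n_sires, config$daughters_per_sire, seed)
  sg <- simulate_genotypes(ped, config, seed)
  sp <- simulate_ebv_phenotypes(ped, sg, config, seed)
  list(ped = ped, geno = sg$geno, phases = sg$phases,
       phenotypes = sp$phenotypes, truth = sp$truth, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits pedigree.tsv, genotypes.tsv (allele-pair dialect), map.tsv,
#' phenotypes.tsv and truth.json, readable by the package's own readers.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped_out <- sim$ped
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  utils::write.table(ped_out, file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # reconstruct allele pairs from phases
  cfg <- sim$config
  n <- nrow(sim$ped)
  gstr <- matrix("", n, nrow(cfg$map), dimnames = list(sim$ped$id,
                                                       cfg$map$snp_id))
  for (bi in seq_along(cfg$block_specs)) {
    b <- cfg$block_specs[[bi]]
    cols <- match(b$snp_ids, cfg$map$snp_id)
    for (w in seq_along(cols)) {
      al <- substr(b$haplotypes, w, w)
      gstr[, cols[w]] <- paste0(al[sim$phases[[bi]][, 1L]],
                                al[sim$phases[[bi]][, 2L]])
    }
  }
  gt <- data.frame(id = sim$ped$id, gstr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cfg$map, file.path(dir, "map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$polygenic <- NULL   # bulky; keep the scalar summaries
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate genotype-group qPCR expression data
#'
#' Generates Ct-scale data whose 2^-ddCt group means match the requested
#' relative-expression means in expectation: per sample, a relative
#' quantity is drawn N(mean, sd) (redrawn if non-positive) and converted to
#' Ct_target = Ct_reference - log2(rq). Technical replicates are exact
#' copies unless `technical_sd > 0`.
#'
#' @param genotype_groups data frame with columns group, mean, sd, n.
#' @param seed RNG seed.
#' @param n_replicates technical replicates per sample.
#' @param technical_sd Ct-scale technical noise (default 0).
#' @param ct_reference baseline reference-gene Ct.
#' @return An `expression_table`.
#' @export
simulate_expression <- function(genotype_groups, seed = 1L,
                                n_replicates = 3L, technical_sd = 0,
                                ct_reference = 20) {
  gg <- as.data.frame(genotype_groups, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(gg)),
            all(gg$sd >= 0), all(gg$n >= 1))
  set.seed(.substream(seed, 3L))
  rows <- list()
  for (g in seq_len(nrow(gg))) {
    for (i in seq_len(gg$n[g])) {
      rq <- stats::rnorm(1L, gg$mean[g], gg$sd[g])
      tries <- 0L
      while (rq <= 0 && tries < 100L) {
        rq <- stats::rnorm(1L, gg$mean[g], gg$sd[g]); tries <- tries + 1L
      }
      if (rq <= 0) rq <- gg$mean[g] * 1e-3
      ct_t <- ct_reference - log2(rq)
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%02d", gg$group[g], i),
          group = gg$group[g],
          ct_target = ct_t + if (technical_sd > 0)
            stats::rnorm(1L, 0, technical_sd) else 0,
          ct_reference = ct_reference,
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  as_expression_table(do.call(rbind, rows))
}
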