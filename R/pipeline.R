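# End-to-end orchestration: SNP summary and HWE screen, single-SNP mixed
# model scan with Bonferroni over SNPs, EM phasing, LD + block detection,
# rare-haplotype pooling, block-level haplotype trend regression with
# Bonferroni over blocks, optional expression comparison. Deterministic
# given (inputs, config, seed).

#' Build a pipeline run configuration
#'
#' @param pedigree,genotypes,map,phenotypes input file paths.
#' @param variance_components named list per trait, each a list/vector with
#'   var_a, var_e, var_p.
#' @param traits traits to analyse (default: all traits present).
#' @param alpha family-wise significance level.
#' @param genotype_format "tabular" or "vcf".
#' @param expression optional Ct table path for the expression stage.
#' @param expression_groups optional length-2 character vector of genotype
#'   groups to compare.
#' @param block_thresholds Gabriel thresholds passed to [detect_blocks()].
#' @param em list of EM settings (n_restarts, max_iter, tol).
#' @param pool_threshold rare-haplotype pooling cutoff.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(pedigree, genotypes, map = NULL, phenotypes,
                       variance_components, traits = NULL, alpha = 0.05,
                       genotype_format = "tabular", expression = NULL,
                       expression_groups = NULL,
                       block_thresholds = list(strong_lower = 0.70,
                                               strong_upper = 0.98,
                                               recomb_upper = 0.90,
                                               min_frac = 0.95),
                       em = list(n_restarts = 5L, max_iter = 1000L,
                                 tol = 1e-8),
                       pool_threshold = 0.05, seed = 1L, out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  paths <- c(pedigree, genotypes, phenotypes,
             if (is.character(map)) map, expression)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(pedigree = pedigree, genotypes = genotypes, map = map,
                 phenotypes = phenotypes,
                 variance_components = variance_components, traits = traits,
                 alpha = alpha, genotype_format = genotype_format,
                 expression = expression,
                 expression_groups = expression_groups,
                 block_thresholds = block_thresholds, em = em,
                 pool_threshold = pool_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full candidate-gene analysis pipeline
#'
#' Executes SNP summary + HWE screen, the per-trait single-SNP scan, EM
#' phasing with LD-based block detection, pooling and per-trait block
#' tests, and (optionally) the expression comparison. When `out_dir` is
#' set, writes snp_summary.tsv, assoc_single_<trait>.tsv, ld_pairs.tsv,
#' blocks.tsv, assoc_blocks.tsv, summary.json and run_log.txt.
#'
#' @param config a `run_config`.
#' @return list with all stage outputs, invisibly when writing files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("expected `run_config`")
  ped <- .stage("read_pedigree", read_pedigree(config$pedigree))
  geno <- .stage("read_genotypes",
                 read_genotypes(config$genotypes, config$genotype_format,
                                map = config$map))
  pheno <- .stage("read_phenotypes",
                  read_phenotypes(config$phenotypes, pedigree = ped))
  traits <- config$traits
  if (is.null(traits)) traits <- sort(unique(pheno$trait))
  vcs <- config$variance_components
  for (tr in traits) {
    if (is.null(vcs[[tr]])) stop("no variance components for trait ", tr)
  }

  summary_tab <- .stage("snp_summary", snp_summary(geno))
  n_snps <- nrow(summary_tab)
  hwe_flagged <- summary_tab$snp_id[
    summary_tab$hwe_p < bonferroni_threshold(config$alpha, n_snps)]

  scans <- lapply(traits, function(tr) {
    v <- vcs[[tr]]
    .stage(paste0("single_snp_scan[", tr, "]"),
           single_snp_scan(geno, pheno, ped,
                           variance_components(v$var_a, v$var_e, v$var_p),
                           tr, alpha = config$alpha))
  })
  names(scans) <- traits

  ld <- .stage("ld_scan", ld_scan(geno))
  bt <- config$block_thresholds
  blocks <- .stage("detect_blocks",
                   detect_blocks(ld, geno$map,
                                 strong_lower = bt$strong_lower,
                                 strong_upper = bt$strong_upper,
                                 recomb_upper = bt$recomb_upper,
                                 min_frac = bt$min_frac))

  block_fits <- list()
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      idx <- blocks$start[b]:blocks$end[b]
      hs <- .stage(paste0("em_phasing[block", b, "]"),
                   em_haplotype_frequencies(
                     geno, idx, max_iter = config$em$max_iter,
                     tol = config$em$tol,
                     n_restarts = config$em$n_restarts,
                     seed = config$seed))
      pooled <- .stage(paste0("pooling[block", b, "]"),
                       pool_rare_haplotypes(hs, config$pool_threshold))
      design <- htr_design_matrix(pooled)
      per_trait <- lapply(traits, function(tr) {
        v <- vcs[[tr]]
        .stage(paste0("block_test[block", b, ",", tr, "]"),
               block_association_test(
                 design, pheno, ped,
                 variance_components(v$var_a, v$var_e, v$var_p), tr,
                 n_blocks = nrow(blocks), alpha = config$alpha,
                 block_id = paste0("block", b)))
      })
      names(per_trait) <- traits
      block_fits[[b]] <- list(haplotypes = pooled, tests = per_trait)
    }
  }

  expression <- NULL
  if (!is.null(config$expression)) {
    expr_tab <- .stage("read_expression", as_expression_table(
      utils::read.table(config$expression, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)))
    if (!is.null(config$expression_groups)) {
      expression <- .stage("expression_test", genotype_expression_test(
        expr_tab, config$expression_groups[1], config$expression_groups[2]))
    }
  }

  out <- list(ped = ped, geno = geno, phenotypes = pheno,
              snp_summary = summary_tab, hwe_flagged = hwe_flagged,
              scans = scans, ld = ld, blocks = blocks,
              block_fits = block_fits, expression = expression,
              config = config)

  if (!is.null(config$out_dir)) .write_pipeline_outputs(out)
  invisible(out)
}

.write_pipeline_outputs <- function(out) {
  dir <- out$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
    df
  }
  utils::write.table(fmt(out$snp_summary), file.path(dir, "snp_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in names(out$scans)) {
    write_results(out$scans[[tr]],
                  file.path(dir, paste0("assoc_single_", tr, ".tsv")))
  }
  utils::write.table(fmt(out$ld), file.path(dir, "ld_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$blocks, file.path(dir, "blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(out$block_fits)) {
    rows <- do.call(rbind, lapply(out$block_fits, function(bf) {
      do.call(rbind, lapply(bf$tests, function(x) x$result))
    }))
    write_results(rows, file.path(dir, "assoc_blocks.tsv"))
  }
  summary <- list(
    n_individuals = nrow(out$ped),
    n_snps = nrow(out$snp_summary),
    hwe_flagged = out$hwe_flagged,
    n_blocks = nrow(out$blocks),
    blocks = out$blocks[, c("start", "end")],
    significant_snps = lapply(out$scans, function(s) s$id[s$significant]),
    significant_blocks = if (length(out$block_fits)) {
      lapply(names(out$scans), function(tr) {
        unlist(lapply(out$block_fits, function(bf) {
          r <- bf$tests[[tr]]$result
          if (isTRUE(r$significant)) r$id else character(0)
        }))
      })
    } else list(),
    expression_fold_change = if (!is.null(out$expression))
      out$expression$fold_change else NULL,
    seed = out$config$seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("pedassoc ", as.character(utils::packageVersion("pedassoc"))),
    paste0("R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("seed: ", out$config$seed),
    vapply(names(out$scans), function(tr) {
      v <- out$config$variance_components[[tr]]
      sprintf("trait %s: lambda = var_e/var_a = %.6g", tr,
              v$var_e / v$var_a)
    }, character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
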