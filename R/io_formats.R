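# Readers and writers for the on-disk artifacts: pedigree, genotype matrix +
# SNP map (tabular or VCF), EBV phenotype table, association result tables.
# All readers validate their invariants and fail loudly.

.UNKNOWN_PARENT <- c("0", "", "NA", ".")
.MISSING_GENO <- c("--", "..", "", ".", "NA", "00")
.VALID_ALLELES <- c("A", "C", "G", "T")

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with character columns `id`, `sire`, `dam`
#' (NA for unknown parents), sorted so that parents precede their offspring.
#' Individuals referenced only as parents are inserted as founders.
#'
#' @param df data frame with columns id, sire, dam (character or coercible).
#' @return A `pedigree` data frame in topological order.
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("pedigree needs three columns: id, sire, dam")
  names(df)[1:3] <- c("id", "sire", "dam")
  for (col in c("id", "sire", "dam")) {
    df[[col]] <- trimws(as.character(df[[col]]))
    df[[col]][df[[col]] %in% .UNKNOWN_PARENT | is.na(df[[col]])] <- NA_character_
  }
  if (anyNA(df$id)) stop("pedigree contains a missing individual id")
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id in pedigree: ",
         df$id[duplicated(df$id)][1L])
  }
  # insert parent-only individuals as founders
  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(parents)) {
    df <- rbind(data.frame(id = parents, sire = NA_character_,
                           dam = NA_character_, stringsAsFactors = FALSE),
                df[, c("id", "sire", "dam")])
  }
  df <- df[, c("id", "sire", "dam")]
  # Kahn topological sort; cycle detection
  n <- nrow(df)
  placed <- logical(n)
  idx_of <- function(x) match(x, df$id)
  order_out <- integer(0)
  ready <- function() {
    ok <- !placed
    s <- idx_of(df$sire); d <- idx_of(df$dam)
    ok & (is.na(s) | placed[ifelse(is.na(s), 1L, s)]) &
      (is.na(d) | placed[ifelse(is.na(d), 1L, d)])
  }
  while (length(order_out) < n) {
    r <- which(ready())
    if (!length(r)) {
      bad <- df$id[!placed][1L]
      stop("pedigree cycle detected involving individual: ", bad)
    }
    placed[r] <- TRUE
    order_out <- c(order_out, r)
  }
  out <- df[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree file
#'
#' Accepts CSV/TSV/whitespace files with three columns (individual, sire,
#' dam); a header row is optional; unknown parents are coded "0" or empty.
#'
#' @param path path to the pedigree file.
#' @return A validated `pedigree` in topological order.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("pedigree file must have >= 3 columns")
  hdr <- tolower(trimws(as.character(raw[1L, ])))
  if (any(hdr %in% c("id", "individual", "individual_id", "animal"))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  as_pedigree(raw[, 1:3])
}

#' Founder indicator
#' @param ped a `pedigree`.
#' @return logical vector, TRUE where both parents are unknown.
#' @export
is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' Construct a genotype container
#'
#' Bundles a minor-allele dosage matrix with its SNP map. Codes count copies
#' of the minor allele (0/1/2, NA = missing).
#'
#' @param codes integer matrix, individuals x SNPs, rownames = ids.
#' @param map data frame with columns snp_id, chrom, pos, ref, alt,
#'   minor_allele.
#' @return A `genotype_data` object.
#' @export
genotype_data <- function(codes, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "minor_allele")
  if (!all(need %in% names(map))) {
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  }
  if (ncol(codes) != nrow(map)) stop("genotype matrix / SNP map size mismatch")
  if (is.null(rownames(codes))) stop("genotype matrix needs individual ids as rownames")
  bad <- codes[!is.na(codes) & !(codes %in% 0:2)]
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("SNP positions not strictly increasing on chromosome ", ch)
  }
  if (any(map$ref == map$alt)) stop("ref and alt alleles must differ")
  colnames(codes) <- map$snp_id
  structure(list(codes = codes, map = map), class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$codes), "individuals x", ncol(x$codes), "SNPs\n")
  invisible(x)
}

# alt-allele dosages + map (no minor yet) -> genotype_data with minor coding
.finish_genotypes <- function(alt_dose, map) {
  n2 <- 2 * colSums(!is.na(alt_dose))
  alt_freq <- colSums(alt_dose, na.rm = TRUE) / n2
  minor_is_alt <- alt_freq <= 0.5    # tie broken toward alt
  codes <- alt_dose
  flip <- which(!minor_is_alt)
  for (j in flip) codes[, j] <- 2L - codes[, j]
  map$minor_allele <- ifelse(minor_is_alt, map$alt, map$ref)
  genotype_data(codes, map)
}

.read_snp_map <- function(map) {
  if (is.character(map)) {
    sep <- .detect_sep(map)
    map <- utils::read.table(map, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map))) {
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  }
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$ref <- toupper(map$ref); map$alt <- toupper(map$alt)
  if (!all(c(map$ref, map$alt) %in% .VALID_ALLELES)) {
    stop("SNP map alleles must be A/C/G/T")
  }
  map
}

#' Read unphased biallelic SNP genotypes
#'
#' Two dialects: `tabular` (one row per individual; first column id; one
#' column per SNP holding an allele pair such as "TG", missing "--") with a
#' companion MAP-like file, and `vcf` (biallelic SNP records with a GT
#' field; other records are skipped with a warning). Codes count copies of
#' the minor allele, determined from the observed sample frequency with
#' ties broken toward the alt allele.
#'
#' @param path genotype file path.
#' @param format "tabular" or "vcf".
#' @param map SNP map path or data frame (required for tabular input).
#' @return A `genotype_data` object.
#' @export
read_genotypes <- function(path, format = c("tabular", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tabular") {
    if (is.null(map)) stop("tabular genotypes require a SNP map")
    map <- .read_snp_map(map)
    sep <- .detect_sep(path)
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE, check.names = FALSE)
    ids <- tab[[1L]]
    if (anyDuplicated(ids)) stop("duplicate individual id in genotype file")
    gcols <- names(tab)[-1L]
    if (!identical(gcols, map$snp_id)) {
      if (!setequal(gcols, map$snp_id)) stop("genotype columns do not match SNP map")
      tab <- tab[, c(names(tab)[1L], map$snp_id)]
    }
    alt_dose <- matrix(NA_integer_, nrow(tab), nrow(map),
                       dimnames = list(ids, map$snp_id))
    for (j in seq_len(nrow(map))) {
      g <- toupper(trimws(tab[[j + 1L]]))
      miss <- g %in% .MISSING_GENO
      gg <- g[!miss]
      if (any(nchar(gg) != 2L)) stop("malformed genotype at SNP ", map$snp_id[j])
      a1 <- substr(gg, 1L, 1L); a2 <- substr(gg, 2L, 2L)
      obs <- unique(c(a1, a2))
      if (!all(obs %in% .VALID_ALLELES)) {
        stop("allele not in A/C/G/T at SNP ", map$snp_id[j])
      }
      if (!all(obs %in% c(map$ref[j], map$alt[j]))) {
        stop("triallelic or unexpected allele at SNP ", map$snp_id[j])
      }
      d <- (a1 == map$alt[j]) + (a2 == map$alt[j])
      v <- rep(NA_integer_, length(g)); v[!miss] <- as.integer(d)
      alt_dose[, j] <- v
    }
    return(.finish_genotypes(alt_dose, map))
  }
  # VCF
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% .VALID_ALLELES & fix$ALT %in% .VALID_ALLELES
  if (any(!keep)) {
    warning(sum(!keep), " non-biallelic-SNP VCF record(s) skipped")
  }
  if (!any(keep)) stop("no usable biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  parse_gt <- function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1L]]
    if (any(al == "." ) || length(al) != 2L) return(NA_integer_)
    sum(al == "1")
  }
  alt_dose <- t(apply(gt, c(1L, 2L), parse_gt))
  snp_id <- fix$ID
  snp_id[is.na(snp_id) | snp_id == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(snp_id) | snp_id == "."]
  map <- data.frame(snp_id = snp_id, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  colnames(alt_dose) <- map$snp_id
  .finish_genotypes(alt_dose, map)
}

#' Read an EBV phenotype table
#'
#' Expects columns id, trait, ebv, reliability (one row per individual x
#' trait). Reliabilities must lie in (0, 1].
#'
#' @param path phenotype file path.
#' @param pedigree optional `pedigree` for id cross-checking.
#' @return A `phenotype_table` data frame.
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  as_phenotype_table(tab, pedigree = pedigree)
}

#' Validate a phenotype table
#' @param df data frame with columns id, trait, ebv, reliability.
#' @param pedigree optional `pedigree` for id cross-checking.
#' @return A `phenotype_table` data frame.
#' @export
as_phenotype_table <- function(df, pedigree = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "trait", "ebv", "reliability")
  if (!all(need %in% names(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df$id <- as.character(df$id); df$trait <- as.character(df$trait)
  df$ebv <- as.numeric(df$ebv); df$reliability <- as.numeric(df$reliability)
  if (any(!is.finite(df$ebv))) stop("non-finite EBV in phenotype table")
  if (any(!is.finite(df$reliability) | df$reliability <= 0 |
          df$reliability > 1)) {
    stop("reliability must lie in (0, 1]")
  }
  if (anyDuplicated(df[, c("id", "trait")])) {
    stop("duplicate (id, trait) row in phenotype table")
  }
  if (!is.null(pedigree)) {
    missing_ids <- setdiff(df$id, pedigree$id)
    if (length(missing_ids)) {
      stop("phenotyped individual(s) absent from pedigree: ",
           paste(utils::head(missing_ids, 3L), collapse = ", "))
    }
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

.RESULT_COLS <- c("id", "effect", "se", "wald_chisq", "df", "p_raw",
                  "p_threshold", "significant", "var_explained")

#' Write an association result table
#'
#' Tab-separated, full double precision, so that a read-back reproduces
#' every value.
#'
#' @param results data frame of association results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (!nrow(results)) stop("no results to write")
  miss <- setdiff(.RESULT_COLS, names(results))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  out <- results[, .RESULT_COLS]
  for (col in c("effect", "se", "wald_chisq", "p_raw", "p_threshold",
                "var_explained")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association result table written by `write_results`
#' @param path results file path.
#' @return data frame of association results.
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  tab$significant <- as.logical(tab$significant)
  tab
}
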