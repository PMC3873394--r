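# Relative quantification of qPCR data by the Livak 2^-ddCt method, and
# two-group comparisons of relative expression between genotype classes.

#' Validate a Ct expression table
#'
#' @param df data frame with columns sample_id, group, ct_target,
#'   ct_reference and optionally replicate.
#' @return An `expression_table` data frame.
#' @export
as_expression_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(df))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$ct_target <- as.numeric(df$ct_target)
  df$ct_reference <- as.numeric(df$ct_reference)
  if (any(!is.finite(df$ct_target)) || any(df$ct_target <= 0)) {
    stop("Ct values must be positive and finite")
  }
  if (any(!is.finite(df$ct_reference)) || any(df$ct_reference <= 0)) {
    stop("missing or invalid reference-gene Ct")
  }
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Relative quantification by 2^-ddCt
#'
#' Technical replicates are averaged on the Ct scale, then
#' dCt = Ct_target - Ct_reference per sample, ddCt = dCt - mean dCt of the
#' calibrator group, and RQ = 2^-ddCt. Because the calibrator is centred
#' on the Ct scale, its geometric mean RQ is exactly 1 (the arithmetic
#' mean coincides when the calibrator samples agree).
#'
#' @param expr an `expression_table` (or coercible data frame).
#' @param calibrator_group group label used as the calibrator.
#' @return list with `per_sample` (sample_id, group, dct, ddct, rq) and
#'   `per_group` (group, mean_rq, se_rq, n).
#' @export
relative_quantification <- function(expr, calibrator_group) {
  expr <- as_expression_table(expr)
  if (!calibrator_group %in% expr$group) {
    stop("calibrator group not present: ", calibrator_group)
  }
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ sample_id + group,
                          data = expr, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  cal_mean <- mean(agg$dct[agg$group == calibrator_group])
  agg$ddct <- agg$dct - cal_mean
  agg$rq <- 2^(-agg$ddct)
  per_group <- do.call(rbind, lapply(split(agg, agg$group), function(g) {
    data.frame(group = g$group[1L], mean_rq = mean(g$rq),
               geo_mean_rq = 2^(-mean(g$ddct)),
               se_rq = stats::sd(g$rq) / sqrt(nrow(g)), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_sample = agg[, c("sample_id", "group", "dct", "ddct", "rq")],
       per_group = per_group)
}

#' Two-group expression comparison
#'
#' Fold change of group A over group B on the relative-quantification
#' scale (group B is the calibrator, so its mean RQ is 1) and a two-sided
#' two-sample t-test on the per-sample RQ values (Welch by default).
#'
#' @param expr an `expression_table`.
#' @param group_a,group_b group labels to compare.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `fold_change`, `t_statistic`, `p`, `mean_a`, `mean_b`.
#' @export
genotype_expression_test <- function(expr, group_a, group_b,
                                     var_equal = FALSE) {
  rq <- relative_quantification(expr, calibrator_group = group_b)$per_sample
  ra <- rq$rq[rq$group == group_a]
  rb <- rq$rq[rq$group == group_b]
  if (!length(ra) || !length(rb)) stop("empty comparison group")
  if (mean(rb) == 0) stop("zero mean relative expression in denominator group")
  fold <- mean(ra) / mean(rb)
  tt <- if (length(ra) >= 2L && length(rb) >= 2L) {
    # degenerate (zero-variance) data yields NA rather than an error
    tryCatch(stats::t.test(ra, rb, var.equal = var_equal),
             error = function(e) NULL)
  } else NULL
  list(fold_change = fold,
       t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p = if (is.null(tt)) NA_real_ else tt$p.value,
       mean_a = mean(ra), mean_b = mean(rb),
       n_a = length(ra), n_b = length(rb))
}
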