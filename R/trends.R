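# Per-gene age trends in mean expression and in within-group variance, and
# the driver classification of predictability hits: is a change in
# predictability accompanied by a change in expression level, in expression
# variance, both, or neither.

#' Per-gene expression slope over age
#'
#' Ordinary least squares of per-sample expression on numeric age (the age
#' group average), per gene. Slopes are log2 units per year. Constant genes
#' get slope 0 and p 1.
#'
#' @param expr expression matrix in `residual` or `normalized_log` space.
#' @param meta sample metadata.
#' @param exclude_groups age-group labels to leave out (e.g. the oldest, for
#'   the consistency check).
#' @return data.frame: gene, slope, stderr, t_statistic, p_value.
#' @export
expression_slopes <- function(expr, meta, exclude_groups = character()) {
  assert_space(expr, c("residual", "normalized_log"))
  check_metadata(meta, expr)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  keep <- !meta$age_group %in% exclude_groups
  x <- meta$age_numeric[keep]
  if (length(unique(x)) < 3) stop("need at least 3 distinct ages")
  fits <- row_ols(expr[, keep, drop = FALSE], x)
  data.frame(gene = rownames(expr), slope = fits$slope, stderr = fits$stderr,
             t_statistic = fits$t_statistic, p_value = fits$p_value,
             stringsAsFactors = FALSE)
}

#' Per-gene variance slope over age
#'
#' Computes the sample variance (denominator n - 1) of each gene within
#' every age group with at least 3 samples, then fits OLS of the per-group
#' variances on the group ages. Slopes are variance units per year. Genes
#' need at least 3 usable groups.
#'
#' @inheritParams expression_slopes
#' @return data.frame: gene, slope, stderr, t_statistic, p_value, n_groups;
#'   attribute `group_variances` carries the gene x group variance matrix.
#' @export
variance_slopes <- function(expr, meta, exclude_groups = character()) {
  assert_space(expr, c("residual", "normalized_log"))
  check_metadata(meta, expr)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  meta <- meta[!meta$age_group %in% exclude_groups, , drop = FALSE]
  ag <- age_group_table(meta)
  sizes <- table(meta$age_group)[ag$age_group]
  ag <- ag[sizes[ag$age_group] >= 3, , drop = FALSE]
  if (nrow(ag) < 3) stop("need at least 3 age groups with >= 3 samples")
  V <- matrix(NA_real_, nrow(expr), nrow(ag),
              dimnames = list(rownames(expr), ag$age_group))
  for (g in ag$age_group) {
    ids <- meta$sample_id[meta$age_group == g]
    sub <- expr[, ids, drop = FALSE]
    V[, g] <- rowSums((sub - rowMeans(sub))^2) / (length(ids) - 1)
  }
  fits <- row_ols(V, ag$age_numeric)
  out <- data.frame(gene = rownames(expr), slope = fits$slope,
                    stderr = fits$stderr, t_statistic = fits$t_statistic,
                    p_value = fits$p_value, n_groups = fits$n_obs,
                    stringsAsFactors = FALSE)
  attr(out, "group_variances") <- V
  out
}

#' Classify predictability hits by their drivers
#'
#' A hit shows an "expression change" when the absolute expression slope
#' reaches `cutoff` (default 0.001 log2 units/year) and keeps its sign when
#' the oldest age group is excluded; "variance change" is defined
#' analogously on the variance slope. Hits missing a slope are classified
#' with `NA` flags and a warning.
#'
#' @param hits data.frame from [select_top_hits()] (columns `gene`,
#'   `direction`).
#' @param expr_slopes,var_slopes data.frames from [expression_slopes()] /
#'   [variance_slopes()] on all groups.
#' @param expr_slopes_wo,var_slopes_wo the same, fit without the oldest
#'   group.
#' @param cutoff absolute-slope cutoff (default 0.001).
#' @return data.frame: gene, direction, expression_slope, variance_slope,
#'   expression_change, variance_change; attribute `counts` tabulates flags
#'   per direction (the "Expression change" / "Variance change" / "Total"
#'   summary).
#' @export
classify_hits <- function(hits, expr_slopes, var_slopes,
                          expr_slopes_wo, var_slopes_wo, cutoff = 0.001) {
  flag <- function(gene, full, wo) {
    s <- full$slope[match(gene, full$gene)]
    sw <- wo$slope[match(gene, wo$gene)]
    ifelse(is.na(s) | is.na(sw), NA,
           abs(s) >= cutoff & sign(s) * sign(sw) > 0)
  }
  out <- data.frame(
    gene = hits$gene,
    direction = hits$direction,
    expression_slope = expr_slopes$slope[match(hits$gene, expr_slopes$gene)],
    variance_slope = var_slopes$slope[match(hits$gene, var_slopes$gene)],
    expression_change = flag(hits$gene, expr_slopes, expr_slopes_wo),
    variance_change = flag(hits$gene, var_slopes, var_slopes_wo),
    stringsAsFactors = FALSE
  )
  n_missing <- sum(is.na(out$expression_change) | is.na(out$variance_change))
  if (n_missing)
    warning(n_missing, " hit(s) missing a slope; flags set to NA")
  counts <- do.call(rbind, lapply(split(out, out$direction), function(d)
    data.frame(direction = d$direction[1],
               expression_change = sum(d$expression_change, na.rm = TRUE),
               variance_change = sum(d$variance_change, na.rm = TRUE),
               total = nrow(d))))
  rownames(counts) <- NULL
  attr(out, "counts") <- counts
  out
}
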