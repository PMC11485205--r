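# Per-age-group predictability, threshold calibration against the
# target-swapped network null, the Predictability ~ Age regression, the
# age-permutation null, and top-hit selection.

#' Per-age-group predictability table
#'
#' Computes the Spearman correlation between observed and reconstructed
#' expression separately within every age group (groups with fewer than 3
#' samples are dropped with a warning).
#'
#' @param observed expression matrix.
#' @param predicted reconstructed matrix.
#' @param meta sample metadata (`sample_id`, `age_group`, `age_numeric`).
#' @return list of class `predictability_table`: `rho` (gene x group
#'   matrix), `group_ages`, `group_sizes`.
#' @export
predictability_by_group <- function(observed, predicted, meta) {
  check_metadata(meta, observed)
  meta <- meta[meta$sample_id %in% colnames(observed), , drop = FALSE]
  ag <- age_group_table(meta)
  sizes <- table(meta$age_group)[ag$age_group]
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("age group(s) with < 3 samples dropped: ",
            paste(small, collapse = ", "))
    ag <- ag[!ag$age_group %in% small, , drop = FALSE]
  }
  genes <- intersect(rownames(observed), rownames(predicted))
  rho <- matrix(NA_real_, length(genes), nrow(ag),
                dimnames = list(genes, ag$age_group))
  for (g in ag$age_group) {
    ids <- meta$sample_id[meta$age_group == g]
    rho[, g] <- row_spearman(observed[genes, , drop = FALSE],
                             predicted[genes, , drop = FALSE], ids)[genes]
  }
  structure(list(rho = rho,
                 group_ages = setNames(ag$age_numeric, ag$age_group),
                 group_sizes = as.integer(sizes[ag$age_group])),
            class = "predictability_table")
}

#' Drop the oldest age group from a predictability table
#'
#' Used for the slope-sign consistency check of hit selection and driver
#' classification.
#'
#' @param table a `predictability_table`.
#' @return the table without its oldest group.
#' @export
drop_oldest_group <- function(table) {
  k <- length(table$group_ages)
  if (k < 2) stop("need at least 2 groups")
  structure(list(rho = table$rho[, -k, drop = FALSE],
                 group_ages = table$group_ages[-k],
                 group_sizes = table$group_sizes[-k]),
            class = "predictability_table")
}

#' Calibrate the predictability inclusion threshold
#'
#' Randomizes the model by degree-preserving target swaps (which destroys
#' the biology while keeping the topology), reconstructs expression over all
#' samples pooled, computes per-gene Spearman agreement, and returns the
#' upper quantile (default 95th percentile, linear interpolation between
#' order statistics) of that null distribution. Genes whose mean
#' predictability across age groups falls below the threshold are excluded
#' downstream.
#'
#' @param expr expression matrix.
#' @param model a [regulatory_model()] with >= 2 edges.
#' @param quantile upper quantile (default 0.95).
#' @param n_randomizations number of independent randomizations pooled
#'   (default 1).
#' @param seed integer seed.
#' @return the threshold (numeric); attribute `null_rho` carries the pooled
#'   null distribution.
#' @export
calibrate_predictability_threshold <- function(expr, model, quantile = 0.95,
                                               n_randomizations = 1,
                                               seed = 1) {
  pool <- numeric()
  for (r in seq_len(n_randomizations)) {
    rnd <- randomize_targets(model, seed = derive_seed(seed, paste0("cal", r)))
    rec <- reconstruct_expression(rnd, expr)
    pool <- c(pool, prediction_quality(expr, rec))
  }
  pool <- pool[is.finite(pool)]
  thr <- stats::quantile(pool, quantile, names = FALSE, type = 7)
  attr(thr, "null_rho") <- pool
  thr
}

#' Predictability ~ Age regression per gene
#'
#' Ordinary least squares of the per-group Spearman coefficients on the
#' group ages, with a two-sided t-test on the slope (df = n_groups - 2, no
#' multiple-testing correction). Genes with constant predictability get
#' slope 0 and p 1; genes with fewer than `min_groups` defined values are
#' skipped and reported.
#'
#' @param table a `predictability_table`.
#' @param min_groups minimum number of groups with a defined coefficient.
#' @return data.frame: gene, slope, stderr, t_statistic, p_value, n_groups;
#'   attribute `skipped` lists genes with too few groups.
#' @export
fit_predictability_slopes <- function(table, min_groups = 3) {
  stopifnot(inherits(table, "predictability_table"))
  if (min_groups < 3) stop("min_groups must be >= 3")
  fits <- row_ols(table$rho, table$group_ages)
  ok <- !is.na(fits$n_obs) & fits$n_obs >= min_groups & !is.na(fits$slope)
  out <- data.frame(gene = rownames(table$rho),
                    slope = fits$slope, stderr = fits$stderr,
                    t_statistic = fits$t_statistic, p_value = fits$p_value,
                    n_groups = fits$n_obs, stringsAsFactors = FALSE)
  skipped <- out$gene[!ok]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Age-permutation null for predictability slopes
#'
#' Repeatedly permutes the group-age vector used as the explanatory
#' variable (group labels, not individual samples), refits all slopes, and
#' collects the null p-values. The summary compares the real p-value
#' distribution with the permutation average over a grid of cutoffs.
#'
#' @param table a `predictability_table` with >= 3 groups.
#' @param n_perm number of permutations (default 100; permutations are
#'   drawn with replacement, duplicates allowed).
#' @param seed integer seed.
#' @param cutoffs p-value grid for the enrichment summary.
#' @return list: `p_real` (named), `p_null` (genes x n_perm matrix),
#'   `summary` (data.frame: cutoff, real_fraction, null_fraction),
#'   `n_perm`, `seed`.
#' @export
permutation_null <- function(table, n_perm = 100, seed = 1,
                             cutoffs = c(0.001, 0.005, 0.01, 0.05, 0.1)) {
  stopifnot(inherits(table, "predictability_table"))
  if (length(table$group_ages) < 3) stop("need at least 3 groups")
  real <- fit_predictability_slopes(table)
  p_real <- setNames(real$p_value, real$gene)
  set.seed(derive_seed(seed, "permutation_null"))
  p_null <- matrix(NA_real_, nrow(table$rho), n_perm,
                   dimnames = list(rownames(table$rho), NULL))
  for (b in seq_len(n_perm)) {
    ages_p <- sample(table$group_ages)
    p_null[, b] <- row_ols(table$rho, ages_p)$p_value
  }
  summary <- data.frame(
    cutoff = cutoffs,
    real_fraction = vapply(cutoffs, function(cc)
      mean(p_real < cc, na.rm = TRUE), numeric(1)),
    null_fraction = vapply(cutoffs, function(cc)
      mean(p_null < cc, na.rm = TRUE), numeric(1))
  )
  list(p_real = p_real, p_null = p_null, summary = summary,
       n_perm = n_perm, seed = seed)
}

#' Select the top predictability hits
#'
#' Ranks genes by ascending regression p-value (ties by descending absolute
#' slope, then gene id) and returns the top `n_top` (default 100) -
#' the "high-confidence" hits. With `require_consistency`, genes whose slope
#' sign flips when the oldest age group is excluded are dropped before
#' ranking.
#'
#' @param trends data.frame from [fit_predictability_slopes()].
#' @param n_top number of hits (default 100).
#' @param trends_without_oldest optional matching trends fit without the
#'   oldest group; required when `require_consistency` is `TRUE`.
#' @param require_consistency drop sign-flipping genes (default `TRUE` when
#'   `trends_without_oldest` is given).
#' @return data.frame of hits with columns of `trends` plus `rank` and
#'   `direction` (`"increase"`/`"decrease"`).
#' @export
select_top_hits <- function(trends, n_top = 100,
                            trends_without_oldest = NULL,
                            require_consistency = !is.null(trends_without_oldest)) {
  if (!nrow(trends)) stop("empty trend table")
  out <- trends
  if (require_consistency) {
    if (is.null(trends_without_oldest))
      stop("consistency filtering needs `trends_without_oldest`")
    swo <- trends_without_oldest$slope[
      match(out$gene, trends_without_oldest$gene)]
    consistent <- !is.na(swo) & sign(out$slope) * sign(swo) > 0
    out$consistent_without_oldest <- consistent
    out <- out[consistent, , drop = FALSE]
  }
  ord <- order(out$p_value, -abs(out$slope), out$gene)
  out <- out[ord, , drop = FALSE]
  if (n_top > nrow(out))
    warning("n_top (", n_top, ") exceeds available genes (", nrow(out), ")")
  out <- head(out, n_top)
  out$rank <- seq_len(nrow(out))
  out$direction <- ifelse(out$slope >= 0, "increase", "decrease")
  rownames(out) <- NULL
  out
}
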