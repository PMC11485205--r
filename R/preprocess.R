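# Bulk-count preprocessing: biotype/abundance gene filtering,
# median-of-ratios size-factor normalisation with log2 transform, covariate
# residualisation, and balanced age-group subsampling.

#' Filter genes by mean count and biotype
#'
#' Keeps genes whose mean raw count across all samples is at least
#' `min_mean_count` (the boundary is kept: only strictly lower means are
#' excluded) and, when an annotation is supplied, whose biotype is in
#' `allowed_biotypes`. Gene order is preserved.
#'
#' @param counts expression matrix in counts space.
#' @param annotation optional data.frame with columns `gene_id`, `biotype`.
#' @param min_mean_count minimum mean count (default 100).
#' @param allowed_biotypes character vector of biotypes to keep (`NULL`
#'   disables the biotype filter).
#' @return the filtered counts matrix.
#' @export
filter_genes <- function(counts, annotation = NULL, min_mean_count = 100,
                         allowed_biotypes = NULL) {
  assert_space(counts, "counts")
  if (min_mean_count < 0) stop("min_mean_count must be >= 0")
  keep_count <- rowMeans(counts) >= min_mean_count
  keep_bio <- rep(TRUE, nrow(counts))
  if (!is.null(annotation) && !is.null(allowed_biotypes)) {
    bio <- annotation$biotype[match(rownames(counts), annotation$gene_id)]
    keep_bio <- !is.na(bio) & bio %in% allowed_biotypes
  }
  keep <- keep_count & keep_bio
  if (!any(keep))
    stop("no genes survive filtering (", sum(keep_count),
         " pass the count filter, ", sum(keep_bio), " the biotype filter)")
  out <- counts[keep, , drop = FALSE]
  expression_matrix(out, "counts")
}

#' Median-of-ratios normalisation and log2 transform
#'
#' Size factors are the per-sample median ratio to a per-gene
#' geometric-mean reference, computed over genes with all-positive counts
#' (the standard median-of-ratios estimator, delegated to DESeq2). The
#' output is `log2(count / factor + 1)`.
#'
#' @param counts expression matrix in counts space with >= 2 samples.
#' @return expression matrix in `normalized_log` space; attribute
#'   `size_factors` carries the per-sample factors.
#' @export
normalize_and_log <- function(counts) {
  assert_space(counts, "counts")
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (!any(rowSums(counts > 0) == ncol(counts)))
    stop("no gene with all-positive counts; size factors are undefined")
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  out <- log2(t(t(counts) / sf) + 1)
  out <- expression_matrix(out, "normalized_log")
  attr(out, "size_factors") <- sf
  out
}

#' Regress covariates out of normalised expression
#'
#' Per gene, fits an ordinary-least-squares model of expression on an
#' intercept plus the named covariates (categoricals one-hot coded with a
#' dropped reference level) and returns the residuals - the batch-corrected
#' matrix used by all downstream stages.
#'
#' @param expr expression matrix in `normalized_log` space.
#' @param meta sample metadata containing the covariate columns.
#' @param covariate_names columns of `meta` to regress out.
#' @return expression matrix in `residual` space.
#' @export
regress_out_covariates <- function(expr, meta, covariate_names) {
  assert_space(expr, c("normalized_log"))
  check_metadata(meta, expr)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  missing <- setdiff(covariate_names, names(meta))
  if (length(missing))
    stop("covariates absent from metadata: ", paste(missing, collapse = ", "))
  covs <- meta[, covariate_names, drop = FALSE]
  if (any(!complete.cases(covs)))
    stop("covariate value missing for samples: ",
         paste(head(meta$sample_id[!complete.cases(covs)], 5), collapse = ", "))
  covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
  X <- stats::model.matrix(~ ., data = covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, t(expr))
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(expr)
  expression_matrix(res, "residual")
}

#' Balance age-group sizes by random subsampling
#'
#' Downsamples every age group to a common size: either `n_fixed`, or the
#' size of the smallest group computed excluding the groups named in
#' `exclude_from_min` (typically the oldest). An excluded group is retained
#' (at its own size if smaller than the target) only if it has at least
#' `min_keep_oldest` samples, and is never upsampled.
#'
#' @param meta sample metadata.
#' @param exclude_from_min age-group labels excluded from the minimum-size
#'   computation.
#' @param min_keep_oldest minimum size for an excluded group to be retained
#'   (default 10).
#' @param n_fixed optional fixed per-group size (overrides the minimum rule).
#' @param seed integer seed for the random draws.
#' @return character vector of retained sample ids.
#' @export
balance_age_groups <- function(meta, exclude_from_min = character(),
                               min_keep_oldest = 10, n_fixed = NULL,
                               seed = 1) {
  check_metadata(meta)
  sizes <- table(meta$age_group)
  if (length(sizes) < 2) stop("need at least 2 age groups")
  core <- setdiff(names(sizes), exclude_from_min)
  target <- if (!is.null(n_fixed)) n_fixed else min(sizes[core])
  if (any(sizes[core] < target))
    stop("n_fixed (", target, ") exceeds the size of group(s): ",
         paste(core[sizes[core] < target], collapse = ", "))
  set.seed(derive_seed(seed, "balance"))
  keep <- character()
  ord_groups <- age_group_table(meta)$age_group
  for (g in ord_groups) {
    ids <- meta$sample_id[meta$age_group == g]
    if (g %in% exclude_from_min) {
      if (length(ids) < min_keep_oldest) next      # group dropped entirely
      n_take <- min(length(ids), target)
    } else n_take <- target
    keep <- c(keep, sample(ids, n_take))
  }
  keep
}
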