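# Expression reconstruction from regulatory neighbours and observed-vs-
# predicted agreement. The model is frozen external knowledge: weights are
# never re-estimated on the evaluation data.

#' Reconstruct expression from regulatory neighbours
#'
#' Per target t, the prediction is `sum_p w_pt * (x_p - mean(x_p))`, the
#' weighted sum of the predictors' expression centered over the provided
#' sample set (so reconstruction within a tissue is centered within that
#' tissue). Predictors absent from the matrix are dropped from the sum;
#' targets with no present predictor are excluded and listed.
#'
#' @param model a [regulatory_model()].
#' @param expr expression matrix in `normalized_log` or `residual` space.
#' @return genes x samples matrix of reconstructed (centered-scale) values
#'   for the covered targets; attributes `excluded` (targets with no present
#'   predictor) and `coverage` (per-target fraction of predictors present).
#' @export
reconstruct_expression <- function(model, expr) {
  assert_space(expr, c("normalized_log", "residual"))
  present <- model$predictor %in% rownames(expr)
  targets_all <- unique(model$target)
  usable <- model[present, , drop = FALSE]
  covered <- unique(usable$target)
  excluded <- setdiff(targets_all, covered)
  centered <- expr - rowMeans(expr)
  pred_idx <- match(usable$predictor, rownames(centered))
  tgt_idx <- match(usable$target, covered)
  recon <- matrix(0, length(covered), ncol(expr),
                  dimnames = list(covered, colnames(expr)))
  for (i in seq_len(nrow(usable)))
    recon[tgt_idx[i], ] <- recon[tgt_idx[i], ] +
      usable$weight[i] * centered[pred_idx[i], ]
  n_pred <- table(model$target)
  n_used <- table(usable$target)
  coverage <- setNames(rep(0, length(targets_all)), targets_all)
  coverage[names(n_used)] <- as.numeric(n_used) /
    as.numeric(n_pred[names(n_used)])
  attr(recon, "excluded") <- excluded
  attr(recon, "coverage") <- coverage
  recon
}

#' Observed-versus-predicted agreement (predictability)
#'
#' Spearman rank correlation (average ranks for ties) between observed and
#' reconstructed expression, per gene, over a sample subset. Genes with zero
#' variance in either vector get `NA`.
#'
#' @param observed expression matrix.
#' @param predicted reconstructed matrix (from
#'   [reconstruct_expression()]).
#' @param sample_subset sample ids to use (default: all shared samples);
#'   must contain at least 3 samples.
#' @return named numeric vector of Spearman coefficients for the genes
#'   present in both matrices.
#' @export
prediction_quality <- function(observed, predicted, sample_subset = NULL) {
  if (is.null(sample_subset))
    sample_subset <- intersect(colnames(observed), colnames(predicted))
  if (length(sample_subset) < 3)
    stop("need at least 3 samples to compute predictability")
  row_spearman(observed, predicted, sample_subset)
}

#' Poorly predicted genes
#'
#' Genes whose average predictability across contexts (e.g. tissues) falls
#' below a threshold (default 0.2) are flagged as poorly predicted; the set
#' is monotone in the threshold.
#'
#' @param rho_list list of per-context named Spearman vectors, or a single
#'   named vector.
#' @param threshold mean-correlation threshold (default 0.2).
#' @return character vector of poorly predicted genes.
#' @export
poorly_predicted_genes <- function(rho_list, threshold = 0.2) {
  if (!is.list(rho_list)) rho_list <- list(rho_list)
  genes <- unique(unlist(lapply(rho_list, names)))
  m <- vapply(rho_list, function(r) r[genes], numeric(length(genes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(genes))
  avg <- rowMeans(m, na.rm = TRUE)
  genes[!is.nan(avg) & avg < threshold]
}
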