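# Internal helpers shared across modules.

#' Construct an expression matrix
#'
#' A thin wrapper around a base numeric matrix (genes in rows, samples in
#' columns) that records which space the values live in: raw `"counts"`,
#' size-factor normalised log2 values (`"normalized_log"`), or covariate
#' residuals (`"residual"`).
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param space one of `"counts"`, `"normalized_log"`, `"residual"`.
#' @return the matrix with a `space` attribute.
#' @export
expression_matrix <- function(values,
                              space = c("counts", "normalized_log", "residual")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (space == "counts") {
    if (any(values < 0)) stop("counts space requires non-negative values")
  } else if (any(!is.finite(values))) {
    stop("non-finite values in ", space, " space")
  }
  attr(values, "space") <- space
  values
}

#' @rdname expression_matrix
#' @param x an expression matrix.
#' @export
expr_space <- function(x) {
  sp <- attr(x, "space")
  if (is.null(sp)) "normalized_log" else sp
}

`expr_space<-` <- function(x, value) {
  attr(x, "space") <- value
  x
}

assert_space <- function(x, allowed) {
  sp <- expr_space(x)
  if (!sp %in% allowed)
    stop("expression matrix must be in space ", paste(allowed, collapse = "/"),
         ", got ", sp)
  invisible(sp)
}

#' Construct a regulatory model
#'
#' A sparse directed weighted gene-gene graph stored as an edge table with
#' columns `predictor`, `target`, `weight`. Weights are the coefficients of
#' the per-target linear model and are used verbatim for reconstruction.
#'
#' @param edges data.frame with columns predictor, target, weight.
#' @return a `data.frame` of class `regulatory_model`.
#' @export
regulatory_model <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("predictor", "target", "weight")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  edges <- edges[, need]
  edges$predictor <- as.character(edges$predictor)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$predictor == edges$target)) stop("self-edges are not allowed")
  if (anyDuplicated(paste0(edges$predictor, "\r", edges$target)))
    stop("duplicate (predictor, target) pairs")
  if (any(!is.finite(edges$weight)) || any(edges$weight == 0))
    stop("weights must be finite and nonzero")
  rownames(edges) <- NULL
  class(edges) <- c("regulatory_model", "data.frame")
  edges
}

model_genes <- function(model) sort(unique(c(model$predictor, model$target)))

edge_key <- function(predictor, target) paste0(predictor, "\r", target)

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw from independent streams so that any stage can
#' be rerun in isolation; the per-stage seed is a deterministic hash of the
#' global seed and the stage name, kept within 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# Row-wise OLS of y (rows of Y) on a single covariate x.
# Returns slope, stderr, t, p (two-sided, df = n-2). Constant rows get
# slope 0 / p 1; an exact non-constant fit gets p = 0. NA cells are dropped
# pairwise per row.
row_ols <- function(Y, x) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  n_gene <- nrow(Y)
  out <- data.frame(slope = rep(NA_real_, n_gene),
                    stderr = rep(NA_real_, n_gene),
                    t_statistic = rep(NA_real_, n_gene),
                    p_value = rep(NA_real_, n_gene),
                    n_obs = rep(NA_integer_, n_gene))
  rownames(out) <- rownames(Y)
  for (i in seq_len(n_gene)) {
    y <- Y[i, ]
    ok <- is.finite(y) & is.finite(x)
    yi <- y[ok]; xi <- x[ok]
    n <- length(yi)
    out$n_obs[i] <- n
    if (n < 3) next
    sxx <- sum((xi - mean(xi))^2)
    if (sxx == 0) next
    if (max(yi) - min(yi) == 0) {      # constant response: flat line, no test
      out[i, c("slope", "stderr", "t_statistic", "p_value")] <-
        c(0, 0, 0, 1)
      next
    }
    b <- sum((xi - mean(xi)) * yi) / sxx
    res <- yi - mean(yi) - b * (xi - mean(xi))
    rss <- sum(res^2)
    se <- sqrt(rss / (n - 2) / sxx)
    tt <- if (se == 0) sign(b) * Inf else b / se
    out$slope[i] <- b
    out$stderr[i] <- se
    out$t_statistic[i] <- tt
    out$p_value[i] <- if (is.infinite(tt)) 0 else 2 * pt(-abs(tt), df = n - 2)
  }
  out
}

# Spearman correlation columns of two matrices share: per-gene rho between
# matching rows over the given samples. Zero-variance rows give NA.
row_spearman <- function(obs, pred, samples = NULL) {
  if (is.null(samples)) samples <- colnames(obs)
  genes <- intersect(rownames(obs), rownames(pred))
  rho <- setNames(rep(NA_real_, length(genes)), genes)
  o <- obs[genes, samples, drop = FALSE]
  p <- pred[genes, samples, drop = FALSE]
  for (g in genes) {
    if (sd(o[g, ]) == 0 || sd(p[g, ]) == 0) next
    rho[g] <- cor(o[g, ], p[g, ], method = "spearman")
  }
  rho
}

check_metadata <- function(meta, expr = NULL) {
  need <- c("sample_id", "age_group", "age_numeric")
  if (!all(need %in% names(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(expr)) {
    missing <- setdiff(colnames(expr), meta$sample_id)
    if (length(missing))
      stop("samples without metadata: ", paste(head(missing, 5), collapse = ", "))
  }
  ag <- unique(meta[, c("age_group", "age_numeric")])
  if (anyDuplicated(ag$age_group))
    stop("age_numeric must be constant within an age_group")
  invisible(meta)
}

# Ordered (by numeric age) age groups present in metadata.
age_group_table <- function(meta) {
  ag <- unique(meta[, c("age_group", "age_numeric")])
  ag <- ag[order(ag$age_numeric), ]
  ag$age_group <- as.character(ag$age_group)
  rownames(ag) <- NULL
  ag
}
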