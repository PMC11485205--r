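# Sparse regulatory-model training: per target gene, stable predictors are
# selected by subsampled L1-regularised regression, then final linear
# weights are fit by OLS on centered data. The per-subsample regularisation
# level is the smallest value of a fixed grid that keeps at most
# `max_predictors_per_fit` coefficients nonzero, which bounds model
# complexity per fit while letting stable predictors accumulate frequency.

#' Stability-selection configuration
#'
#' @param n_subsamples number of random sample subsets (default 100).
#' @param subsample_fraction fraction of samples per subset, in (0, 1).
#' @param selection_threshold minimum selection frequency for a predictor to
#'   enter the model, in (0, 1\].
#' @param lambda_grid decreasing positive lambda grid, or `NULL` for an
#'   automatic 50-point log grid from the data.
#' @param max_predictors optional cap on predictors per target (by frequency,
#'   ties by absolute marginal correlation).
#' @param max_predictors_per_fit cap on nonzero coefficients per subsample
#'   fit, used to pick the per-subsample lambda (default 20).
#' @param n_candidates size of the marginal-correlation candidate pre-filter.
#' @param prefilter_above apply the pre-filter only when the number of genes
#'   exceeds this (default 1000).
#' @param seed integer seed.
#' @return a list of class `stability_config`.
#' @export
stability_config <- function(n_subsamples = 100, subsample_fraction = 0.5,
                             selection_threshold = 0.6, lambda_grid = NULL,
                             max_predictors = NULL,
                             max_predictors_per_fit = 20,
                             n_candidates = 500, prefilter_above = 1000,
                             seed = 1) {
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("subsample_fraction must be in (0, 1)")
  if (selection_threshold <= 0 || selection_threshold > 1)
    stop("selection_threshold must be in (0, 1]")
  if (!is.null(lambda_grid) && any(lambda_grid <= 0))
    stop("lambda_grid must be positive")
  structure(list(n_subsamples = n_subsamples,
                 subsample_fraction = subsample_fraction,
                 selection_threshold = selection_threshold,
                 lambda_grid = lambda_grid,
                 max_predictors = max_predictors,
                 max_predictors_per_fit = max_predictors_per_fit,
                 n_candidates = n_candidates,
                 prefilter_above = prefilter_above,
                 seed = seed),
            class = "stability_config")
}

# Lambda grid on z-scored data: from the smallest lambda that zeroes every
# coefficient down to a noise floor, 50 log-spaced points. The floor is the
# universal threshold sqrt(2 log(p) / m) at the subsample size m - the
# scale of the largest spurious correlation among p independent candidates -
# so the path never descends into the regime where pure-noise predictors
# enter the active set (without it, targets with few candidates would
# select everything at the bottom of the path).
auto_lambda_grid <- function(X, y, m, length.out = 50) {
  lmax <- max(abs(crossprod(X, y)) / length(y))
  p <- ncol(X)
  # p floored at 4 so fits with one or two candidates keep a non-degenerate
  # null scale (a persistent chance correlation of order 1/sqrt(n) would
  # otherwise be selected in every subsample)
  floor_l <- sqrt(2 * log(max(p, 4)) / m)
  lmin <- max(0.01 * lmax, floor_l)
  lmax <- max(lmax, lmin)     # lmax below the floor: nothing is selectable
  exp(seq(log(lmax), log(lmin), length.out = length.out))
}

# Nonzero pattern of the lasso path for one subsample: a p x L logical
# matrix. Uses glmnet for p >= 2 and the closed-form univariate
# soft-threshold solution for p = 1.
lasso_path_nonzero <- function(X, y, grid) {
  if (ncol(X) >= 2) {
    fit <- glmnet::glmnet(X, y, lambda = grid, standardize = FALSE,
                          intercept = TRUE)
    as.matrix(fit$beta != 0)
  } else {
    xc <- X[, 1] - mean(X[, 1])
    yc <- y - mean(y)
    n <- length(y)
    cxy <- sum(xc * yc) / n
    matrix(abs(cxy) > grid, nrow = 1,
           dimnames = list(colnames(X), NULL))
  }
}

#' Stability-selection frequencies for one target gene
#'
#' Genes are z-scored across samples; for each of `n_subsamples` random
#' subsets of size `floor(fraction * n)`, an L1-regularised regression of
#' the target on the candidates is fit over a fixed lambda grid and the
#' per-subsample lambda is the smallest grid value with at most
#' `max_predictors_per_fit` nonzero coefficients. The selection frequency of
#' a candidate is the fraction of subsamples in which its coefficient is
#' nonzero.
#'
#' @param target target gene id.
#' @param candidates candidate predictor gene ids (must not contain the
#'   target).
#' @param expr expression matrix in `normalized_log` or `residual` space.
#' @param config a [stability_config()].
#' @return named numeric vector of selection frequencies in \[0, 1\].
#' @export
select_stable_predictors <- function(target, candidates, expr, config) {
  assert_space(expr, c("normalized_log", "residual"))
  stopifnot(inherits(config, "stability_config"))
  if (target %in% candidates) stop("target must not be among candidates")
  n <- ncol(expr)
  if (n < 10) stop("need at least 10 samples for stability selection")
  y <- expr[target, ]
  if (sd(y) == 0) {
    warning("constant target '", target, "': no selection possible")
    return(setNames(numeric(0), character(0)))
  }
  sds <- apply(expr[candidates, , drop = FALSE], 1, sd)
  cand <- candidates[sds > 0]               # constant candidates can't be selected
  Z <- expr[c(target, cand), , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1, sd)
  X <- t(Z[cand, , drop = FALSE])
  yz <- Z[target, ]
  m <- floor(config$subsample_fraction * n)
  grid <- config$lambda_grid
  if (is.null(grid)) grid <- auto_lambda_grid(X, yz, m)
  grid <- sort(grid, decreasing = TRUE)
  counts <- setNames(numeric(length(cand)), cand)
  set.seed(config$seed)
  for (b in seq_len(config$n_subsamples)) {
    idx <- sample.int(n, m)
    nz <- lasso_path_nonzero(X[idx, , drop = FALSE], yz[idx], grid)
    df <- colSums(nz)
    ok <- which(df <= config$max_predictors_per_fit)
    pick <- if (length(ok)) max(ok) else which.min(df)  # smallest admissible lambda
    counts <- counts + nz[, pick]
  }
  freq <- counts / config$n_subsamples
  out <- setNames(rep(0, length(candidates)), candidates)
  out[names(freq)] <- freq
  out
}

#' Final linear weights for a target given its stable predictors
#'
#' Ordinary least squares of the centered target on the centered selected
#' predictors (no intercept after centering). Collinear predictor sets fall
#' back to a ridge solve with penalty 1e-8 and a warning.
#'
#' @param target target gene id.
#' @param selected nonempty character vector of predictor gene ids.
#' @param expr expression matrix in `normalized_log` or `residual` space.
#' @return named numeric vector of weights (expression units).
#' @export
fit_target_weights <- function(target, selected, expr) {
  assert_space(expr, c("normalized_log", "residual"))
  if (!length(selected)) stop("`selected` must be nonempty")
  if (length(selected) >= ncol(expr))
    stop("more predictors than samples")
  yc <- expr[target, ] - mean(expr[target, ])
  Xc <- t(expr[selected, , drop = FALSE] -
            rowMeans(expr[selected, , drop = FALSE]))
  XtX <- crossprod(Xc)
  if (qr(XtX)$rank < ncol(XtX)) {
    warning("collinear predictors for '", target,
            "'; ridge fallback with penalty 1e-8")
    XtX <- XtX + diag(1e-8, ncol(XtX))
  }
  drop(solve(XtX, crossprod(Xc, yc)))
}

#' Train the sparse regulatory model
#'
#' Runs stability selection for every gene as target (candidates are all
#' other genes, optionally pre-filtered to the `n_candidates` strongest
#' marginal correlations when the gene universe is large), keeps candidates
#' whose selection frequency reaches `selection_threshold`, and fits final
#' OLS weights. Targets with no stable predictor are absent from the model;
#' per-target errors are collected, not fatal.
#'
#' @param expr expression matrix (>= 2 genes) in `normalized_log` or
#'   `residual` space.
#' @param config a [stability_config()].
#' @return a [regulatory_model()]; attributes `config` (training
#'   configuration) and `errors` (named list of per-target failures).
#' @export
train_network <- function(expr, config = stability_config()) {
  assert_space(expr, c("normalized_log", "residual"))
  genes <- rownames(expr)
  if (length(genes) < 2) stop("need at least 2 genes")
  edges <- list()
  errors <- list()
  prefilter <- length(genes) > config$prefilter_above
  for (target in genes) {
    res <- tryCatch({
      candidates <- setdiff(genes, target)
      mcor <- NULL
      if (prefilter) {
        mcor <- abs(drop(cor(t(expr[candidates, , drop = FALSE]),
                             expr[target, ])))
        names(mcor) <- candidates
        candidates <- names(sort(mcor, decreasing = TRUE))[
          seq_len(min(config$n_candidates, length(candidates)))]
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("target:", target))
      freq <- select_stable_predictors(target, candidates, expr, cfg)
      sel <- names(freq)[freq >= config$selection_threshold]
      if (length(sel) && !is.null(config$max_predictors) &&
          length(sel) > config$max_predictors) {
        if (is.null(mcor))
          mcor <- setNames(abs(drop(cor(t(expr[sel, , drop = FALSE]),
                                        expr[target, ]))), sel)
        ord <- order(-freq[sel], -mcor[sel], sel)
        sel <- sel[ord][seq_len(config$max_predictors)]
      }
      if (!length(sel)) return2 <- NULL
      else {
        w <- fit_target_weights(target, sel, expr)
        return2 <- data.frame(predictor = sel, target = target,
                              weight = unname(w),
                              stringsAsFactors = FALSE)
      }
      return2
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[target]] <- conditionMessage(res)
    else if (!is.null(res)) edges[[target]] <- res
  }
  if (!length(edges))
    model <- regulatory_model(data.frame(predictor = character(),
                                         target = character(),
                                         weight = numeric()))
  else
    model <- regulatory_model(do.call(rbind, edges))
  attr(model, "config") <- config
  attr(model, "errors") <- errors
  model
}
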