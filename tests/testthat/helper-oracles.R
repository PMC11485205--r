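# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive loops / closed forms and
# never call the code paths they check.

# Spearman: rank (average ties) then textbook Pearson.
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Median-of-ratios size factors, written out explicitly: per-gene
# geometric-mean reference over genes positive in all samples, then the
# per-sample median log-ratio (the median taken in log space, where an
# even-count median averages geometrically).
bf_size_factors <- function(counts) {
  pos <- apply(counts > 0, 1, all)
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  apply(counts[pos, , drop = FALSE], 2,
        function(cc) exp(median(log(cc / ref))))
}

# Simple-regression slope/t/p via stats::lm (independent of row_ols).
bf_ols <- function(y, x) {
  fit <- summary(lm(y ~ x))$coefficients
  list(slope = fit["x", "Estimate"], stderr = fit["x", "Std. Error"],
       t = fit["x", "t value"], p = fit["x", "Pr(>|t|)"])
}

# Gene-set edge density by double loop over all unordered pairs.
bf_edge_density <- function(model, members) {
  members <- sort(members)
  k <- length(members)
  hits <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- members[i]; b <- members[j]
    if (any(model$predictor == a & model$target == b) ||
        any(model$predictor == b & model$target == a)) hits <- hits + 1
  }
  hits / (k * (k - 1) / 2)
}

# Coordinate-descent lasso solving min (1/2n)||y - b0 - Xb||^2 + lambda||b||_1
# (the glmnet objective with an unpenalised intercept). Returns the
# coefficient vector (no intercept) at one lambda.
cd_lasso <- function(X, y, lambda, max_iter = 10000, tol = 1e-12) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- length(y)
  p <- ncol(X)
  b <- rep(0, p)
  xsq <- colSums(Xc^2) / n
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  r <- yc
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      old <- b[j]
      z <- sum(Xc[, j] * r) / n + xsq[j] * old
      b[j] <- soft(z, lambda) / xsq[j]
      if (b[j] != old) {
        r <- r - Xc[, j] * (b[j] - old)
        delta <- max(delta, abs(b[j] - old))
      }
    }
    if (delta < tol) break
  }
  b
}

# Brute-force re-run of the stability-selection loop with the independent
# CD lasso solver, reproducing the documented subsample and lambda policy.
bf_stability_frequencies <- function(target, candidates, expr, config) {
  n <- ncol(expr)
  Z <- expr[c(target, candidates), , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1, sd)
  X <- t(Z[candidates, , drop = FALSE])
  y <- Z[target, ]
  m <- floor(config$subsample_fraction * n)
  grid <- config$lambda_grid
  if (is.null(grid)) {
    lmax <- max(abs(crossprod(X, y)) / n)
    floor_l <- sqrt(2 * log(max(ncol(X), 4)) / m)
    lmin <- max(0.01 * lmax, floor_l)
    lmax <- max(lmax, lmin)
    grid <- exp(seq(log(lmax), log(lmin), length.out = 50))
  }
  grid <- sort(grid, decreasing = TRUE)
  counts <- setNames(numeric(length(candidates)), candidates)
  set.seed(config$seed)
  for (b in seq_len(config$n_subsamples)) {
    idx <- sample.int(n, m)
    betas <- sapply(grid, function(l) cd_lasso(X[idx, , drop = FALSE],
                                               y[idx], l))
    if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
    nz <- abs(betas) > 1e-9
    df <- colSums(nz)
    ok <- which(df <= config$max_predictors_per_fit)
    pick <- if (length(ok)) max(ok) else which.min(df)
    counts <- counts + nz[, pick]
  }
  counts / config$n_subsamples
}

# Closed-form propagation solve.
bf_propagate <- function(A_rownorm, f0, alpha) {
  unname(drop((1 - alpha) *
                solve(diag(nrow(A_rownorm)) - alpha * A_rownorm) %*% f0))
}
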