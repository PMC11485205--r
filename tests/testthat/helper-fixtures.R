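# Small fixtures built in code.

# Expression matrix with named genes/samples from a plain matrix.
fx_expr <- function(m, space = "residual", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, space)
}

# Metadata for evenly sized groups at the given ages.
fx_meta <- function(samples, ages_per_sample,
                    groups = paste0("grp", ages_per_sample)) {
  data.frame(sample_id = samples, age_group = groups,
             age_numeric = ages_per_sample, tissue = "test",
             stringsAsFactors = FALSE)
}

# Metadata with n samples in each of the given (label, age) groups.
fx_group_meta <- function(ages = c(25, 35, 45, 55, 65, 75), n = 5) {
  N <- length(ages) * n
  data.frame(sample_id = sprintf("s%03d", seq_len(N)),
             age_group = rep(paste0("a", ages), each = n),
             age_numeric = rep(ages, each = n), tissue = "test",
             stringsAsFactors = FALSE)
}

# A random sparse DAG-ish model for invariance tests (not necessarily
# acyclic; fine for network-ops).
fx_random_model <- function(n_genes = 10, n_edges = 15, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  pairs <- expand.grid(predictor = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$predictor != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ]
  pick$weight <- round(runif(nrow(pick), 0.1, 2) *
                         sample(c(-1, 1), nrow(pick), TRUE), 3)
  regulatory_model(pick)
}

# Model from a compact edge specification list(c(p, t, w), ...).
fx_model <- function(...) {
  e <- do.call(rbind, lapply(list(...), function(x)
    data.frame(predictor = x[[1]], target = x[[2]],
               weight = as.numeric(x[[3]]), stringsAsFactors = FALSE)))
  regulatory_model(e)
}
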