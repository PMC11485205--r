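# Post-processing and null models over the regulatory network:
# reciprocal-edge pruning, same-chromosome-arm removal, largest connected
# component, degree-preserving target-swap randomization, gene-set edge
# density, undirected symmetrization and score propagation.

#' Prune residual reciprocal edges
#'
#' For every reciprocal edge pair (i -> j, j -> i) the ratio
#' `min(|w_ij|, |w_ji|) / (|w_ij| + |w_ji|)` is computed; when it falls below
#' `ratio_threshold` (default 0.1) the weaker edge (smaller absolute weight)
#' is removed. Equal absolute weights at a sub-threshold ratio (impossible
#' for thresholds <= 0.5) would remove the lexicographically larger
#' (predictor, target) pair. Unpaired edges are untouched.
#'
#' @param model a [regulatory_model()].
#' @param ratio_threshold fraction in \[0, 0.5\].
#' @return the pruned model.
#' @export
prune_residual_edges <- function(model, ratio_threshold = 0.1) {
  if (ratio_threshold < 0 || ratio_threshold > 0.5)
    stop("ratio_threshold must be in [0, 0.5]")
  keys <- edge_key(model$predictor, model$target)
  rev_idx <- match(edge_key(model$target, model$predictor), keys)
  drop <- logical(nrow(model))
  for (i in seq_len(nrow(model))) {
    j <- rev_idx[i]
    if (is.na(j) || j < i) next               # each pair handled once
    wi <- abs(model$weight[i]); wj <- abs(model$weight[j])
    if (min(wi, wj) / (wi + wj) >= ratio_threshold) next
    if (wi < wj) drop[i] <- TRUE
    else if (wj < wi) drop[j] <- TRUE
    else drop[if (keys[i] > keys[j]) i else j] <- TRUE
  }
  out <- model[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove predictors on the target's chromosome arm
#'
#' Drops edges whose predictor and target share both chromosome and arm -
#' such couplings can reflect local effects (e.g. shared copy-number
#' changes in the training data) rather than regulation. Genes without
#' annotation keep their edges, with a warning stating how many.
#'
#' @param model a [regulatory_model()].
#' @param annotation data.frame with columns `gene_id`, `chromosome`, `arm`
#'   (arm labels must be `"p"` or `"q"`).
#' @return the filtered model.
#' @export
remove_same_arm_predictors <- function(model, annotation) {
  if (!all(c("gene_id", "chromosome", "arm") %in% names(annotation)))
    stop("annotation needs columns gene_id, chromosome, arm")
  if (!all(annotation$arm %in% c("p", "q")))
    stop("malformed arm labels (must be 'p' or 'q'): ",
         paste(unique(setdiff(annotation$arm, c("p", "q"))), collapse = ", "))
  ip <- match(model$predictor, annotation$gene_id)
  it <- match(model$target, annotation$gene_id)
  unann <- is.na(ip) | is.na(it)
  if (any(unann))
    warning(sum(unann), " edge(s) with unannotated genes kept")
  same <- !unann &
    annotation$chromosome[ip] == annotation$chromosome[it] &
    annotation$arm[ip] == annotation$arm[it]
  out <- model[!same, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Largest weakly connected component
#'
#' Restricts the model to the largest connected component, ignoring edge
#' direction. Size ties are broken in favour of the component containing the
#' lexicographically smallest gene identifier.
#'
#' @param model a nonempty [regulatory_model()].
#' @return the induced sub-model.
#' @export
largest_connected_component <- function(model) {
  if (!nrow(model)) stop("empty model")
  g <- igraph::graph_from_data_frame(model[, c("predictor", "target")])
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k)
      min(names(comp$membership)[comp$membership == k]), character(1))
    best <- best[order(firsts)[1]]
  }
  keep_genes <- names(comp$membership)[comp$membership == best]
  out <- model[model$predictor %in% keep_genes & model$target %in% keep_genes,
               , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree-preserving target-swap randomization
#'
#' One full pass in which edges are randomly paired and each pair
#' (p1 -> t1, p2 -> t2) becomes (p1 -> t2, p2 -> t1), weights staying with
#' their predictor slot. Swaps that would create a self-edge or a duplicate
#' edge are skipped and the involved edges re-paired, up to `max_retries`
#' rounds. Both degree sequences and the weight multiset are preserved.
#'
#' @param model a [regulatory_model()] with >= 2 edges.
#' @param seed integer seed.
#' @param passes number of full passes (default 1).
#' @param max_retries re-pairing rounds for skipped swaps per pass.
#' @return the randomized model.
#' @export
randomize_targets <- function(model, seed = 1, passes = 1, max_retries = 10) {
  if (nrow(model) < 2) stop("need at least 2 edges")
  set.seed(derive_seed(seed, "randomize_targets"))
  pred <- model$predictor
  tgt <- model$target
  keyenv <- new.env(hash = TRUE, size = nrow(model) * 2)
  for (k in edge_key(pred, tgt)) assign(k, TRUE, envir = keyenv)
  try_swap <- function(i, j) {
    t1 <- tgt[i]; t2 <- tgt[j]
    if (t1 == t2) return(TRUE)                 # identity swap, trivially valid
    k_old1 <- edge_key(pred[i], t1); k_old2 <- edge_key(pred[j], t2)
    k_new1 <- edge_key(pred[i], t2); k_new2 <- edge_key(pred[j], t1)
    if (pred[i] == t2 || pred[j] == t1) return(FALSE)
    rm(list = c(k_old1, k_old2), envir = keyenv)
    if (exists(k_new1, envir = keyenv) || exists(k_new2, envir = keyenv) ||
        k_new1 == k_new2) {
      assign(k_old1, TRUE, envir = keyenv)
      assign(k_old2, TRUE, envir = keyenv)
      return(FALSE)
    }
    assign(k_new1, TRUE, envir = keyenv)
    assign(k_new2, TRUE, envir = keyenv)
    tgt[i] <<- t2; tgt[j] <<- t1
    TRUE
  }
  for (pass in seq_len(passes)) {
    pending <- sample(seq_along(tgt))
    for (round in seq_len(max_retries)) {
      if (length(pending) < 2) break
      nxt <- integer()
      for (k in seq(1, length(pending) - 1, by = 2)) {
        i <- pending[k]; j <- pending[k + 1]
        if (!try_swap(i, j)) nxt <- c(nxt, i, j)
      }
      if (length(pending) %% 2 == 1) nxt <- c(nxt, pending[length(pending)])
      if (length(nxt) < 2) break
      pending <- sample(nxt)
    }
  }
  out <- model
  out$target <- tgt
  regulatory_model(out)
}

#' Gene-set edge density with a one-sample t-test against background
#'
#' The density of a set of k genes is the number of unordered gene pairs in
#' the set connected by at least one edge (in either direction), divided by
#' the maximum possible `k * (k - 1) / 2`. The background is the same
#' statistic over all model genes; set densities are tested against it with
#' a two-sided one-sample t-test.
#'
#' @param model a [regulatory_model()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size sets with fewer usable genes are skipped with a warning.
#' @return list with `densities` (data.frame: set, k, n_connected_pairs,
#'   density), `background`, and `t_test` (an `htest`, or `NULL` when fewer
#'   than 2 sets are usable).
#' @export
gene_set_edge_density <- function(model, sets, min_size = 3) {
  genes <- model_genes(model)
  pairkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  connected <- unique(pairkey(model$predictor, model$target))
  conn_env <- new.env(hash = TRUE, size = length(connected) * 2)
  for (k in connected) assign(k, TRUE, envir = conn_env)
  density_of <- function(members) {
    k <- length(members)
    if (k < 2) return(c(0, 0))
    cmb <- utils::combn(sort(members), 2)
    hits <- sum(vapply(seq_len(ncol(cmb)), function(i)
      exists(pairkey(cmb[1, i], cmb[2, i]), envir = conn_env), logical(1)))
    c(hits, hits / (k * (k - 1) / 2))
  }
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) < min_size) {
      warning("set '", nm, "' has fewer than ", min_size,
              " genes in the model; skipped")
      next
    }
    d <- density_of(members)
    rows[[nm]] <- data.frame(set = nm, k = length(members),
                             n_connected_pairs = d[1], density = d[2],
                             stringsAsFactors = FALSE)
  }
  densities <- if (length(rows)) do.call(rbind, rows)
               else data.frame(set = character(), k = integer(),
                               n_connected_pairs = numeric(),
                               density = numeric())
  rownames(densities) <- NULL
  background <- length(connected) / choose(length(genes), 2)
  tt <- NULL
  if (nrow(densities) >= 2 && sd(densities$density) > 0)
    tt <- t.test(densities$density, mu = background)
  list(densities = densities, background = background, t_test = tt)
}

#' Symmetrize a regulatory model
#'
#' Undirected edge weight `u_ij = w_ij + w_ji` (absent directions contribute
#' 0); pairs whose weights sum to exactly zero are dropped.
#'
#' @param model a [regulatory_model()].
#' @return data.frame with columns `gene1`, `gene2`, `weight`
#'   (gene1 < gene2).
#' @export
symmetrize_model <- function(model) {
  g1 <- pmin(model$predictor, model$target)
  g2 <- pmax(model$predictor, model$target)
  key <- paste(g1, g2, sep = "\r")
  w <- tapply(model$weight, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(gene1 = vapply(parts, `[`, "", 1),
                    gene2 = vapply(parts, `[`, "", 2),
                    weight = as.numeric(w), stringsAsFactors = FALSE)
  out <- out[out$weight != 0, , drop = FALSE]
  out <- out[order(out$gene1, out$gene2), ]
  rownames(out) <- NULL
  out
}

#' Propagate node scores over an undirected weighted graph
#'
#' Random-walk-with-restart smoothing: iterates
#' `F <- alpha * A %*% F + (1 - alpha) * F0` with `A` the row-normalised
#' adjacency (rows divided by their sum; absolute weights by default so
#' negative couplings do not produce signless mixing) until the maximum
#' absolute change falls below `tol`. At convergence this equals
#' `(1 - alpha) * solve(I - alpha * A) %*% F0`. Isolated nodes keep their
#' own score.
#'
#' @param graph data.frame `gene1`, `gene2`, `weight` (see
#'   [symmetrize_model()]).
#' @param scores named numeric vector; graph nodes missing from it get 0
#'   with a warning.
#' @param alpha smoothing weight in \[0, 1) (default 0.2).
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @param abs_weights row-normalise absolute weights (default TRUE).
#' @return named numeric vector of smoothed scores over the graph nodes.
#' @export
propagate_scores <- function(graph, scores, alpha = 0.2, tol = 1e-8,
                             max_iter = 1000, abs_weights = TRUE) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  nodes <- sort(unique(c(graph$gene1, graph$gene2)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w <- if (abs_weights) abs(graph$weight) else graph$weight
  for (i in seq_len(nrow(graph))) {
    A[graph$gene1[i], graph$gene2[i]] <- A[graph$gene1[i], graph$gene2[i]] + w[i]
    A[graph$gene2[i], graph$gene1[i]] <- A[graph$gene2[i], graph$gene1[i]] + w[i]
  }
  rs <- rowSums(abs(A))
  iso <- rs == 0
  A[!iso, ] <- A[!iso, , drop = FALSE] / rs[!iso]
  if (any(iso)) diag(A)[iso] <- 1              # isolated node keeps its score
  f0 <- setNames(rep(0, length(nodes)), nodes)
  known <- intersect(nodes, names(scores))
  if (length(known) < length(nodes))
    warning(length(nodes) - length(known),
            " node(s) without a score set to 0")
  f0[known] <- scores[known]
  f <- f0
  for (it in seq_len(max_iter)) {
    f_new <- alpha * drop(A %*% f) + (1 - alpha) * f0
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) return(f)
  }
  warning("propagation did not reach tol within max_iter iterations")
  f
}
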