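# Module-level decomposition of predictability changes: age slopes of
# target-neighbour correlations, split into within-set versus between-set
# contributions weighted by the model coefficients, and hit-centered
# subnetwork extraction.

#' Age slopes of target-neighbour correlations
#'
#' For every (target, regulatory neighbour) pair - genes sharing at least
#' one edge with the target, in either direction, with the summed edge
#' weight as the pair weight - computes the Pearson correlation within each
#' age group and the OLS slope of those correlations on the group ages.
#' Groups where either gene has zero variance contribute a missing
#' correlation; pairs with fewer than 3 usable groups are skipped.
#'
#' @param expr expression matrix.
#' @param model a [regulatory_model()].
#' @param targets genes (subset of model targets) whose neighbourhoods to
#'   analyse - typically the predictability hits.
#' @param meta sample metadata (every group needs >= 3 samples).
#' @param method correlation method within groups (default `"pearson"`).
#' @return data.frame: target, neighbor, weight, slope, n_groups; attribute
#'   `correlations` carries the per-group correlation matrix (pairs x
#'   groups).
#' @export
neighbor_correlation_slopes <- function(expr, model, targets, meta,
                                        method = "pearson") {
  check_metadata(meta, expr)
  bad <- setdiff(targets, unique(c(model$target, model$predictor)))
  if (length(bad))
    stop("targets absent from the model: ", paste(head(bad, 5), collapse = ", "))
  und <- symmetrize_model(model)
  inc <- und[und$gene1 %in% targets | und$gene2 %in% targets, , drop = FALSE]
  pairs <- data.frame(
    target = ifelse(inc$gene1 %in% targets, inc$gene1, inc$gene2),
    neighbor = ifelse(inc$gene1 %in% targets, inc$gene2, inc$gene1),
    weight = inc$weight, stringsAsFactors = FALSE
  )
  pairs <- pairs[pairs$neighbor %in% rownames(expr) &
                   pairs$target %in% rownames(expr), , drop = FALSE]
  meta <- meta[meta$sample_id %in% colnames(expr), , drop = FALSE]
  ag <- age_group_table(meta)
  sizes <- table(meta$age_group)[ag$age_group]
  if (any(sizes < 3)) stop("every age group needs >= 3 samples")
  C <- matrix(NA_real_, nrow(pairs), nrow(ag),
              dimnames = list(NULL, ag$age_group))
  for (g in ag$age_group) {
    ids <- meta$sample_id[meta$age_group == g]
    sub <- expr[, ids, drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      a <- sub[pairs$target[i], ]; b <- sub[pairs$neighbor[i], ]
      if (sd(a) == 0 || sd(b) == 0) next
      C[i, g] <- cor(a, b, method = method)
    }
  }
  fits <- row_ols(C, ag$age_numeric)
  pairs$slope <- fits$slope
  pairs$n_groups <- fits$n_obs
  keep <- !is.na(pairs$slope) & pairs$n_groups >= 3
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "correlations") <- C[keep, , drop = FALSE]
  out
}

#' Within-set versus between-set contribution summary
#'
#' Splits each hit's neighbour pairs by whether target and neighbour share
#' at least one gene set ("within") or not ("between"), and accumulates the
#' correlation-change slopes weighted by the model coefficients, so strongly
#' coupled neighbours are prioritised. Reported per predictability direction
#' and scope: `weighted_sum = sum(w * slope)` and
#' `weighted_average = weighted_sum / sum(|w|)`.
#'
#' Signed weights are the default: for a negatively coupled neighbour the
#' baseline correlation is negative, so a loss of coordination raises the
#' correlation toward 0; `w * slope` turns every decoupling event into a
#' negative contribution regardless of the coupling sign, whereas `|w|`
#' would let positive- and negative-weight neighbours cancel.
#'
#' @param pairs data.frame from [neighbor_correlation_slopes()].
#' @param hits data.frame with columns `gene`, `direction` (from
#'   [select_top_hits()]).
#' @param sets named list of gene-id vectors; an empty collection makes all
#'   pairs "between". Hits absent from every set are counted and warned
#'   about.
#' @param signed_weights multiply slopes by the signed weight (default);
#'   `FALSE` uses `|w|`.
#' @return data.frame: direction, scope, weighted_sum, weighted_average,
#'   n_pairs; attribute `pair_scope` maps each pair row to its scope.
#' @export
within_between_contributions <- function(pairs, hits, sets = list(),
                                         signed_weights = TRUE) {
  if (!all(c("gene", "direction") %in% names(hits)))
    stop("hits need columns gene, direction")
  pairs <- pairs[pairs$target %in% hits$gene, , drop = FALSE]
  membership <- function(g)
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
  orphan <- unique(pairs$target[!vapply(pairs$target, function(g)
    length(membership(g)) > 0, logical(1))])
  if (length(sets) && length(orphan))
    warning(length(orphan), " hit(s) absent from all gene sets; ",
            "their pairs count as between")
  scope <- vapply(seq_len(nrow(pairs)), function(i) {
    shared <- intersect(membership(pairs$target[i]),
                        membership(pairs$neighbor[i]))
    if (length(shared)) "within" else "between"
  }, character(1))
  direction <- hits$direction[match(pairs$target, hits$gene)]
  w <- if (signed_weights) pairs$weight else abs(pairs$weight)
  wa_denom <- abs(pairs$weight)          # magnitude-normalised average
  grid <- expand.grid(direction = c("increase", "decrease"),
                      scope = c("within", "between"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- direction == grid$direction[i] & scope == grid$scope[i]
    ws <- sum(w[sel] * pairs$slope[sel])
    data.frame(direction = grid$direction[i], scope = grid$scope[i],
               weighted_sum = ws,
               weighted_average = if (any(sel)) ws / sum(wa_denom[sel])
                                  else NA_real_,
               n_pairs = sum(sel), stringsAsFactors = FALSE)
  }))
  attr(out, "pair_scope") <- scope
  out
}

#' Extract the subnetwork around the strongest hits
#'
#' Takes the `n_strongest` hits by absolute predictability slope plus all
#' their immediate regulatory neighbours and returns the induced subgraph
#' with per-node slope annotation (missing for neighbours without a trend).
#'
#' @param model a [regulatory_model()].
#' @param trends data.frame with columns `gene`, `slope` (typically the hit
#'   list).
#' @param n_strongest number of seed hits (default 20); if larger than the
#'   available trends, all are used with a warning.
#' @return list: `edges` (model edges among the nodes), `nodes` (data.frame:
#'   gene, slope, is_hit).
#' @export
extract_hit_subnetwork <- function(model, trends, n_strongest = 20) {
  if (n_strongest > nrow(trends)) {
    warning("n_strongest (", n_strongest, ") exceeds available hits (",
            nrow(trends), "); using all")
    n_strongest <- nrow(trends)
  }
  seeds <- trends$gene[order(-abs(trends$slope), trends$gene)][
    seq_len(n_strongest)]
  incident <- model$predictor %in% seeds | model$target %in% seeds
  nodes <- sort(unique(c(seeds, model$predictor[incident],
                         model$target[incident])))
  edges <- model[model$predictor %in% nodes & model$target %in% nodes,
                 , drop = FALSE]
  rownames(edges) <- NULL
  node_df <- data.frame(
    gene = nodes,
    slope = trends$slope[match(nodes, trends$gene)],
    is_hit = nodes %in% seeds, stringsAsFactors = FALSE
  )
  list(edges = edges, nodes = node_df)
}
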