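make_pair_study <- function(seed = 50) {
  set.seed(seed)
  meta <- fx_group_meta(n = 10)
  x <- rnorm(nrow(meta))
  y <- x + rnorm(nrow(meta), 0, 0.1)
  z <- rnorm(nrow(meta))
  expr <- fx_expr(rbind(t1 = y, p1 = x, p2 = z),
                  samples = meta$sample_id, genes = c("t1", "p1", "p2"))
  model <- fx_model(list("p1", "t1", 1.5), list("p2", "t1", -0.4))
  list(expr = expr, meta = meta, model = model)
}

test_that("a constant perfect correlation has slope zero and Pearson matches the textbook formula", {
  st <- make_pair_study()
  st$expr["t1", ] <- 2 * st$expr["p1", ] + 1   # exact correlation 1 everywhere
  st$expr <- fx_expr(unclass(st$expr), genes = rownames(st$expr),
                     samples = colnames(st$expr))
  pairs <- neighbor_correlation_slopes(st$expr, st$model, "t1", st$meta)
  expect_equal(pairs$slope[pairs$neighbor == "p1"], 0, tolerance = 1e-12)
  # worked 4-sample Pearson check against the covariance formula
  a <- c(1, 2, 4, 7); b <- c(2, 1, 5, 9)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cor(a, b), manual, tolerance = 1e-12)
})

test_that("planted decoupling produces negative correlation slopes for true predictor pairs", {
  cfg0 <- sim_config(n_genes = 60, n_modules = 2, n_samples_per_group = 80,
                     seed = 51)
  net <- simulate_network(cfg0)
  leaves <- sort(setdiff(unique(net$model$target), net$model$predictor))
  planted <- head(leaves, 8)
  cfg <- sim_config(n_genes = 60, n_modules = 2, n_samples_per_group = 80,
                    seed = 51,
                    coupling_schedule = setNames(
                      lapply(planted, function(g) seq(1, 0, length.out = 6)),
                      planted))
  sim <- simulate_expression(net, cfg)
  pairs <- neighbor_correlation_slopes(sim$expr, net$model, planted, sim$meta)
  keep <- paste(pairs$neighbor, pairs$target) %in%
    paste(net$model$predictor, net$model$target)
  true_pairs <- pairs[keep, ]
  # decoupling pulls every pair correlation toward 0: the slope is opposite
  # in sign to the youngest-group (fully coupled) correlation
  base_cor <- attr(pairs, "correlations")[keep, 1]
  expect_gte(mean(sign(base_cor) * true_pairs$slope < 0), 0.95)
})

test_that("contribution sums follow the worked arithmetic example", {
  pairs <- data.frame(target = c("h1", "h1"), neighbor = c("n1", "n2"),
                      weight = c(2, 1), slope = c(0.01, -0.02),
                      n_groups = 6)
  hits <- data.frame(gene = "h1", direction = "increase")
  sets <- list(s1 = c("h1", "n1"))
  contr <- within_between_contributions(pairs, hits, sets)
  inc <- contr[contr$direction == "increase", ]
  expect_equal(inc$weighted_sum[inc$scope == "within"], 0.02)
  expect_equal(inc$weighted_sum[inc$scope == "between"], -0.02)
  expect_equal(inc$weighted_average[inc$scope == "within"], 0.01)
  expect_equal(inc$n_pairs, c(1, 1))
})

test_that("an empty collection sends all pairs between, and additivity holds", {
  set.seed(52)
  pairs <- data.frame(target = rep(c("h1", "h2"), each = 4),
                      neighbor = paste0("n", 1:8),
                      weight = rnorm(8), slope = rnorm(8, 0, 0.01),
                      n_groups = 6)
  hits <- data.frame(gene = c("h1", "h2"),
                     direction = c("increase", "decrease"))
  c_empty <- within_between_contributions(pairs, hits, list())
  expect_true(all(c_empty$n_pairs[c_empty$scope == "within"] == 0))
  sets <- list(a = c("h1", "n1", "n2"), b = c("h2", "n5"))
  ctr <- within_between_contributions(pairs, hits, sets)
  for (d in c("increase", "decrease")) {
    tot <- sum(ctr$weighted_sum[ctr$direction == d])
    sel <- hits$gene[hits$direction == d]
    direct <- sum((pairs$weight * pairs$slope)[pairs$target %in% sel])
    expect_equal(tot, direct, tolerance = 1e-12)
  }
})

test_that("renaming sets changes nothing and enlarging a set only moves pairs inward", {
  set.seed(53)
  pairs <- data.frame(target = "h1", neighbor = paste0("n", 1:5),
                      weight = runif(5, 0.2, 1), slope = rnorm(5, 0, 0.01),
                      n_groups = 6)
  hits <- data.frame(gene = "h1", direction = "decrease")
  sets1 <- list(alpha = c("h1", "n1"))
  sets2 <- list(zzz = c("h1", "n1"))
  expect_equal(within_between_contributions(pairs, hits, sets1)[, -(1:2)],
               within_between_contributions(pairs, hits, sets2)[, -(1:2)])
  bigger <- list(alpha = c("h1", "n1", "n2", "n3"))
  s1 <- attr(within_between_contributions(pairs, hits, sets1), "pair_scope")
  s2 <- attr(within_between_contributions(pairs, hits, bigger), "pair_scope")
  expect_true(all(s2[s1 == "within"] == "within"))
})

test_that("hit subnetworks contain the strongest hits plus immediate neighbours", {
  model <- fx_model(list("n1", "h1", 1), list("n2", "h1", -1),
                    list("h1", "n3", 0.5),
                    list("n3", "h2", 1), list("x", "y", 1))
  trends <- data.frame(gene = c("h1", "h2"), slope = c(-0.02, 0.01))
  sub <- extract_hit_subnetwork(model, trends, n_strongest = 1)
  expect_setequal(sub$nodes$gene, c("h1", "n1", "n2", "n3"))  # 4-node star
  expect_true(sub$nodes$is_hit[sub$nodes$gene == "h1"])
  sub2 <- extract_hit_subnetwork(model, trends, n_strongest = 2)
  expect_setequal(sub2$nodes$gene, c("h1", "h2", "n1", "n2", "n3"))
  # two hits sharing neighbour n3 form one connected component
  g <- igraph::graph_from_data_frame(sub2$edges[, 1:2])
  expect_equal(igraph::components(g)$no, 1)
  # node set is monotone in n_strongest
  expect_true(all(sub$nodes$gene %in% sub2$nodes$gene))
  expect_warning(extract_hit_subnetwork(model, trends, n_strongest = 5),
                 "exceeds")
})
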