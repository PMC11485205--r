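test_that("reciprocal-edge pruning removes the weaker edge of unbalanced pairs only", {
  m <- fx_model(list("a", "b", 1.0), list("b", "a", 0.05),   # ratio 0.0476
                list("c", "d", 0.5), list("d", "c", 0.5),    # ratio 0.5
                list("e", "f", 0.9))                          # unpaired
  out <- prune_residual_edges(m, 0.1)
  expect_false(any(out$predictor == "b" & out$target == "a"))
  expect_true(any(out$predictor == "a" & out$target == "b"))
  expect_equal(sum(out$predictor %in% c("c", "d")), 2)
  expect_true(any(out$predictor == "e"))
  # the threshold is behavioural: at 0.04 the weak edge survives
  out2 <- prune_residual_edges(m, 0.04)
  expect_true(any(out2$predictor == "b" & out2$target == "a"))
  expect_error(prune_residual_edges(m, 0.7), "0.5")
})

test_that("same-arm predictors are removed and unannotated genes kept with a warning", {
  m <- fx_model(list("a", "b", 1), list("c", "d", 1), list("x", "b", 1))
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chromosome = c("1", "1", "1", "1"),
                    arm = c("p", "p", "p", "q"))
  expect_warning(out <- remove_same_arm_predictors(m, ann), "unannotated")
  expect_false(any(out$predictor == "a"))       # 1p -> 1p removed
  expect_true(any(out$predictor == "c"))        # 1p -> 1q kept
  expect_true(any(out$predictor == "x"))        # unannotated kept
  bad <- ann; bad$arm[1] <- "z"
  expect_error(remove_same_arm_predictors(m, bad), "arm labels")
})

test_that("the largest weakly connected component is selected with a lexicographic tie-break", {
  m <- fx_model(list("a", "b", 1), list("b", "c", 1), list("c", "d", 1),
                list("d", "e", 1),                       # component of 5
                list("x", "y", 1), list("y", "z", 1))    # component of 3
  out <- largest_connected_component(m)
  expect_setequal(model_genes(out), c("a", "b", "c", "d", "e"))
  # identity on a connected model
  expect_identical(largest_connected_component(out), out)
  tie <- fx_model(list("m", "n", 1), list("n", "o", 1),
                  list("a", "b", 1), list("b", "c", 1))
  out_tie <- largest_connected_component(tie)
  expect_setequal(model_genes(out_tie), c("a", "b", "c"))
})

test_that("a forced target swap exchanges targets and keeps weights with their predictor", {
  m <- fx_model(list("a", "b", 0.5), list("c", "d", -0.2))
  out <- randomize_targets(m, seed = 1)
  expect_setequal(paste(out$predictor, out$target),
                  c("a d", "c b"))
  expect_equal(out$weight[out$predictor == "a"], 0.5)
  expect_equal(out$weight[out$predictor == "c"], -0.2)
})

test_that("target-swap randomization preserves degrees and the weight multiset", {
  for (s in 1:25) {
    m <- fx_random_model(n_genes = 8, n_edges = 12, seed = s)
    out <- randomize_targets(m, seed = s + 100)
    expect_equal(nrow(out), nrow(m))
    expect_equal(sort(out$weight), sort(m$weight))
    expect_equal(table(out$predictor), table(m$predictor))
    expect_equal(sort(table(out$target)), sort(table(m$target)))
    expect_false(any(out$predictor == out$target))
    expect_equal(anyDuplicated(paste(out$predictor, out$target)), 0)
  }
})

test_that("gene-set edge density matches the pair-enumeration oracle", {
  m <- fx_model(list("a", "b", 1), list("b", "c", 1), list("d", "e", 1),
                list("e", "a", 1))
  res <- gene_set_edge_density(m, list(s1 = c("a", "b", "c")))
  expect_equal(res$densities$density, 2 / 3)
  res0 <- gene_set_edge_density(m, list(s0 = c("a", "c", "d")))
  expect_equal(res0$densities$density, 0)
  set.seed(3)
  m2 <- fx_random_model(n_genes = 30, n_edges = 80, seed = 3)
  sets <- lapply(1:5, function(i) sample(model_genes(m2), sample(4:10, 1)))
  names(sets) <- paste0("set", 1:5)
  res2 <- gene_set_edge_density(m2, sets)
  for (nm in names(sets))
    expect_equal(res2$densities$density[res2$densities$set == nm],
                 bf_edge_density(m2, sets[[nm]]))
  expect_s3_class(res2$t_test, "htest")
  # small sets are skipped with a warning and no test with < 2 usable sets
  expect_warning(r3 <- gene_set_edge_density(m, list(tiny = c("a", "b"),
                                                     s1 = c("a", "b", "c"))),
                 "skipped")
  expect_null(r3$t_test)
})

test_that("symmetrization sums reciprocal weights and drops exact zero sums", {
  m <- fx_model(list("a", "b", 0.3), list("b", "a", 0.2),
                list("c", "d", 0.3),
                list("e", "f", 0.3), list("f", "e", -0.3))
  u <- symmetrize_model(m)
  expect_equal(u$weight[u$gene1 == "a"], 0.5)
  expect_equal(u$weight[u$gene1 == "c"], 0.3)
  expect_false(any(u$gene1 == "e"))
})

test_that("propagation matches the closed form and collapses to the input at alpha 0", {
  g <- data.frame(gene1 = "a", gene2 = "b", weight = 1)
  f <- propagate_scores(g, c(a = 1, b = 0), alpha = 0.2)
  expect_equal(unname(f), c(5 / 6, 1 / 6), tolerance = 1e-8)
  expect_equal(unname(propagate_scores(g, c(a = 1, b = 0), alpha = 0)),
               c(1, 0))
  # random graph: fixed point equals (1 - a)(I - aA)^-1 F0
  set.seed(8)
  m <- fx_random_model(n_genes = 12, n_edges = 25, seed = 8)
  u <- symmetrize_model(m)
  nodes <- sort(unique(c(u$gene1, u$gene2)))
  f0 <- setNames(rnorm(length(nodes)), nodes)
  f1 <- propagate_scores(u, f0, alpha = 0.2, tol = 1e-12)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(u))) {
    A[u$gene1[i], u$gene2[i]] <- A[u$gene1[i], u$gene2[i]] + abs(u$weight[i])
    A[u$gene2[i], u$gene1[i]] <- A[u$gene2[i], u$gene1[i]] + abs(u$weight[i])
  }
  A <- A / rowSums(A)
  expect_equal(unname(f1[nodes]), bf_propagate(A, f0[nodes], 0.2),
               tolerance = 1e-8)
  # smoothing is a contraction toward the input range
  expect_true(all(f1 >= min(f0) - 1e-12 & f1 <= max(f0) + 1e-12))
})

test_that("isolated nodes keep their own score and missing scores warn", {
  g <- data.frame(gene1 = c("a", "c"), gene2 = c("b", "c2"),
                  weight = c(1, 1))
  expect_warning(f <- propagate_scores(g, c(a = 1, b = 0, c = 2),
                                       alpha = 0.5), "without a score")
  expect_true(is.finite(f["c2"]))
})

test_that("prune -> largest-component is idempotent on its own output", {
  for (s in 1:5) {
    m <- fx_random_model(n_genes = 12, n_edges = 20, seed = s)
    once <- largest_connected_component(prune_residual_edges(m, 0.1))
    twice <- largest_connected_component(prune_residual_edges(once, 0.1))
    expect_identical(as.data.frame(twice), as.data.frame(once))
  }
})
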