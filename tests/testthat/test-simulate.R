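test_that("a single-module network with edge probability 1 is the complete DAG", {
  cfg <- sim_config(n_genes = 4, n_modules = 1, within_module_edge_prob = 1,
                    max_in_degree = Inf, seed = 3)
  net <- simulate_network(cfg)
  expect_equal(nrow(net$model), 6)            # 4-node DAG in topological order
  expect_equal(sort(unique(net$model$target)), sort(setdiff(net$order, net$order[1])))
})

test_that("no edge crosses module boundaries when the between probability is 0", {
  cfg <- sim_config(n_genes = 60, n_modules = 3,
                    within_module_edge_prob = 0.2,
                    between_module_edge_prob = 0, seed = 5)
  net <- simulate_network(cfg)
  expect_true(all(net$modules[net$model$predictor] ==
                    net$modules[net$model$target]))
})

test_that("every non-root gene has at least one predictor and the seed fixes the draw", {
  cfg <- sim_config(n_genes = 80, n_modules = 4, seed = 11)
  net1 <- simulate_network(cfg)
  net2 <- simulate_network(cfg)
  expect_identical(net1$model, net2$model)
  expect_identical(net1$order, net2$order)
  expect_setequal(unique(net1$model$target), setdiff(net1$order, net1$order[1]))
  expect_true(all(table(net1$model$target) <= cfg$max_in_degree))
  expect_true(all(net1$model$weight != 0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(within_module_edge_prob = 1.2), "probabilities")
  expect_error(sim_config(n_samples_per_group = 2), "n_samples_per_group")
  expect_error(sim_config(n_genes = 2, n_modules = 5), "n_genes")
  expect_error(sim_config(age_groups = data.frame(age_group = c("a", "b"),
                                                  age_numeric = c(30, 30))),
               "strictly increasing")
  expect_error(sim_config(coupling_schedule = list(g0001 = rep(3, 6))),
               "\\[0, 2\\]")
})

test_that("the noiseless system reproduces each gene as its exact weighted predictor sum", {
  cfg <- sim_config(n_genes = 30, n_modules = 2, noise_sd = 0, seed = 2)
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  m <- net$model
  for (g in unique(m$target)) {
    rows <- m[m$target == g, ]
    pred_sum <- drop(crossprod(sim$expr[rows$predictor, , drop = FALSE],
                               rows$weight))
    expect_equal(unname(sim$expr[g, ]), unname(pred_sum), tolerance = 1e-12)
  }
})

test_that("a coupling declining to 0 decorrelates the gene from its predictors in the oldest group", {
  cfg0 <- sim_config(n_genes = 40, n_modules = 2, n_samples_per_group = 200,
                     seed = 4)
  net <- simulate_network(cfg0)
  g <- sort(unique(net$model$target))[1]
  cfg <- sim_config(n_genes = 40, n_modules = 2, n_samples_per_group = 200,
                    seed = 4,
                    coupling_schedule = setNames(
                      list(seq(1, 0, length.out = 6)), g))
  sim <- simulate_expression(net, cfg)
  old <- sim$meta$sample_id[sim$meta$age_group == "70-79"]
  for (p in net$model$predictor[net$model$target == g])
    expect_lt(abs(cor(sim$expr[g, old], sim$expr[p, old])), 0.15)
  # and in the youngest group the coupling is intact
  young <- sim$meta$sample_id[sim$meta$age_group == "20-29"]
  preds <- net$model[net$model$target == g, ]
  s <- drop(crossprod(sim$expr[preds$predictor, young, drop = FALSE],
                      preds$weight))
  expect_gt(cor(sim$expr[g, young], s), 0.9)
  expect_identical(unname(sim$truth$labels[g]), "coordination_loss")
})

test_that("a mean trend of 0.01/year separates the extreme group means by 0.5", {
  cfg0 <- sim_config(n_genes = 20, n_modules = 1, n_samples_per_group = 400,
                     noise_sd = 0.01, expr_sd = 0.05, seed = 9)
  net <- simulate_network(cfg0)
  g <- net$order[1]                            # root: no upstream variability
  cfg <- sim_config(n_genes = 20, n_modules = 1, n_samples_per_group = 400,
                    noise_sd = 0.01, expr_sd = 0.05, seed = 9,
                    mean_trend = setNames(0.01, g))
  sim <- simulate_expression(net, cfg)
  young <- sim$meta$sample_id[sim$meta$age_group == "20-29"]
  old <- sim$meta$sample_id[sim$meta$age_group == "70-79"]
  expect_equal(mean(sim$expr[g, old]) - mean(sim$expr[g, young]), 0.5,
               tolerance = 0.02)
  expect_true(g %in% sim$truth$mean_changers)
})

test_that("ground-truth labels are reproducible and consistent with the schedule", {
  sched <- list(g0005 = seq(1, 0.2, length.out = 6),
                g0006 = seq(0.5, 1.5, length.out = 6),
                g0007 = c(1, 1.4, 1, 1.4, 1, 1.4))
  cfg <- sim_config(n_genes = 50, n_modules = 2, seed = 6,
                    coupling_schedule = sched)
  net <- simulate_network(cfg)
  s1 <- simulate_expression(net, cfg)
  s2 <- simulate_expression(net, cfg)
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_identical(unname(s1$truth$labels[c("g0005", "g0006", "g0007")]),
                   c("coordination_loss", "coordination_gain", "stable"))
  expect_identical(s1$expr, s2$expr)
})

test_that("count export is Poisson-like and preprocessing recovers the signal", {
  cfg <- sim_config(n_genes = 50, n_modules = 2, n_samples_per_group = 10,
                    seed = 8)
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  counts <- simulate_counts(sim, base_count = 2000, seed = 8)
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  norm <- normalize_and_log(counts)
  cors <- vapply(rownames(sim$expr),
                 function(g) cor(sim$expr[g, ], norm[g, ]), numeric(1))
  expect_gt(median(cors), 0.8)
})

test_that("a cyclic bare model is rejected by the generator", {
  cyc <- fx_model(list("a", "b", 1), list("b", "a", 1))
  cfg <- sim_config(n_genes = 2, n_modules = 1)
  expect_error(simulate_expression(cyc, cfg), "acyclic")
})
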