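make_table <- function(rho, ages = c(25, 35, 45, 55, 65, 75)) {
  structure(list(rho = rho,
                 group_ages = setNames(ages, colnames(rho)),
                 group_sizes = rep(30L, length(ages))),
            class = "predictability_table")
}

test_that("per-group predictability is perfect on the noiseless simulation", {
  cfg <- sim_config(n_genes = 30, n_modules = 2, noise_sd = 0,
                    n_samples_per_group = 10, seed = 15)
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  rec <- reconstruct_expression(net$model, sim$expr)
  tab <- predictability_by_group(sim$expr, rec, sim$meta)
  expect_true(all(abs(tab$rho[rownames(rec), ] - 1) < 1e-12))
  expect_equal(unname(tab$group_ages), c(25, 35, 45, 55, 65, 75))
})

test_that("groups with fewer than 3 samples are dropped with a warning", {
  cfg <- sim_config(n_genes = 10, n_modules = 1, n_samples_per_group = 4,
                    seed = 16)
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  rec <- reconstruct_expression(net$model, sim$expr)
  meta <- sim$meta[-(1:2), ]                   # 20-29 down to 2 samples
  obs <- expression_matrix(sim$expr[, meta$sample_id], "residual")
  expect_warning(tab <- predictability_by_group(obs, rec, meta), "dropped")
  expect_false("20-29" %in% colnames(tab$rho))
})

test_that("a declining planted coupling yields declining predictability", {
  cfg0 <- sim_config(n_genes = 50, n_modules = 2, n_samples_per_group = 40,
                     seed = 17)
  net <- simulate_network(cfg0)
  g <- sort(setdiff(unique(net$model$target), net$model$predictor))[1]
  cfg <- sim_config(n_genes = 50, n_modules = 2, n_samples_per_group = 40,
                    seed = 17,
                    coupling_schedule = setNames(list(seq(1, 0, length.out = 6)), g))
  sim <- simulate_expression(net, cfg)
  rec <- reconstruct_expression(net$model, sim$expr)
  tab <- predictability_by_group(sim$expr, rec, sim$meta)
  expect_lt(tab$rho[g, "70-79"], tab$rho[g, "20-29"] - 0.5)
  tr <- fit_predictability_slopes(tab)
  expect_lt(tr$slope[tr$gene == g], -0.01)
})

test_that("slope fitting reproduces exact lines and the degenerate constant case", {
  rho <- rbind(lin = seq(0.9, 0.8, by = -0.02), flat = rep(0.7, 6))
  colnames(rho) <- paste0("a", 1:6)
  tr <- fit_predictability_slopes(make_table(rho))
  expect_equal(tr$slope[tr$gene == "lin"], -0.002, tolerance = 1e-12)
  expect_lt(tr$p_value[tr$gene == "lin"], 1e-12)
  expect_equal(tr$slope[tr$gene == "flat"], 0)
  expect_equal(tr$p_value[tr$gene == "flat"], 1)
})

test_that("slope, t and p match the lm oracle on random tables", {
  set.seed(30)
  rho <- matrix(runif(8 * 6, -0.2, 0.9), 8, 6,
                dimnames = list(paste0("g", 1:8), paste0("a", 1:6)))
  ages <- c(25, 35, 45, 55, 65, 75)
  tr <- fit_predictability_slopes(make_table(rho, ages))
  for (g in rownames(rho)) {
    o <- bf_ols(rho[g, ], ages)
    i <- which(tr$gene == g)
    expect_equal(tr$slope[i], o$slope, tolerance = 1e-10)
    expect_equal(tr$t_statistic[i], o$t, tolerance = 1e-10)
    expect_equal(tr$p_value[i], o$p, tolerance = 1e-10)
  }
})

test_that("slopes are antisymmetric under reversing the age axis", {
  set.seed(31)
  rho <- matrix(runif(5 * 6, 0, 1), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("a", 1:6)))
  fwd <- fit_predictability_slopes(make_table(rho, c(25, 35, 45, 55, 65, 75)))
  rev <- fit_predictability_slopes(make_table(rho, -c(25, 35, 45, 55, 65, 75)))
  expect_equal(fwd$slope, -rev$slope, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("the calibration threshold is the interpolated 95th percentile of the null", {
  cfg <- sim_config(n_genes = 60, n_modules = 2, n_samples_per_group = 10,
                    seed = 18)
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  thr <- calibrate_predictability_threshold(sim$expr, net$model, seed = 6)
  null_rho <- attr(thr, "null_rho")
  s <- sort(null_rho)
  h <- (length(s) - 1) * 0.95 + 1
  manual <- unname(s[floor(h)] +
                     (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)]))
  expect_equal(as.numeric(thr), manual, tolerance = 1e-12)
  # under the true model most genes clear the randomized-model threshold
  rec <- reconstruct_expression(net$model, sim$expr)
  rho_true <- prediction_quality(sim$expr, rec)
  expect_gt(mean(rho_true > as.numeric(thr), na.rm = TRUE),
            mean(null_rho > as.numeric(thr)) + 0.3)
})

test_that("the permutation null has the configured size and is seed-reproducible", {
  set.seed(33)
  rho <- matrix(runif(20 * 6, 0.2, 0.9), 20, 6,
                dimnames = list(paste0("g", 1:20), paste0("a", 1:6)))
  tab <- make_table(rho)
  pn <- permutation_null(tab, n_perm = 100, seed = 4)
  expect_equal(ncol(pn$p_null), 100)
  expect_equal(pn$n_perm, 100)
  pn2 <- permutation_null(tab, n_perm = 100, seed = 4)
  expect_identical(pn$p_null, pn2$p_null)
  expect_named(pn$summary, c("cutoff", "real_fraction", "null_fraction"))
})

test_that("hit selection ranks by p-value and enforces slope-sign consistency", {
  tr <- data.frame(gene = c("g1", "g2", "g3"),
                   slope = c(0.01, 0.02, -0.03),
                   stderr = 1, t_statistic = 1,
                   p_value = c(0.001, 0.5, 0.01), n_groups = 6)
  hits <- select_top_hits(tr, n_top = 2)
  expect_identical(hits$gene, c("g1", "g3"))
  expect_identical(hits$direction, c("increase", "decrease"))
  # sign flip without the oldest group drops the gene
  wo <- data.frame(gene = c("g1", "g2", "g3"),
                   slope = c(-0.0005, 0.01, -0.01))
  hits2 <- suppressWarnings(select_top_hits(tr, n_top = 3,
                                            trends_without_oldest = wo))
  expect_false("g1" %in% hits2$gene)
  # order invariance
  perm <- tr[c(3, 1, 2), ]
  expect_identical(select_top_hits(perm, n_top = 2)$gene, hits$gene)
  expect_warning(select_top_hits(tr, n_top = 10), "exceeds")
})
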