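# Canonical benchmark scenarios built on the synthetic generator. These fix
# the study conditions used to validate the method at desk scale:
#
#   null                500 genes, 6 groups x 40 samples, no planted trends;
#                       calibrates the false-positive behaviour of the
#                       Predictability ~ Age test.
#   recovery            as null, plus 50 planted coordination-loss genes
#                       (coupling 1 -> 0.2 across groups) and 10 planted
#                       variance-increase genes with rising coupling
#                       (0.2 -> 2) and noise-scale drift 0.05/year; measures
#                       top-100 recall and driver classification.
#   between_decoupling  120 genes, 4 modules with abundant cross-module
#                       edges; up to 20 targets lose only their
#                       between-module couplings (1 -> 0); measures the
#                       within/between decomposition.

#' Simulate a canonical benchmark study
#'
#' Builds the network first, then plants effects on deterministically chosen
#' non-root genes (the first gene in the topological order has no
#' predictors and is never planted).
#'
#' @param scenario one of `"null"`, `"recovery"`, `"between_decoupling"`.
#' @param seed integer seed.
#' @return list: `network` (`sim_network`), `sim` (`sim_study`), `config`,
#'   and `planted` (list of planted gene vectors: `loss`, `var_gain`,
#'   `between_loss`).
#' @export
simulate_benchmark <- function(scenario = c("null", "recovery",
                                            "between_decoupling"),
                               seed = 1) {
  scenario <- match.arg(scenario)
  decline <- seq(1, 0.2, length.out = 6)
  if (scenario %in% c("null", "recovery")) {
    base <- sim_config(n_genes = 500, n_modules = 5, seed = seed)
    net <- simulate_network(base)
    planted <- list(loss = character(), var_gain = character(),
                    between_loss = character())
    schedule <- list()
    vtrend <- numeric()
    if (scenario == "recovery") {
      # plant on leaf targets (out-degree 0) so each planted phenotype is
      # isolated: no planted gene feeds another gene, hence no cascading
      # secondary trends that would confound recovery
      leaves <- sort(setdiff(unique(net$model$target), net$model$predictor))
      if (length(leaves) < 60)
        stop("network has too few leaf targets for the recovery scenario")
      planted$loss <- leaves[1:50]
      planted$var_gain <- leaves[51:60]
      schedule <- c(
        setNames(lapply(planted$loss, function(g) decline), planted$loss),
        setNames(lapply(planted$var_gain,
                        function(g) seq(0.1, 2, length.out = 6)),
                 planted$var_gain))
      vtrend <- setNames(rep(0.18, 10), planted$var_gain)
    }
    cfg <- sim_config(n_genes = 500, n_modules = 5, seed = seed,
                      coupling_schedule = schedule, variance_trend = vtrend)
  } else {
    base <- sim_config(n_genes = 120, n_modules = 4,
                       within_module_edge_prob = 0.04,
                       between_module_edge_prob = 0.03, seed = seed)
    net <- simulate_network(base)
    m <- net$model
    mods <- net$modules
    between_edges <- mods[m$predictor] != mods[m$target]
    eligible <- sort(unique(m$target[between_edges]))
    full_loss <- seq(1, 0, length.out = 6)   # complete between-module decoupling
    planted <- list(loss = character(), var_gain = character(),
                    between_loss = head(eligible, 20))
    schedule <- setNames(lapply(planted$between_loss, function(g)
      list(multiplier = full_loss, scope = "between")), planted$between_loss)
    cfg <- sim_config(n_genes = 120, n_modules = 4,
                      within_module_edge_prob = 0.04,
                      between_module_edge_prob = 0.03, seed = seed,
                      coupling_schedule = schedule)
  }
  sim <- simulate_expression(net, cfg)
  list(network = net, sim = sim, config = cfg, planted = planted)
}

#' Run the predictability analysis on a simulated study
#'
#' Convenience wrapper used by the benchmark scenarios: reconstructs
#' expression with the true network, computes per-age-group predictability,
#' fits the Predictability ~ Age slopes with and without the oldest group,
#' and selects the consistency-filtered top hits.
#'
#' @param bench result of [simulate_benchmark()].
#' @param n_top number of hits to select (default 100).
#' @return list: `recon`, `table`, `trends`, `trends_wo`, `hits`.
#' @export
analyze_benchmark <- function(bench, n_top = 100) {
  recon <- reconstruct_expression(bench$network$model, bench$sim$expr)
  tab <- predictability_by_group(bench$sim$expr, recon, bench$sim$meta)
  trends <- fit_predictability_slopes(tab)
  trends_wo <- fit_predictability_slopes(drop_oldest_group(tab))
  hits <- select_top_hits(trends, n_top = n_top,
                          trends_without_oldest = trends_wo)
  list(recon = recon, table = tab, trends = trends, trends_wo = trends_wo,
       hits = hits)
}
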