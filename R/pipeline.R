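# End-to-end orchestration behind a single (YAML or list) configuration:
# simulate or ingest -> preprocess -> train or load the model -> network
# processing -> threshold calibration -> reconstruction -> predictability
# trends and permutation null -> hits -> drivers -> module decomposition,
# with stage-derived seeds and a hashed output manifest.

#' Default pipeline configuration
#'
#' All method constants default to their canonical values: prune ratio 0.1,
#' calibration quantile 0.95, 100 age permutations, driver cutoff 0.001,
#' top-100 hits, 20-strongest subnetwork seeds, propagation alpha 0.2,
#' minimum mean count 100, poor-prediction threshold 0.2.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    simulate = list(enabled = TRUE),
    inputs = list(expression = NULL, counts = NULL, metadata = NULL,
                  model = NULL, annotation = NULL, gene_sets = NULL),
    preprocess = list(enabled = FALSE, min_mean_count = 100,
                      allowed_biotypes = NULL, covariates = NULL,
                      balance = FALSE, exclude_from_min = NULL,
                      min_keep_oldest = 10, n_fixed = NULL),
    train = list(enabled = FALSE, n_subsamples = 100,
                 subsample_fraction = 0.5, selection_threshold = 0.6,
                 max_predictors = NULL, max_predictors_per_fit = 20),
    network = list(prune = TRUE, ratio_threshold = 0.1,
                   same_arm = FALSE, largest_component = TRUE),
    predictability = list(quantile = 0.95, n_randomizations = 1,
                          n_perm = 100, n_top = 100,
                          require_consistency = TRUE,
                          poor_prediction_threshold = 0.2),
    drivers = list(cutoff = 0.001),
    coordination = list(enabled = TRUE, n_strongest = 20),
    propagation = list(enabled = FALSE, alpha = 0.2, tol = 1e-8,
                       max_iter = 1000)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "simulate" && k != "inputs") {
      if (!is.list(user[[k]])) stop("'", k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Fills defaults (see [default_config()]), rejects unknown keys, checks
#' field types and referenced files, and returns the completed
#' configuration.
#'
#' @param config a YAML file path or a nested list.
#' @return the validated configuration list (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_config()
  # `simulate` accepts sim_config() arguments beyond `enabled`
  sim_user <- config$simulate
  config$simulate <- NULL
  inputs_user <- config$inputs
  config$inputs <- NULL
  cfg <- merge_config(defaults, config)
  if (!is.null(sim_user)) {
    extra <- setdiff(names(sim_user),
                     c("enabled", names(formals(sim_config))))
    if (length(extra))
      stop("unknown configuration key(s): ",
           paste0("simulate.", extra, collapse = ", "))
    cfg$simulate <- modifyList(cfg$simulate, sim_user)
  }
  if (!is.null(inputs_user)) {
    extra <- setdiff(names(inputs_user), names(defaults$inputs))
    if (length(extra))
      stop("unknown configuration key(s): ",
           paste0("inputs.", extra, collapse = ", "))
    cfg$inputs <- modifyList(cfg$inputs, inputs_user)
  }
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop("field '", nm, "' must be a positive number")
  }
  check_pos(cfg$predictability$n_perm, "predictability.n_perm")
  check_pos(cfg$predictability$n_top, "predictability.n_top")
  check_pos(cfg$coordination$n_strongest, "coordination.n_strongest")
  check_pos(cfg$drivers$cutoff, "drivers.cutoff")
  if (cfg$propagation$alpha < 0 || cfg$propagation$alpha >= 1)
    stop("field 'propagation.alpha' must be in [0, 1)")
  if (cfg$network$ratio_threshold < 0 || cfg$network$ratio_threshold > 0.5)
    stop("field 'network.ratio_threshold' must be in [0, 0.5]")
  q <- cfg$predictability$quantile
  if (q <= 0 || q >= 1) stop("field 'predictability.quantile' must be in (0, 1)")
  for (nm in names(cfg$inputs)) {
    f <- cfg$inputs[[nm]]
    if (!is.null(f) && !file.exists(f))
      stop("input file for '", nm, "' not found: ", f)
  }
  if (!isTRUE(cfg$simulate$enabled) &&
      (is.null(cfg$inputs$expression) && is.null(cfg$inputs$counts)))
    stop("either enable simulation or provide an expression/counts input")
  class(cfg) <- c("run_config", "list")
  cfg
}

write_stage <- function(obj, dir, name, writer) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  writer(obj, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order. With `out_dir` set,
#' every stage output is written as TSV and hashed (md5) into
#' `manifest.json`; rerunning with the same configuration reproduces
#' identical hashes. Stage failures halt the run with the failing stage
#' named; outputs written up to that point are retained.
#'
#' @param config a [validate_config()] result, YAML path, or list.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir <- cfg$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  log_path <- if (!is.null(dir)) file.path(dir, "run.log") else NULL
  log_line <- function(stage, status, secs = NULL) {
    message(sprintf("[coordshift] %-14s %s%s", stage, status,
                    if (is.null(secs)) "" else sprintf(" in %.1fs", secs)))
    if (!is.null(log_path))
      cat(jsonlite::toJSON(list(stage = stage, status = status,
                                wall_time_s = secs, seed = cfg$seed,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE, null = "null"),
          "\n", file = log_path, append = TRUE, sep = "")
  }
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      log_line(stage, paste0("failed: ", conditionMessage(e)))
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line(stage, "done", as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  # --- data -----------------------------------------------------------
  truth <- NULL
  modules <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate
    sim_args$enabled <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(cfg$seed, "simulate")
    sc <- do.call(sim_config, sim_args)
    net <- run_stage("simulate", function() {
      n <- simulate_network(sc)
      list(net = n, sim = simulate_expression(n, sc))
    })
    expr <- net$sim$expr
    meta <- net$sim$meta
    truth <- net$sim$truth
    modules <- net$net$modules
    model <- net$net$model
    if (!is.null(dir)) write_simulation(net$sim, file.path(dir, "simulation"))
  } else {
    expr <- NULL
    if (!is.null(cfg$inputs$counts))
      expr <- read_expression_tsv(cfg$inputs$counts, space = "counts")
    else
      expr <- read_expression_tsv(cfg$inputs$expression,
                                  space = "normalized_log")
    meta <- read_metadata_tsv(cfg$inputs$metadata)
    model <- if (!is.null(cfg$inputs$model)) read_model_tsv(cfg$inputs$model)
             else NULL
  }
  annotation <- if (!is.null(cfg$inputs$annotation))
    data.table::fread(cfg$inputs$annotation, data.table = FALSE) else NULL
  gene_sets <- if (!is.null(cfg$inputs$gene_sets))
    read_gmt(cfg$inputs$gene_sets)
  else if (!is.null(modules)) {
    ms <- split(names(modules), modules)
    names(ms) <- paste0("module_", names(ms))
    ms
  } else list()

  # --- preprocessing --------------------------------------------------
  if (isTRUE(cfg$preprocess$enabled)) {
    pp <- cfg$preprocess
    expr <- run_stage("preprocess", function() {
      x <- expr
      if (expr_space(x) == "counts") {
        x <- filter_genes(x, annotation, pp$min_mean_count, pp$allowed_biotypes)
        x <- normalize_and_log(x)
      }
      if (!is.null(pp$covariates))
        x <- regress_out_covariates(x, meta, pp$covariates)
      x
    })
    if (isTRUE(pp$balance)) {
      keep <- balance_age_groups(meta,
                                 exclude_from_min = pp$exclude_from_min,
                                 min_keep_oldest = pp$min_keep_oldest,
                                 n_fixed = pp$n_fixed,
                                 seed = derive_seed(cfg$seed, "balance"))
      expr <- expression_matrix(expr[, keep, drop = FALSE], expr_space(expr))
      meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
    }
  }
  res$expr <- expr
  res$meta <- meta
  res$truth <- truth
  res$modules <- modules

  # --- model ----------------------------------------------------------
  if (isTRUE(cfg$train$enabled)) {
    tr <- cfg$train
    model <- run_stage("train", function() train_network(
      expr, stability_config(
        n_subsamples = tr$n_subsamples,
        subsample_fraction = tr$subsample_fraction,
        selection_threshold = tr$selection_threshold,
        max_predictors = tr$max_predictors,
        max_predictors_per_fit = tr$max_predictors_per_fit,
        seed = derive_seed(cfg$seed, "train"))))
  }
  if (is.null(model))
    stop("stage 'model' failed: no model trained, simulated, or supplied")
  model <- run_stage("network", function() {
    m <- model
    if (isTRUE(cfg$network$prune))
      m <- prune_residual_edges(m, cfg$network$ratio_threshold)
    if (isTRUE(cfg$network$same_arm) && !is.null(annotation))
      m <- remove_same_arm_predictors(m, annotation)
    if (isTRUE(cfg$network$largest_component))
      m <- largest_connected_component(m)
    m
  })
  res$model <- model
  write_stage(model, dir, "model.tsv", write_model_tsv)

  # --- predictability -------------------------------------------------
  pr <- cfg$predictability
  res$threshold <- run_stage("calibrate", function()
    calibrate_predictability_threshold(
      expr, model, quantile = pr$quantile,
      n_randomizations = pr$n_randomizations,
      seed = derive_seed(cfg$seed, "calibrate")))
  recon <- run_stage("reconstruct", function()
    reconstruct_expression(model, expr))
  res$reconstruction <- recon
  ptab <- run_stage("predictability", function()
    predictability_by_group(expr, recon, meta))
  mean_rho <- rowMeans(ptab$rho, na.rm = TRUE)
  keep_genes <- names(mean_rho)[!is.nan(mean_rho) &
                                  mean_rho >= as.numeric(res$threshold)]
  if (!length(keep_genes))
    stop("stage 'predictability' failed: no gene's mean predictability ",
         "clears the calibrated threshold (",
         signif(as.numeric(res$threshold), 3), ")", call. = FALSE)
  ptab_kept <- ptab
  ptab_kept$rho <- ptab$rho[keep_genes, , drop = FALSE]
  res$predictability <- ptab_kept
  res$retained_genes <- keep_genes
  trends <- run_stage("trend", function()
    fit_predictability_slopes(ptab_kept))
  trends_wo <- fit_predictability_slopes(drop_oldest_group(ptab_kept))
  res$trends <- trends
  write_stage(trends, dir, "predictability_trends.tsv",
              function(x, p) data.table::fwrite(x, p, sep = "\t"))
  res$null <- run_stage("null", function()
    permutation_null(ptab_kept, n_perm = pr$n_perm,
                     seed = derive_seed(cfg$seed, "null")))
  hits <- run_stage("hits", function()
    select_top_hits(trends, n_top = pr$n_top,
                    trends_without_oldest = trends_wo,
                    require_consistency = pr$require_consistency))
  res$hits <- hits
  write_stage(hits, dir, "hits.tsv",
              function(x, p) data.table::fwrite(x, p, sep = "\t"))
  if (!is.null(dir))
    write_rnk(setNames(trends$slope, trends$gene),
              file.path(dir, "predictability_slopes.rnk"))

  # --- drivers --------------------------------------------------------
  oldest <- names(ptab$group_ages)[length(ptab$group_ages)]
  res$drivers <- run_stage("drivers", function() {
    es <- expression_slopes(expr, meta)
    es_wo <- expression_slopes(expr, meta, exclude_groups = oldest)
    vs <- variance_slopes(expr, meta)
    vs_wo <- variance_slopes(expr, meta, exclude_groups = oldest)
    classify_hits(hits, es, vs, es_wo, vs_wo, cutoff = cfg$drivers$cutoff)
  })
  write_stage(res$drivers, dir, "drivers.tsv",
              function(x, p) data.table::fwrite(x, p, sep = "\t"))

  # --- coordination ---------------------------------------------------
  if (isTRUE(cfg$coordination$enabled) && nrow(hits)) {
    res$pairs <- run_stage("pairs", function()
      neighbor_correlation_slopes(expr, model, hits$gene, meta))
    res$contributions <- run_stage("contributions", function()
      within_between_contributions(res$pairs, hits, gene_sets))
    res$subnetwork <- run_stage("subnetwork", function()
      extract_hit_subnetwork(model, hits,
                             n_strongest = cfg$coordination$n_strongest))
    write_stage(res$contributions, dir, "contributions.tsv",
                function(x, p) data.table::fwrite(x, p, sep = "\t"))
    if (!is.null(dir)) {
      write_model_tsv(res$subnetwork$edges, file.path(dir, "subnetwork_edges.tsv"))
      data.table::fwrite(res$subnetwork$nodes,
                         file.path(dir, "subnetwork_nodes.tsv"), sep = "\t")
    }
  }

  # --- propagation ----------------------------------------------------
  if (isTRUE(cfg$propagation$enabled)) {
    res$propagated <- run_stage("propagate", function()
      propagate_scores(symmetrize_model(model),
                       setNames(trends$slope, trends$gene),
                       alpha = cfg$propagation$alpha,
                       tol = cfg$propagation$tol,
                       max_iter = cfg$propagation$max_iter))
    if (!is.null(dir))
      data.table::fwrite(data.frame(gene = names(res$propagated),
                                    smoothed_slope = res$propagated),
                         file.path(dir, "propagated_slopes.tsv"), sep = "\t")
  }

  # --- manifest -------------------------------------------------------
  if (!is.null(dir)) {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    files <- files[!basename(files) %in% c("manifest.json", "run.log")]
    manifest <- list(
      seed = cfg$seed,
      config = unclass(cfg),
      outputs = lapply(setNames(files, sub(paste0("^", dir, "/?"), "", files)),
                       function(f) unname(tools::md5sum(f)))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    res$manifest <- manifest
  }
  invisible(res)
}
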