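## End-to-end pipeline orchestration with a single config, derived seeds
## and a content-hash manifest.

#' Default pipeline configuration
#'
#' Nested key-value configuration for [run_pipeline()].  Every stochastic
#' stage derives its seed deterministically from the global seed and the
#' stage name.
#'
#' @param seed Global seed.
#' @param out Output directory.
#' @return List of stage settings (classification K values and threshold,
#'   specificity pseudocount and window, modelling filters, optimiser
#'   budget, AIC formula, ...).
#' @export
pipeline_config <- function(seed = 1, out = tempfile("costim_run_")) {
  list(
    seed = seed, out = out,
    design = list(nacl_times = c(0, 1, 5, 10, 20, 45),
                  phe_times = c(0, 1, 5, 10, 20, 45), n_replicates = 3),
    simulate = list(panel = "modeling", cv = 0.08, tic_spread = 0.1,
                    missing_rate = 0),
    classify = list(k_nacl = 6, k_phe = 8, threshold = 0.7, restarts = 50),
    specificity = list(window = 4, r_min = 0.8),
    cluster = list(k = 7, p = 2, linkage = "complete"),
    filters = list(cv_threshold = 0.25, max_missing = 0.25,
                   ap_damping = 0.9),
    fit = list(enabled = TRUE, variants = c("base", "both_mechanisms"),
               restarts = 2, eval_budget = 400, free = c("tau", "k")),
    hill_n = 4)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> classify -> specificity -> cluster
#' -> filter -> build -> fit -> compare on a configuration, writing every
#' stage output as CSV into the run directory together with a manifest
#' (config digest, stage seeds, file content hashes).  Reruns with the
#' same config reproduce all outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; stage results are also
#'   returned as attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) stage_seed(config$seed, name)
  res <- list()

  ## -- simulate ------------------------------------------------------------
  design <- stim_design(config$design$nacl_times, config$design$phe_times,
                        config$design$n_replicates)
  panel <- switch(config$simulate$panel,
                  modeling = panel_modeling(), effects = panel_effects(),
                  stopf("stage simulate: unknown panel '%s'",
                        config$simulate$panel))
  dataset <- sim_costim(panel, design,
                        noise_model(config$simulate$cv,
                                    config$simulate$tic_spread,
                                    config$simulate$missing_rate),
                        seed = stage("simulate"))
  write_costim_csv(dataset, file.path(config$out, "dataset.csv"))

  ## -- preprocess ----------------------------------------------------------
  dataset <- tic_normalize(dataset)
  kept <- detection_filter(dataset)
  dataset2 <- as_costim_data(
    as.data.frame(dataset)[dataset$ppep_id %in% kept, ], design)
  surface <- impute_spline(average_replicates(dataset2))
  utils::write.csv(data.frame(ppep_id = rownames(surface$mean),
                              surface$mean, check.names = FALSE),
                   file.path(config$out, "surface.csv"), row.names = FALSE)

  ## -- classify ------------------------------------------------------------
  calls <- classify_effects(surface, k_nacl = config$classify$k_nacl,
                            k_phe = config$classify$k_phe,
                            threshold = config$classify$threshold,
                            seed = stage("classify"),
                            restarts = config$classify$restarts)
  utils::write.csv(calls, file.path(config$out, "effect_calls.csv"),
                   row.names = FALSE)

  ## -- specificity ---------------------------------------------------------
  spec_nacl <- specificity_vectors(surface, "NaCl")
  spec_phe <- specificity_vectors(surface, "Phe")
  utils::write.csv(cbind(data.frame(ppep_id = rownames(spec_nacl)),
                         S_NaCl = spec_nacl, S_Phe = spec_phe),
                   file.path(config$out, "specificity_vectors.csv"),
                   row.names = FALSE)

  ## -- cluster -------------------------------------------------------------
  clus <- hier_cluster(surface, p = config$cluster$p,
                       linkage = config$cluster$linkage,
                       k = min(config$cluster$k, nrow(surface$mean)))
  utils::write.csv(data.frame(ppep_id = names(clus), cluster = clus),
                   file.path(config$out, "profile_clusters.csv"),
                   row.names = FALSE)

  ## -- modelling filters and network build ---------------------------------
  training <- select_training_conditions(design)
  keep_cv <- suppressWarnings(
    cv_filter(dataset, config$filters$cv_threshold, conditions = training))
  raw_surface <- average_replicates(dataset)
  keep_miss <- missingness_filter(raw_surface, config$filters$max_missing,
                                  conditions = training)
  survivors <- intersect(keep_cv, keep_miss)
  tcols <- condition_name(training$t_nacl, training$t_phe)
  traj <- impute_spline(raw_surface)$mean[survivors, tcols, drop = FALSE]
  info <- raw_surface$ppep_info
  known <- if (!is.null(panel$known_function))
    panel$known_function[match(survivors, panel$ppep_id)] else
      rep(TRUE, length(survivors))
  merged <- ap_merge(traj, info$protein[match(survivors, info$ppep_id)],
                     known, damping = config$filters$ap_damping)
  reps <- merged$ppep_id[merged$representative]
  utils::write.csv(merged, file.path(config$out, "modeling_set.csv"),
                   row.names = FALSE)

  prior <- costim_prior_network()
  assignment <- data.frame(
    protein = merged$protein[merged$representative],
    ppep_id = reps, stringsAsFactors = FALSE)
  assignment <- assignment[assignment$protein %in% prior$nodes$name, ]
  base <- build_pepnet(prior, assignment)
  write_sif(base, file.path(config$out, "base_model.sif"))
  ensemble <- enumerate_ensemble(base)
  utils::write.csv(
    data.frame(id = vapply(ensemble, `[[`, character(1), "id"),
               nodes = vapply(ensemble, function(m) n_nodes(m$model),
                              integer(1)),
               interactions = vapply(ensemble, function(m)
                 n_interactions(m$model), numeric(1))),
    file.path(config$out, "ensemble.csv"), row.names = FALSE)

  ## -- fit and compare ------------------------------------------------------
  if (isTRUE(config$fit$enabled)) {
    norm_surface <- hill_normalize_surface(
      impute_spline(raw_surface), n = config$hill_n)
    norm_surface$mean <- norm_surface$mean[
      intersect(rownames(norm_surface$mean), base$nodes$name), ,
      drop = FALSE]
    midas <- midas_from_surface(norm_surface,
                                file.path(config$out, "training.midas"))
    models <- list(base = base,
                   both_mechanisms = apply_variant(
                     base, variant_spec(TRUE, TRUE)))
    models <- models[intersect(config$fit$variants, names(models))]
    fits <- lapply(models, function(m)
      fit_logic_ode(m, midas, free = config$fit$free,
                    restarts = config$fit$restarts,
                    eval_budget = config$fit$eval_budget,
                    seed = stage("fit")))
    ranking <- compare_models(fits)
    utils::write.csv(ranking, file.path(config$out, "model_ranking.csv"),
                     row.names = FALSE)
    res$ranking <- ranking
  }

  ## -- manifest -------------------------------------------------------------
  files <- list.files(config$out, full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  manifest <- rbind(manifest,
                    data.frame(file = "<global_seed>", md5 = as.character(config$seed)))
  utils::write.csv(manifest, file.path(config$out, "manifest.csv"),
                   row.names = FALSE)

  res$surface <- surface; res$calls <- calls; res$modeling_set <- reps
  res$base_model <- base; res$n_ensemble <- length(ensemble)
  out <- config$out
  attr(out, "results") <- res
  invisible(out)
}
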