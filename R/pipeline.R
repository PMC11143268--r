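# ---------------------------------------------------------------------------
# Configuration-driven orchestration of the analysis stages, with
# deterministic per-stage seeds derived from one global seed and a manifest
# recording what was produced. Results are CSV/JSON only.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @param n_plots synthetic inventory size.
#' @return nested configuration list (serializable to YAML).
#' @export
default_config <- function(seed = 1, n_plots = 1500) {
  list(
    seed = seed,
    stages = c("generate", "bimodality_null", "demography", "simulate",
               "bimodality_map", "drivers"),
    generator = list(n_plots = n_plots),
    filters = list(min_trees = 10, max_unknown_ba_frac = 0.10,
                   max_mortality_frac = 0.50, min_species = 2,
                   max_single_species_ba_frac = 0.90),
    null_model = list(n_rep = 200, min_trees = 10, df = 4, rho = -1.5),
    demography = list(k = 5, n_draws = 100),
    simulator = list(n_plots = 200, horizon_years = 500, step_years = 5),
    clustering = list(method = "fishing_net", cell_arcmin = 10, min_plots = 10),
    drivers = list(n_boot = 100, frac = 1/3)
  )
}

required_blocks <- c("seed", "stages", "generator", "filters", "null_model",
                     "demography", "simulator", "clustering", "drivers")

#' Validate a pipeline configuration
#'
#' @param config configuration list (or path to a YAML file).
#' @return the validated configuration, invisibly errors listing every
#'   missing block otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  miss <- setdiff(required_blocks, names(config))
  if (length(miss))
    stop("configuration lacks required blocks: ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed)) stop("seed must be numeric")
  bad <- setdiff(config$stages, c("generate", "bimodality_null", "demography",
                                  "simulate", "hysteresis", "bimodality_map",
                                  "drivers"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  invisible(config)
}

stage_seed <- function(seed, stage) {
  offs <- c(generate = 11L, bimodality_null = 23L, demography = 37L,
            simulate = 41L, hysteresis = 53L, bimodality_map = 67L,
            drivers = 79L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the selected stages over a synthetic inventory: data generation,
#' the environmental null-model test, demographic feedback fits and
#' contrasts, a scaled succession simulation (feedback vs null), cluster
#' bimodality mapping and determinant importance. Writes per-stage CSV/JSON
#' outputs plus a manifest; reruns with the same configuration reproduce the
#' same files.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return list of stage results (also serialized under \code{out_dir}).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("phenostate_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  outputs <- character(0)
  emit_csv <- function(x, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(x, path, row.names = FALSE)
    outputs[[name]] <<- path
  }
  st <- function(s) s %in% config$stages

  gp <- do.call(generator_params,
                c(config$generator, list(seed = stage_seed(config$seed, "generate"))))
  env <- generate_environment(gp)
  if (st("generate")) {
    inv <- generate_two_census_inventory(env, gp)
    filt <- do.call(filter_criteria, config$filters)
    kept <- apply_inclusion_filters(inv$trees, inv$plots, filt)
    emit_csv(inv$trees, "trees")
    emit_csv(env, "plots")
    emit_csv(kept$audit, "filter_audit")
    res$generate <- list(n_trees = nrow(inv$trees), n_plots = nrow(env),
                         n_kept = length(kept$kept_ids), audit = kept$audit)
    res$inventory <- inv
  }

  if (st("bimodality_null")) {
    nm <- config$null_model
    gp2 <- gp
    gp2$abundance$rho <- nm$rho
    ab <- generate_abundance_table(env, gp2)
    pcs <- env[, paste0("env_pc", 1:10)]
    fit_ev <- fit_zap(ab$ev_count, pcs, df = nm$df)
    fit_de <- fit_zap(ab$de_count, pcs, df = nm$df)
    seed_nm <- stage_seed(config$seed, "bimodality_null")
    ens <- null_relev_ensemble(fit_ev, fit_de, pcs,
                               observed = ab, n_rep = nm$n_rep,
                               min_trees = nm$min_trees, seed = seed_nm,
                               dip_p_value = TRUE)
    sp <- spearman_coupling_test(ab$ev_count, ab$de_count, fit_ev, fit_de,
                                 pcs, n_rep = nm$n_rep, seed = seed_nm + 1L)
    emit_csv(ens$bins, "null_envelope")
    res$bimodality_null <- list(envelope = ens, spearman = sp)
    jsonlite::write_json(list(rho_obs = sp$rho_obs, p = sp$p,
                              dip = ens$dip,
                              outer_exceedance = ens$outer_exceedance),
                         file.path(out_dir, "bimodality_null.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs[["bimodality_null"]] <- file.path(out_dir, "bimodality_null.json")
  }

  if (st("demography") || st("simulate") || st("hysteresis")) {
    if (is.null(res$inventory)) res$inventory <- generate_two_census_inventory(env, gp)
    inv <- res$inventory
    models_fb <- fit_vital_rates(inv$trees, inv$plots, feedback = TRUE,
                                 k = config$demography$k)
    models_null <- fit_vital_rates(inv$trees, inv$plots, feedback = FALSE,
                                   k = config$demography$k)
    res$models <- list(feedback = models_fb, null = models_null)
  }
  if (st("demography")) {
    sd0 <- stage_seed(config$seed, "demography")
    contr <- rbind(
      predict_survival_growth_contrast(res$models$feedback, "survival",
                                       n_draws = config$demography$n_draws, seed = sd0),
      predict_survival_growth_contrast(res$models$feedback, "growth",
                                       n_draws = config$demography$n_draws, seed = sd0 + 1L))
    ratio <- predict_recruitment_ratio(res$models$feedback,
                                       n_draws = config$demography$n_draws,
                                       seed = sd0 + 2L)
    emit_csv(contr, "feedback_contrasts")
    emit_csv(ratio, "recruitment_ratio")
    res$demography <- list(contrasts = contr, recruitment_ratio = ratio)
  }

  if (st("simulate")) {
    sc <- config$simulator
    finals <- list()
    for (variant in c("feedback", "null")) {
      cfg <- sim_config(n_plots = sc$n_plots, horizon_years = sc$horizon_years,
                        step_years = sc$step_years, init = "uniform",
                        seed = stage_seed(config$seed, "simulate") +
                          (variant == "null"))
      sim <- run_simulation(cfg, res$models[[variant]], env)
      finals[[variant]] <- sim$final_relev
    }
    simtab <- data.frame(variant = rep(names(finals), each = sc$n_plots),
                         final_relev = unlist(finals, use.names = FALSE))
    emit_csv(simtab, "simulation_final_relev")
    res$simulate <- lapply(finals, function(x)
      bimodality_result(x, p_value = TRUE, n_null = 499,
                        seed = stage_seed(config$seed, "simulate") + 2L))
  }

  if (st("bimodality_map")) {
    inv <- res$inventory
    if (is.null(inv)) stop("bimodality_map requires the generate stage")
    s <- plot_summaries(inv$trees)
    cl <- if (config$clustering$method == "fishing_net")
      fishing_net_clusters(env, config$clustering$cell_arcmin,
                           config$clustering$min_plots)
    else kmeans_env_clusters(env, k = config$clustering$k,
                             seed = stage_seed(config$seed, "bimodality_map"),
                             min_plots = config$clustering$min_plots)
    bi <- cluster_bimodality(cl, stats::setNames(s$relev_area, s$plot_id))
    emit_csv(bi, "cluster_bimodality")
    res$bimodality_map <- bi
  }

  if (st("drivers")) {
    detc <- c("det_mat", "det_precip", "det_tcold", "det_pdry",
              "det_soil_ph", "det_soil_n", "det_soil_cn")
    inv <- res$inventory
    if (is.null(inv)) stop("drivers requires the generate stage")
    s <- plot_summaries(inv$trees)
    y <- s$relev_area[match(env$plot_id, s$plot_id)]
    ok <- !is.na(y)
    imp <- permutation_importance(env[ok, detc], y[ok],
                                  n_boot = config$drivers$n_boot,
                                  frac = config$drivers$frac,
                                  seed = stage_seed(config$seed, "drivers"))
    emit_csv(imp, "determinant_importance")
    res$drivers <- imp
  }

  manifest <- list(package_version = as.character(utils::packageVersion("phenostate")),
                   seed = config$seed,
                   stages_run = intersect(config$stages,
                                          c("generate", "bimodality_null", "demography",
                                            "simulate", "bimodality_map", "drivers")),
                   stages_skipped = setdiff(c("generate", "bimodality_null", "demography",
                                              "simulate", "bimodality_map", "drivers"),
                                            config$stages),
                   outputs = as.list(outputs))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
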