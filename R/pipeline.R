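#' Pipeline configuration
#'
#' Collects every tunable setting of the end-to-end analysis in one object;
#' downstream stages read parameters only from here, and a serialized copy is
#' written with the outputs so a run is fully reproducible.
#'
#' @param group_cfg A [group_effect_config()] describing the synthetic study.
#' @param base_scene A [scene_config()] with the shared scene parameters.
#' @param vs A [visual_system()].
#' @param distances_cm Viewing distances analyzed (default `c(2, 30)`).
#' @param t_color,t_lum RNL clustering thresholds in Delta S (defaults 2, 4).
#' @param filter_falloff,filter_radius,filter_repetition Ranked-filter
#'   parameters (defaults 3, 5, 5).
#' @param cor_threshold Correlation-filter cutoff (default 0.6).
#' @param pa_sims Parallel-analysis simulated datasets (default 10000).
#' @param bootstrap_iters EFA bootstrap replicates (default 1000).
#' @param mcmc Profile for the group models: `"desk"` (4 chains x 500
#'   stored post-warmup draws) or `"full"` (4 chains x 2000 = the
#'   conventional 8000 total); or a list with `chains`, `draws_per_chain`,
#'   `thin`, `adapt`, `burn`.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(group_cfg = group_effect_config(),
                            base_scene = scene_config(),
                            vs = visual_system(),
                            distances_cm = c(2, 30),
                            t_color = 2, t_lum = 4,
                            filter_falloff = 3, filter_radius = 5,
                            filter_repetition = 5,
                            cor_threshold = 0.6,
                            pa_sims = 10000,
                            bootstrap_iters = 1000,
                            mcmc = "desk",
                            seed = 1) {
  if (is.character(mcmc))
    mcmc <- switch(match.arg(mcmc, c("desk", "full")),
                   desk = list(chains = 4, draws_per_chain = 500,
                               thin = 16, adapt = 1000, burn = 3000),
                   full = list(chains = 4, draws_per_chain = 2000,
                               thin = 16, adapt = 2000, burn = 4000))
  structure(
    list(group_cfg = group_cfg, base_scene = base_scene, vs = vs,
         distances_cm = distances_cm, t_color = t_color, t_lum = t_lum,
         filter_falloff = filter_falloff, filter_radius = filter_radius,
         filter_repetition = filter_repetition,
         cor_threshold = cor_threshold, pa_sims = pa_sims,
         bootstrap_iters = bootstrap_iters, mcmc = mcmc,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Scene generation, visual modeling at each viewing distance (acuity blur,
#' ranked filter, RNL clustering), pattern statistics, defense scoring,
#' complete-case and correlation filtering, parallel-analysis factor
#' retention, varimax EFA, and one distributional group model per retained
#' factor. Artifacts (stat tables, factor tables, model summaries, manifest)
#' are written under `out_dir` when given; everything is also returned.
#' Re-running with the same configuration reproduces every stochastic stage
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param fit_models Fit the Bayesian group models (default TRUE; switch off
#'   for statistic-level runs).
#' @param progress Print stage progress to stderr.
#' @return List with `study`, `stats`, `defense`, `filtered`, `k`,
#'   `efa`, `scores` (data frame of factor scores + species, group,
#'   distance), `models` (one `posterior_summary` per factor), `exclusions`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, fit_models = TRUE,
                         progress = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message("[rnlscape] ", ...)
  vs <- config$vs

  say("simulating study")
  study <- make_study(config$group_cfg, config$base_scene, vs)

  say("visual modeling + pattern statistics")
  rows <- list()
  for (sp in names(study$scenes)) {
    for (j in seq_along(study$scenes[[sp]])) {
      sc <- study$scenes[[sp]][[j]]
      for (d in config$distances_cm) {
        geom <- viewing_geometry(d, sc$image$px_per_mm)
        blurred <- apply_acuity(sc$image, vs, geom)
        filtered <- rnl_ranked_filter(blurred, vs, config$filter_falloff,
                                      config$filter_radius,
                                      config$filter_repetition)
        clustered <- rnl_cluster(filtered, vs, config$t_color, config$t_lum)
        rows[[length(rows) + 1]] <- compute_pattern_stats(
          clustered, filtered, vs,
          image_id = sprintf("%s_img%02d", sp, j),
          species = sp, distance_cm = d)
      }
    }
  }
  stats <- do.call(rbind, rows)

  say("defense scoring")
  defense <- score_species(study$assays)

  say("filtering statistic table")
  complete <- filter_complete_cases(stats)
  exclusions <- attr(complete, "exclusions")
  filtered_tab <- correlation_filter(complete, config$cor_threshold)
  kept <- attr(filtered_tab, "kept_stats")

  say("parallel analysis")
  xmat <- as.matrix(filtered_tab[, kept, drop = FALSE])
  k <- parallel_analysis(xmat, n_sims = config$pa_sims,
                         seed = spawn_seed(config$seed, 101L))
  k <- max(1L, as.integer(k))
  say("retained factors: ", k)

  say("factor analysis")
  efa <- fit_efa(xmat, k, bootstrap_iters = config$bootstrap_iters,
                 seed = spawn_seed(config$seed, 102L))
  scores <- data.frame(filtered_tab[, c("image_id", "species",
                                        "distance_cm")],
                       efa$scores)
  scores <- merge(scores, defense[, c("species", "analysis_group")],
                  by = "species", sort = FALSE)
  names(scores)[names(scores) == "analysis_group"] <- "group"
  scores$group <- factor(scores$group,
                         levels = c("undefended", "toxic_moderate",
                                    "toxic_high"))

  models <- NULL
  if (fit_models) {
    models <- vector("list", k)
    names(models) <- colnames(efa$scores)
    for (f in seq_len(k)) {
      say("group model for factor ", f)
      d <- data.frame(score = scores[[colnames(efa$scores)[f]]],
                      species = scores$species, group = scores$group,
                      distance_cm = scores$distance_cm)
      models[[f]] <- fit_distributional(
        d, study$tree,
        chains = config$mcmc$chains,
        draws_per_chain = config$mcmc$draws_per_chain,
        thin = config$mcmc$thin,
        adapt = config$mcmc$adapt, burn = config$mcmc$burn,
        seed = spawn_seed(config$seed, 200L + f))
    }
  }

  manifest <- list(
    seed = config$seed,
    n_species = nrow(study$species),
    n_images = sum(lengths(study$scenes)),
    distances_cm = config$distances_cm,
    exclusions = exclusions,
    kept_stats = kept,
    k = k,
    variance_explained = unname(efa$variance_explained)
  )

  res <- list(study = study, stats = stats, defense = defense,
              filtered = filtered_tab, k = k, efa = efa, scores = scores,
              models = models, exclusions = exclusions, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(stats, file.path(out_dir, "pattern_stats.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(defense, file.path(out_dir, "defense_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "factor_scores.csv"),
                     row.names = FALSE)
    ape::write.tree(study$tree, file.path(out_dir, "tree.nwk"))
    summaries <- list(manifest = manifest,
                      loadings = as.data.frame(efa$loadings))
    if (!is.null(efa$bootstrap_ci)) {
      summaries$loading_ci <- list(
        lower = as.data.frame(efa$bootstrap_ci[, , 1]),
        upper = as.data.frame(efa$bootstrap_ci[, , 2]))
    }
    if (!is.null(models))
      summaries$models <- lapply(models, function(m)
        list(cells = m$cells, mean_contrasts = m$mean_contrasts,
             sigma_contrasts = m$sigma_contrasts,
             max_rhat = max(m$diagnostics$rhat),
             converged = m$converged))
    jsonlite::write_json(summaries, file.path(out_dir, "summaries.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    manifest$files <- as.list(tools::md5sum(list.files(out_dir,
                                                       full.names = TRUE)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    res$manifest <- manifest
  }
  res
}
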