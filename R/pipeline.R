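#' Default pipeline configuration
#'
#' A complete, self-contained run configuration for the synthetic
#' end-to-end pipeline: landscape geometry and class proportions, covariate
#' years, one species with a known truth model on derived features, the
#' stratified survey design (40% urban / 40% agricultural / 20% natural,
#' one visit per location), pseudo-absence count, the three model families
#' with their defaults (100 balanced bootstraps for NLDA and GLM, five
#' balanced subsets for the forest), and evaluation settings (threshold
#' 0.5, 2000 stratified bootstrap replicates). All stage seeds derive from
#' the single master `seed`.
#'
#' @param seed master seed.
#' @return nested named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    landscape = list(width = 50L, height = 50L, cell_size = 1,
                     patch_sigma = 3,
                     proportions = list(urban = 0.2,
                                        agricultural_sampled = 0.3,
                                        agricultural_excluded = 0.2,
                                        natural = 0.25, water = 0.05)),
    covariates = list(years = 3L),
    species = list(species_a = list(
      intercept = 0,
      beta = list(NDVI_A1 = 1.5, DLST_A0 = 1.2, POPDEN = -1.0),
      zero_classes = "agricultural_excluded")),
    survey = list(n_traps = 300L,
                  strata = list(urban = 0.4, agricultural_sampled = 0.4,
                                natural = 0.2)),
    prep = list(n_pseudo_absences = "auto"),  # "auto" = 5% of records
    models = list(families = c("nlda", "rf", "glm"),
                  nlda = list(n_submodels = 100L, k_presence = 4L,
                              k_absence = 4L),
                  rf = list(n_subsets = 5L, n_trees = 500L),
                  glm = list(n_submodels = 100L)),
    evaluation = list(threshold = 0.5, n_replicates = 2000L, level = 0.95),
    output = list(write_rasters = TRUE, write_features = FALSE))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' Values present in the file override [default_run_config()]; the config
#' round-trips through the file unchanged.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_run_config()),
                           yaml::read_yaml(path))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

as_named_numeric <- function(x) unlist(x)

#' Run the full synthetic suitability pipeline
#'
#' Stages, in enforced order: generate landscape -> generate covariates ->
#' temporal Fourier features -> per species: simulate survey, reclassify,
#' deduplicate per cell, add pseudo-absences, extract features -> fit the
#' configured model families -> predict suitability maps -> evaluate
#' (sensitivity/specificity with stratified bootstrap CIs, importance
#' tables, Moran's I correlogram of GLM deviance residuals). All artifacts
#' are plain text (ESRI ASCII rasters, CSV tables, a YAML manifest of the
#' config and derived seeds) so reruns under the same config are
#' byte-identical.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing.
#' @param seed optional master-seed override.
#' @return invisible list (class `suit_run`) with the landscape, features,
#'   per-species occurrence tables, fitted ensembles, suitability grids,
#'   accuracy report, importance and correlogram tables.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  master <- config$seed
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  message("[1/5] generating landscape")
  ls_cfg <- config$landscape
  landscape <- generate_landscape(ls_cfg$width, ls_cfg$height,
                                  as_named_numeric(ls_cfg$proportions),
                                  seed = child_seed(master, 1L),
                                  cell_size = ls_cfg$cell_size,
                                  patch_sigma = ls_cfg$patch_sigma)
  message("[2/5] generating covariates")
  covariates <- generate_covariates(landscape, years = config$covariates$years,
                                    seed = child_seed(master, 2L))
  message("[3/5] temporal Fourier features")
  features <- fourier_stack(covariates)

  if (!is.null(out_dir)) {
    write_asc(env_grid(landscape$values, landscape$origin,
                       landscape$cell_size),
              file.path(out_dir, "landcover.asc"))
    writeLines(landscape$levels, file.path(out_dir, "landcover_classes.txt"))
    if (isTRUE(config$output$write_features))
      write_feature_stack(features, file.path(out_dir, "features"))
  }

  families <- config$models$families
  species_out <- list()
  ens_by_species <- list()
  sp_i <- 0L
  for (sp in names(config$species)) {
    sp_i <- sp_i + 1L
    sp_cfg <- config$species[[sp]]
    message("[4/5] species ", sp, ": survey, prep, fit")
    truth <- truth_model(as_named_numeric(sp_cfg$beta),
                         intercept = sp_cfg$intercept,
                         zero_classes = sp_cfg$zero_classes)
    suit_true <- true_suitability(truth, features, landscape)
    survey <- simulate_survey(landscape, n_traps = config$survey$n_traps,
                              strata_props = as_named_numeric(config$survey$strata),
                              seed = child_seed(master, 100L + sp_i),
                              suitability = suit_true)
    pts <- dedup_cells(survey_to_points(survey), landscape)
    n_pa <- config$prep$n_pseudo_absences
    if (identical(n_pa, "auto")) n_pa <- NULL
    pts <- add_pseudo_absences(pts, landscape, n = n_pa,
                               seed = child_seed(master, 200L + sp_i))
    occ <- extract_features(pts, features)

    fits <- list(); grids <- list()
    for (fam in families) {
      mc <- config$models[[fam]]
      fit <- switch(fam,
        nlda = suitability_ensemble(presence ~ ., occ, method = "nlda",
                                    n_submodels = mc$n_submodels,
                                    seed = child_seed(master, 300L + sp_i),
                                    control = mc[setdiff(names(mc),
                                                         "n_submodels")]),
        rf = suitability_ensemble(presence ~ ., occ, method = "rf",
                                  n_submodels = mc$n_subsets,
                                  seed = child_seed(master, 400L + sp_i),
                                  control = mc[setdiff(names(mc),
                                                       "n_subsets")]),
        glm = suitability_ensemble(presence ~ ., occ, method = "glm",
                                   n_submodels = mc$n_submodels,
                                   seed = child_seed(master, 500L + sp_i),
                                   control = mc[setdiff(names(mc),
                                                        "n_submodels")]))
      fits[[fam]] <- fit
      grids[[fam]] <- predict_grid(fit, features)
    }

    corr <- NULL
    if ("glm" %in% families && !is.null(fits$glm$training_xy))
      corr <- moran_correlogram(residuals(fits$glm, type = "deviance"),
                                fits$glm$training_xy)

    if (!is.null(out_dir)) {
      spdir <- file.path(out_dir, sp)
      if (!dir.exists(spdir)) dir.create(spdir)
      write_occurrence_csv(occ, file.path(spdir, "occurrence.csv"))
      utils::write.csv(as.data.frame(survey),
                       file.path(spdir, "survey.csv"), row.names = FALSE)
      if (isTRUE(config$output$write_rasters)) {
        write_asc(suit_true, file.path(spdir, "suitability_true.asc"))
        for (fam in names(grids))
          write_asc(grids[[fam]],
                    file.path(spdir, paste0("suitability_", fam, ".asc")))
      }
      for (fam in names(fits))
        utils::write.csv(as.data.frame(top_importance(importance(fits[[fam]]))),
                         file.path(spdir, paste0("importance_", fam, ".csv")),
                         row.names = FALSE)
      if (!is.null(corr))
        utils::write.csv(corr, file.path(spdir, "correlogram_glm.csv"),
                         row.names = FALSE)
    }
    species_out[[sp]] <- list(truth = truth, suitability_true = suit_true,
                              survey = survey, occurrence = occ,
                              fits = fits, grids = grids,
                              correlogram = corr)
    ens_by_species[[sp]] <- fits
  }

  report <- NULL
  if (length(families)) {
    message("[5/5] evaluation")
    ev <- config$evaluation
    report <- accuracy_report(ens_by_species, threshold = ev$threshold,
                              n_reps = ev$n_replicates, level = ev$level,
                              seed = child_seed(master, 900L))
  }
  if (!is.null(out_dir)) {
    if (!is.null(report))
      utils::write.csv(as.data.frame(report),
                       file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    manifest <- list(package = "suitscape",
                     version = as.character(utils::packageVersion("suitscape")),
                     master_seed = master, config = unclass(config))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out <- list(config = config, landscape = landscape,
              covariates = covariates, features = features,
              species = species_out, accuracy = report)
  class(out) <- c("suit_run", "list")
  invisible(out)
}

#' Pseudo-absence ablation: paired runs with and without pseudo-absences
#'
#' Runs the pipeline twice with identical seeds, differing only in the
#' pseudo-absence count (0 versus `n`), and reports the mean predicted
#' suitability over the excluded (known-unsuitable) land-cover cells for
#' each run and each model family. With the excluded class truly
#' unsuitable, adding pseudo-absences should lower the predicted
#' suitability there — the more realistic prediction.
#'
#' @param config a `run_config`; its excluded class should have zero true
#'   suitability (the default truth model zeroes it).
#' @param n_pseudo_absences count for the "with" run (default: the
#'   config's value, or 5% of records if that is `NULL`).
#' @param families model families to ablate (default `"rf"`).
#' @param seed optional master-seed override.
#' @return list with the paired runs and a data.frame `excluded_means`
#'   (family, mean suitability without/with, difference, n_cells).
#' @export
ablate_pseudo_absences <- function(config = default_run_config(),
                                   n_pseudo_absences = NULL,
                                   families = "rf", seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config$models$families <- families
  cfg_without <- cfg_with <- config
  cfg_without$prep$n_pseudo_absences <- 0L
  if (!is.null(n_pseudo_absences))
    cfg_with$prep$n_pseudo_absences <- n_pseudo_absences
  run_without <- run_pipeline(cfg_without)
  run_with <- run_pipeline(cfg_with)

  mask <- class_mask(run_without$landscape, "agricultural_excluded")
  rows <- list()
  for (sp in names(run_without$species)) for (fam in families) {
    g0 <- run_without$species[[sp]]$grids[[fam]]$values[mask]
    g1 <- run_with$species[[sp]]$grids[[fam]]$values[mask]
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, family = fam,
      mean_without = mean(g0, na.rm = TRUE),
      mean_with = mean(g1, na.rm = TRUE),
      difference = mean(g1, na.rm = TRUE) - mean(g0, na.rm = TRUE),
      n_cells = sum(mask))
  }
  list(without = run_without, with = run_with,
       excluded_means = do.call(rbind, rows))
}
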