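#' Pipeline configuration
#'
#' Collects every setting of the end-to-end synthetic analysis: the scene
#' generator, the zonation thresholds, the sampling grid, the spatial
#' weights, the Moran inference, the scenario and the driver harness.
#' Defaults mirror the package's standard analysis: 30%/10% NDVI cutoffs,
#' a 1-km grid, disturbance weights (0.5, 0.3, 0.2) / (0.3, 0.2, 0.5),
#' fragility ranks 6..1 and the x0.8 / x1.3 / x1.1 policy multipliers.
#'
#' @param seed master seed for every stochastic stage.
#' @param epochs epoch years (one land-use/NDVI epoch each).
#' @param grid_shape,cellsize scene dimensions (cells, metres).
#' @param radial_decay NDVI decay per epoch; the default shrinks over the
#'   epochs so the oasis belt expands through time.
#' @param noise_sd NDVI noise.
#' @param thresholds a [zone_thresholds()].
#' @param grid_size sampling-cell side (metres).
#' @param connectivity patch connectivity (4 or 8).
#' @param weights_scheme,weights_standardization contiguity weights.
#' @param moran_permutations,moran_alpha local Moran inference settings.
#' @param scenario a [scenario_spec()] for the policy run.
#' @param driver_grid hyperparameter grid for [fit_and_validate()].
#' @param driver_n number of driver sample points (capped at the number of
#'   grid cells).
#' @export
pipeline_config <- function(seed = 1L,
                            epochs = c(1990, 2000, 2010, 2020),
                            grid_shape = c(200L, 200L),
                            cellsize = 100,
                            radial_decay = seq(0.026, 0.018,
                                               length.out = length(epochs)),
                            noise_sd = 0.03,
                            thresholds = zone_thresholds(),
                            grid_size = 1000,
                            connectivity = 8L,
                            weights_scheme = "queen",
                            weights_standardization = "row",
                            moran_permutations = 999L,
                            moran_alpha = 0.05,
                            scenario = government_control_scenario(),
                            driver_grid = oasisrisk::driver_grid(),
                            driver_n = NULL) {
  if (length(radial_decay) == 1L)
    radial_decay <- rep(radial_decay, length(epochs))
  if (length(radial_decay) != length(epochs))
    stop("`radial_decay` must have one value per epoch", call. = FALSE)
  structure(
    list(seed = as.integer(seed), epochs = epochs,
         grid_shape = as.integer(grid_shape), cellsize = cellsize,
         radial_decay = radial_decay, noise_sd = noise_sd,
         thresholds = thresholds, grid_size = grid_size,
         connectivity = as.integer(connectivity),
         weights_scheme = weights_scheme,
         weights_standardization = weights_standardization,
         moran_permutations = as.integer(moran_permutations),
         moran_alpha = moran_alpha, scenario = scenario,
         driver_grid = driver_grid, driver_n = driver_n),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic risk-assessment pipeline
#'
#' Generates the synthetic scene, then runs zonation, the landscape risk
#' index, spatial autocorrelation, transition accounting, Markov scenario
#' projection and the driver harness, returning one machine-readable
#' summary. The run is fully deterministic under a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, the summary is written as
#'   `summary.json` plus CSV tables and ASCII-grid rasters.
#' @return a `pipeline_summary` list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_epochs <- length(config$epochs)
  scfg <- synthetic_config(grid_shape = config$grid_shape,
                           cellsize = config$cellsize,
                           seed = config$seed,
                           noise_sd = config$noise_sd,
                           n_epochs = max(2L, n_epochs))

  ndvi <- stage("generate", lapply(seq_len(n_epochs), function(t)
    generate_ndvi(scfg, radial_decay = config$radial_decay[t], epoch = t)))
  landuse <- stage("generate", generate_landuse_series(scfg))[seq_len(n_epochs)]

  zones <- stage("zonation", lapply(ndvi, classify_zones,
                                    thresholds = config$thresholds))
  areas <- t(vapply(zones, zone_areas, numeric(3)))
  rownames(areas) <- config$epochs

  grids <- stage("risk", lapply(landuse, function(lu)
    assess_risk(lu, grid_size = config$grid_size,
                connectivity = config$connectivity,
                class_names = scfg$class_names)))
  grids <- stage("risk", classify_risk_levels(grids))

  W <- stage("moran", build_weights(grids[[n_epochs]],
                                    scheme = config$weights_scheme,
                                    standardization =
                                      config$weights_standardization))
  moran_global <- vapply(grids, function(g) global_moran(g$cells$eri, W),
                         numeric(1))
  lisa <- stage("moran", local_moran(grids[[n_epochs]]$cells$eri, W,
                                     n_permutations =
                                       config$moran_permutations,
                                     alpha = config$moran_alpha,
                                     seed = config$seed))

  trans <- stage("transitions", lapply(seq_len(n_epochs - 1L), function(t)
    cross_tabulate(landuse[[t]], landuse[[t + 1L]],
                   classes = seq_len(scfg$n_classes),
                   class_names = scfg$class_names,
                   interval = config$epochs[t + 0:1])))
  class_areas <- t(vapply(landuse, function(lu) {
    a <- cell_area_km2(lu)
    vapply(seq_len(scfg$n_classes), function(k)
      sum(lu$values == k, na.rm = TRUE) * a, numeric(1))
  }, numeric(scfg$n_classes)))
  dimnames(class_areas) <- list(config$epochs, scfg$class_names)

  P_nat <- stage("markov", estimate_markov(trans[[n_epochs - 1L]]))
  P_gov <- stage("scenario", apply_scenario(P_nat, config$scenario))
  last_areas <- class_areas[n_epochs, ]
  proj <- rbind(natural = project_areas(last_areas, P_nat, 1L),
                government = project_areas(last_areas, P_gov, 1L))

  zc <- stage("transitions", zone_composition(zones[[n_epochs]],
                                              landuse[[n_epochs]],
                                              class_names =
                                                scfg$class_names))

  drivers <- stage("drivers", {
    tab <- generate_drivers(scfg, grids[[n_epochs]], n = config$driver_n)
    tab <- normalize_and_split(tab, seed = config$seed)
    fit_and_validate(tab, grid = config$driver_grid, seed = config$seed)
  })

  summary <- list(
    seed = config$seed,
    epochs = config$epochs,
    zone_areas_km2 = areas,
    zone_percent_change = list(
      oasis = percent_change(areas[1, "oasis"], areas[n_epochs, "oasis"]),
      transition = percent_change(areas[1, "transition"],
                                  areas[n_epochs, "transition"]),
      desert = percent_change(areas[1, "desert"], areas[n_epochs, "desert"])
    ),
    eri = lapply(grids, function(g)
      list(mean = mean(g$cells$eri), min = min(g$cells$eri),
           max = max(g$cells$eri),
           level_share = as.list(prop.table(table(factor(
             g$cells$risk_level, levels = 1:5)))))),
    moran = list(global = stats::setNames(moran_global,
                                          config$epochs),
                 expectation = moran_expectation(nrow(lisa)),
                 clusters = as.list(table(lisa$cluster))),
    class_areas_km2 = class_areas,
    transition_matrices = lapply(trans, unclass),
    markov = list(natural = unclass(P_nat), government = unclass(P_gov)),
    projected_areas_km2 = proj,
    zone_composition_pct = zc,
    drivers = list(best = as.list(drivers$best),
                   r2 = drivers$report$r2,
                   rmse = drivers$report$rmse,
                   rpd = drivers$report$rpd,
                   category = drivers$report$category,
                   importance = drivers$importance),
    settings = list(thresholds = unclass(config$thresholds),
                    grid_size = config$grid_size,
                    connectivity = config$connectivity,
                    weights = paste(config$weights_scheme,
                                    config$weights_standardization),
                    moran_permutations = config$moran_permutations,
                    moran_alpha = config$moran_alpha)
  )
  class(summary) <- "pipeline_summary"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(summary),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(areas, file.path(outdir, "zone_areas.csv"))
    utils::write.csv(class_areas, file.path(outdir, "class_areas.csv"))
    utils::write.csv(cbind(grids[[n_epochs]]$cells,
                           cluster = lisa$cluster),
                     file.path(outdir, "risk_grid.csv"),
                     row.names = FALSE)
    for (t in seq_len(n_epochs)) {
      write_ascii_grid(zones[[t]],
                       file.path(outdir, sprintf("zones_%s.asc",
                                                 config$epochs[t])))
      write_ascii_grid(landuse[[t]],
                       file.path(outdir, sprintf("landuse_%s.asc",
                                                 config$epochs[t])))
    }
  }
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  n <- length(x$epochs)
  cat("<pipeline_summary>\n")
  cat(sprintf("  epochs: %s\n", paste(x$epochs, collapse = ", ")))
  cat(sprintf("  oasis area: %.1f -> %.1f km2 (%+.1f%%)\n",
              x$zone_areas_km2[1, "oasis"], x$zone_areas_km2[n, "oasis"],
              x$zone_percent_change$oasis))
  cat(sprintf("  global Moran I (last epoch): %.3f\n",
              x$moran$global[n]))
  cat(sprintf("  driver model: R2 %.3f, RPD %.2f (%s)\n",
              x$drivers$r2, x$drivers$rpd, x$drivers$category))
  imp <- x$drivers$importance
  top <- imp$predictor[which.max(imp$relative)]
  cat(sprintf("  top driver: %s (relative %.2f)\n", top,
              max(imp$relative)))
  invisible(x)
}
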