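#' Build / validate a pipeline configuration
#'
#' A single configuration object (optionally loaded from YAML) drives
#' [run_pipeline()]. All seeds are explicit; there is no hidden global RNG
#' state between stages.
#'
#' @param workspace directory holding (or receiving) the analysis artifacts.
#' @param config optional YAML path or list; values override the defaults.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(workspace, config = NULL) {
  cfg <- list(
    workspace = workspace,
    cell_size = 60,
    interval_years = 14,
    min_transition_area_ha = 5000,
    cramer_threshold = 0.15,
    n_bins = 256,
    seed = 1L,
    mlp = list(hidden_size = 8, learning_rate = 0.5, momentum = 0.9,
               epochs = 5000, patience = 1000, n_per_class = 300),
    synth = list(grid_size = c(96, 96), seed = 20230207),
    simulate = list(horizon_years = 5, recalc_every = 5),
    assignment = NULL
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- utils::modifyList(cfg, config)
  if (!is.numeric(cfg$cell_size) || cfg$cell_size <= 0)
    stop("invalid config: cell_size must be > 0")
  if (cfg$min_transition_area_ha < 0)
    stop("invalid config: min_transition_area_ha must be >= 0")
  if (cfg$cramer_threshold < 0 || cfg$cramer_threshold > 1)
    stop("invalid config: cramer_threshold must be in [0, 1]")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the analysis pipeline over a workspace
#'
#' Executes the requested stages in their fixed order
#' `synth < crosstab < screen < train < markov < simulate < validate` against
#' a workspace directory. Each stage writes its artifacts plus a provenance
#' sidecar JSON (inputs, parameters, seed, package version). An empty stage
#' set validates the configuration only.
#'
#' Stage prerequisites are files on disk: e.g. `crosstab` needs `map_t0.asc`,
#' `map_t1.asc` and `legend.csv` (written by `synth` or supplied by the
#' user); `train` needs the crosstab stage's transition table.
#'
#' @param config a [pipeline_config()] (or arguments to build one).
#' @param stages character subset of the stage names above.
#' @return Invisibly, a named list of per-stage primary artifacts.
#' @export
run_pipeline <- function(config, stages = character(0)) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  order_all <- c("synth", "crosstab", "screen", "train", "markov",
                 "simulate", "validate")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  ws <- config$workspace
  if (!dir.exists(ws)) dir.create(ws, recursive = TRUE)
  art <- list()
  need <- function(f, stage, producer) {
    p <- file.path(ws, f)
    if (!file.exists(p))
      stop("stage '", stage, "' needs ", f, "; run stage '", producer, "' first")
    p
  }
  sidecar <- function(stage, params, inputs, outputs) {
    jsonlite::write_json(
      list(stage = stage, inputs = inputs, outputs = outputs, params = params,
           seed = config$seed,
           version = as.character(utils::packageVersion("lulcsim"))),
      file.path(ws, paste0(stage, ".provenance.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      synth = {
        scfg <- synthetic_config(grid_size = config$synth$grid_size,
                                 seed = config$synth$seed,
                                 cell_size = config$cell_size)
        land <- synthetic_landscape(scfg)
        write_categorical(land$map_t0, file.path(ws, "map_t0.asc"))
        write_categorical(land$map_t1, file.path(ws, "map_t1.asc"))
        write_legend(land$map_t0$legend, file.path(ws, "legend.csv"))
        dir.create(file.path(ws, "drivers"), showWarnings = FALSE)
        for (d in land$drivers)
          write_driver(d, file.path(ws, "drivers", paste0(d$name, ".asc")),
                       cell_size = config$cell_size)
        # a simple protected-area block in the map's north-west quarter
        nr <- nrow(land$map_t0$values); nc <- ncol(land$map_t0$values)
        cs <- config$cell_size
        poly <- cbind(c(0, nc / 2, nc / 2, 0), c(nr, nr, nr / 2, nr / 2)) * cs
        write_mask(rasterize_mask(poly, land$map_t0, "protected_areas"),
                   file.path(ws, "masks_protected_areas.asc"),
                   cell_size = cs)
        assign_df <- data.frame(
          from = c("forest", "fragmented vegetation", "forest",
                   "pastures and crops"),
          to = c("fragmented vegetation", "pastures and crops",
                 "pastures and crops", "fragmented vegetation"),
          submodel = c("degradation", "substitution", "substitution",
                       "regeneration"))
        utils::write.csv(assign_df, file.path(ws, "assignment.csv"),
                         row.names = FALSE)
        sidecar("synth", list(grid_size = scfg$grid_size, seed = scfg$seed),
                character(0), c("map_t0.asc", "map_t1.asc", "legend.csv"))
        art$synth <- land
      },
      crosstab = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m0 <- read_categorical(need("map_t0.asc", stage, "synth"), leg)
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        ct <- cross_tabulate(m0, m1, interval_years = config$interval_years)
        assignment <- if (!is.null(config$assignment))
          utils::read.csv(config$assignment, stringsAsFactors = FALSE)
        else if (file.exists(file.path(ws, "assignment.csv")))
          utils::read.csv(file.path(ws, "assignment.csv"), stringsAsFactors = FALSE)
        else NULL
        specs <- select_transitions(ct, config$min_transition_area_ha,
                                    assignment = assignment)
        write_transitions(specs, file.path(ws, "transitions.csv"))
        saveRDS_free_write_crosstab(ct, file.path(ws, "crosstab.csv"))
        sidecar("crosstab",
                list(min_area_ha = config$min_transition_area_ha,
                     interval_years = config$interval_years),
                c("map_t0.asc", "map_t1.asc"),
                c("transitions.csv", "crosstab.csv"))
        art$crosstab <- specs
      },
      screen = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        dfiles <- list.files(file.path(ws, "drivers"), "\\.asc$", full.names = TRUE)
        if (!length(dfiles))
          stop("stage 'screen' needs driver rasters under drivers/")
        drivers <- lapply(dfiles, read_driver)
        res <- screen_drivers(drivers, m1, n_bins = config$n_bins,
                              threshold = config$cramer_threshold)
        utils::write.csv(res, file.path(ws, "associations.csv"),
                         row.names = FALSE)
        sidecar("screen", list(n_bins = config$n_bins,
                               threshold = config$cramer_threshold),
                basename(dfiles), "associations.csv")
        art$screen <- res
      },
      train = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m0 <- read_categorical(need("map_t0.asc", stage, "synth"), leg)
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        specs <- utils::read.csv(need("transitions.csv", stage, "crosstab"),
                                 stringsAsFactors = FALSE)
        dfiles <- list.files(file.path(ws, "drivers"), "\\.asc$", full.names = TRUE)
        drivers <- lapply(dfiles, read_driver)
        if (file.exists(file.path(ws, "associations.csv"))) {
          assoc <- utils::read.csv(file.path(ws, "associations.csv"))
          keep <- assoc$driver[assoc$selected]
          drivers <- Filter(function(d) d$name %in% keep, drivers)
        }
        if (!length(drivers)) stop("no drivers passed screening")
        dir.create(file.path(ws, "potentials"), showWarnings = FALSE)
        stats_rows <- list()
        for (sm in unique(stats::na.omit(specs$submodel))) {
          sm_specs <- specs[!is.na(specs$submodel) & specs$submodel == sm, ]
          ts <- sample_training(m0, m1, sm_specs, drivers,
                                n_per_class = config$mlp$n_per_class,
                                seed = config$seed)
          fit <- train_mlp(ts, hidden_size = config$mlp$hidden_size,
                           learning_rate = config$mlp$learning_rate,
                           momentum = config$mlp$momentum,
                           epochs = config$mlp$epochs,
                           patience = config$mlp$patience,
                           seed = config$seed)
          write_mlp(fit$model, file.path(ws, paste0("model_", sm, ".json")))
          for (r in seq_len(nrow(sm_specs))) {
            pot <- predict_potential(fit$model, drivers, sm_specs[r, ], map = m0)
            fn <- paste0(gsub("[^a-z0-9]+", "_",
                              tolower(paste(sm_specs$from[r], sm_specs$to[r]))),
                         ".asc")
            write_ascii_grid(pot$values, file.path(ws, "potentials", fn),
                             cell_size = config$cell_size)
          }
          stats_rows[[sm]] <- cbind(submodel = sm, fit$stats)
        }
        st <- do.call(rbind, stats_rows)
        utils::write.csv(st, file.path(ws, "fit_stats.csv"), row.names = FALSE)
        sidecar("train", config$mlp, "transitions.csv",
                c("fit_stats.csv", "potentials/"))
        art$train <- st
      },
      markov = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m0 <- read_categorical(need("map_t0.asc", stage, "synth"), leg)
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        ct <- cross_tabulate(m0, m1, interval_years = config$interval_years)
        m <- estimate_matrix(ct)
        write_matrix(m, file.path(ws, "markov_matrix.csv"))
        write_matrix(annualize(m), file.path(ws, "markov_matrix_annual.csv"))
        sidecar("markov", list(interval_years = config$interval_years),
                c("map_t0.asc", "map_t1.asc"),
                c("markov_matrix.csv", "markov_matrix_annual.csv"))
        art$markov <- m
      },
      simulate = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        mat <- load_scenario_matrix(need("markov_matrix.csv", stage, "markov"),
                                    leg, config$interval_years)
        pots <- read_potentials(ws, leg)
        if (!length(pots)) stop("stage 'simulate' needs potentials/; run 'train' first")
        spec <- structure(list(name = "trend",
                               horizon_year = config$simulate$horizon_years,
                               matrix = mat, trajectory = NULL,
                               constraints = list(), incentives = list(),
                               forest_classes = grep("forest", leg$name, value = TRUE),
                               annual_steps = TRUE),
                          class = "scenario_spec")
        res <- simulate_scenario(spec, m1, pots, start_year = 0,
                                 output_years = config$simulate$horizon_years,
                                 seed = config$seed,
                                 recalc_every = config$simulate$recalc_every)
        for (yr in names(res$maps))
          write_categorical(res$maps[[yr]],
                            file.path(ws, paste0("simulated_step", yr, ".asc")))
        utils::write.csv(res$ledger, file.path(ws, "allocation_ledger.csv"),
                         row.names = FALSE)
        sidecar("simulate", config$simulate, "markov_matrix.csv",
                "allocation_ledger.csv")
        art$simulate <- res
      },
      validate = {
        leg <- read_legend(need("legend.csv", stage, "synth"))
        m0 <- read_categorical(need("map_t0.asc", stage, "synth"), leg)
        m1 <- read_categorical(need("map_t1.asc", stage, "synth"), leg)
        mat <- load_scenario_matrix(need("markov_matrix.csv", stage, "markov"),
                                    leg, config$interval_years)
        pots <- read_potentials(ws, leg)
        if (!length(pots)) stop("stage 'validate' needs potentials/; run 'train' first")
        spec <- structure(list(name = "trend",
                               horizon_year = config$interval_years,
                               matrix = mat, trajectory = NULL,
                               constraints = list(), incentives = list(),
                               forest_classes = grep("forest", leg$name, value = TRUE),
                               annual_steps = TRUE),
                          class = "scenario_spec")
        res <- simulate_scenario(spec, m0, pots, start_year = 0,
                                 output_years = config$interval_years,
                                 seed = config$seed, recalc_every = 0)
        sim <- res$maps[[as.character(config$interval_years)]]
        rep <- validation_report(m1, sim)
        write_validation_report(rep, file.path(ws, "validation_report.csv"))
        sidecar("validate", list(interval_years = config$interval_years),
                c("map_t0.asc", "map_t1.asc", "markov_matrix.csv"),
                "validation_report.csv")
        art$validate <- rep
      })
    message(sprintf("[lulcsim] stage %-9s done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(art)
}

# potentials/ files are named from the "<from>_<to>.asc" slug written by the
# train stage; recover the "from -> to" keys by matching legend names.
read_potentials <- function(ws, legend) {
  pfiles <- list.files(file.path(ws, "potentials"), "\\.asc$", full.names = TRUE)
  pots <- list()
  slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  for (f in pfiles) {
    base <- tools::file_path_sans_ext(basename(f))
    hit <- FALSE
    for (fr in legend$name) for (to in legend$name) {
      if (base == paste(slug(fr), slug(to), sep = "_")) {
        pots[[transition_key(fr, to)]] <- read_ascii_grid(f)$values
        hit <- TRUE
      }
    }
    if (!hit) warning("unrecognized potential file: ", basename(f))
  }
  pots
}

# crosstab as plain CSV (counts with class row/col names)
saveRDS_free_write_crosstab <- function(ct, path) {
  df <- data.frame(class = rownames(ct$counts), ct$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
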