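# End-to-end pipeline: simulate -> consensus -> shape-combine ->
# intersect -> interactions -> flip/trajectory, with TSV/JSON reports.

configError <- function(msg) {
  stop(structure(class = c("apoescreen_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stageError <- function(stage, parent) {
  stop(structure(class = c("apoescreen_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(parent)),
                      call = NULL, stage = stage)))
}

#' Default pipeline configuration
#'
#' Thresholds follow the screening campaign's conventions: activity
#' cutoff Kd < 30 micromolar, top-25 hit lists per branch, 45-degree flip
#' threshold, 3.5 / 5.5 / 4.5 Angstrom detector cutoffs, Spearman
#' correlation with bound-substitution for censored Kd.
#'
#' @param seed integer seed for the simulated stages
#' @return named list of configuration values
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    screen = list(nDecoys = 990, nActives = 10, holoCoupling = 0.9,
                  freeCoupling = -0.9),
    kd_activity_cutoff_um = 30,
    top_n = 25,
    flip_threshold_deg = 45,
    hbond_dmax_A = 3.5,
    pistack_dmax_A = 5.5,
    pocket_cutoff_A = 4.5,
    correlation_method = "spearman",
    kd_policy = "substitute",
    structure_categories = NULL,
    trajectory = list(nFrames = 1000, frameIntervalNs = 0.1,
                      pStay = 0.95, stationaryFlipIn = 0.8))
}

validatePipelineConfig <- function(config) {
  base <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    configError(sprintf("unknown config field(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  config <- modifyList(base, config)
  if (!config$correlation_method %in% c("spearman", "pearson", "kendall")) {
    configError(sprintf("unknown correlation_method '%s'",
                        config$correlation_method))
  }
  if (!config$kd_policy %in% c("substitute", "drop", "midpoint")) {
    configError(sprintf("unknown kd_policy '%s'", config$kd_policy))
  }
  for (f in c("kd_activity_cutoff_um", "top_n", "flip_threshold_deg",
              "hbond_dmax_A", "pistack_dmax_A", "pocket_cutoff_A")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        config[[f]] <= 0) {
      configError(sprintf("config field '%s' must be a positive number", f))
    }
  }
  if (!is.null(config$structure_categories)) {
    sc <- unlist(config$structure_categories)
    badId <- setdiff(names(sc), SYNTH_STRUCTURES)
    if (length(badId)) {
      configError(sprintf("unknown structure id in category map: %s",
                          paste(badId, collapse = ", ")))
    }
    badCat <- setdiff(unique(sc), STRUCTURE_CATEGORIES)
    if (length(badCat)) {
      configError(sprintf("unknown structure category: %s",
                          paste(badCat, collapse = ", ")))
    }
    full <- SYNTH_CATEGORIES
    full[names(sc)] <- sc
    config$structure_categories <- full
  }
  config
}

#' Run the full screening-analytics pipeline on synthetic data
#'
#' Executes the stages in dependency order: structure triage, simulated
#' screen generation, consensus ranking with Kd diagnostics and
#' enrichment, shape-score combination, hit-list intersection, pose
#' interaction checklist, and flip-trajectory analytics.  Identical
#' config and seed give byte-identical outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   path to a YAML file with the same fields; missing fields take their
#'   defaults
#' @param outDir optional directory for TSV/JSON stage outputs; created
#'   if needed.  `NULL` skips file output.
#' @return run report list: per-stage results, the echoed config and
#'   elapsed wall time
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      configError(sprintf("config file '%s' does not exist", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) configError("config must be a list or a YAML path")
  config <- validatePipelineConfig(config)
  t0 <- Sys.time()
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  report <- list(config = config, stages = list())
  runStage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      if (inherits(e, "apoescreen_config_error")) stop(e)
      stageError(name, e)
    })
    report$stages[[name]] <<- res
    res
  }

  triage <- runStage("triage", function() {
    triageStructures(genStructureMetadata())
  })

  screen <- runStage("simulate", function() {
    genScreen(screenSpec(
      nDecoys = config$screen$nDecoys, nActives = config$screen$nActives,
      holoCoupling = config$screen$holoCoupling,
      freeCoupling = config$screen$freeCoupling,
      seed = config$seed))
  })

  consensus <- runStage("consensus", function() {
    sm <- screen$scores
    if (!is.null(config$structure_categories)) {
      sm <- ScoreMatrix(scoreValues(sm),
                        categories = config$structure_categories,
                        valueKind = valueKind(sm))
    }
    tab <- buildConsensusTable(sm)
    diag_ <- correlationDiagnostics(sm, screen$kd,
                                    method = config$correlation_method,
                                    kdPolicy = config$kd_policy)
    actives <- names(screen$active)[screen$active]
    enr <- enrichment(tab, actives, topFraction = 0.02)
    if (!is.null(outDir)) {
      write.table(tab, file.path(outDir, "consensus.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(per_structure = as.list(diag_$per_structure),
             consensus = diag_$consensus, method = diag_$method,
             kd_policy = diag_$kd_policy, n_used = diag_$n_used,
             enrichment = enr),
        file.path(outDir, "diagnostics.json"), auto_unbox = TRUE,
        digits = NA)
    }
    list(table = tab, diagnostics = diag_, enrichment = enr)
  })

  shape <- runStage("shape-combine", function() {
    # two shape queries emulated from the latent activity: similarity to
    # an active query tracks activity with independent noise
    withSeed(config$seed + 1L, {
      z <- screen$activity
      tables <- lapply(1:2, function(q) {
        data.frame(ligand_id = names(z),
                   score = pmax(0, pmin(2, 1 + 0.35 * z +
                                            rnorm(length(z), 0, 0.25))),
                   stringsAsFactors = FALSE)
      })
      names(tables) <- c("query1", "query2")
      combineShapeQueries(tables)
    })
  })

  common <- runStage("intersect", function() {
    consTab <- consensus$table
    dockList <- consTab$ligand_id[order(consTab$consensus_rank)]
    out <- intersectHitLists(dockList, shape, n = config$top_n)
    if (!is.null(outDir)) {
      write.table(out, file.path(outDir, "common_hits.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })

  interactions <- runStage("interactions", function() {
    pose <- buildPoseComplex(poseSpec(
      hbondRequests = list(c("ASP35", 2.9), c("ASP153", 3.0)),
      occupancyRequest = 3, seed = config$seed))
    flip <- classifyFlip(protein(pose), 34, axis = c(0, 0, 1),
                         threshold = config$flip_threshold_deg)
    chk <- buildChecklist(pose, flip, dMaxHBond = config$hbond_dmax_A,
                          pocketCutoff = config$pocket_cutoff_A)
    if (!is.null(outDir)) {
      write.table(chk, file.path(outDir, "checklist.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    chk
  })

  traj <- runStage("trajectory", function() {
    tr <- genFlipTrajectory(trajectorySpec(
      nFrames = config$trajectory$nFrames,
      frameIntervalNs = config$trajectory$frameIntervalNs,
      pStay = config$trajectory$pStay,
      stationaryFlipIn = config$trajectory$stationaryFlipIn,
      seed = config$seed + 2L), includeCoords = FALSE)
    ff <- flipFraction(tr$series)
    if (!is.null(outDir)) {
      write.table(tr$series, file.path(outDir, "dihedral_series.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(series = tr$series, flip_in_fraction = ff)
  })

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$stage_names <- names(report$stages)
  if (!is.null(outDir)) {
    jsonlite::write_json(
      list(stages = report$stage_names, seed = config$seed,
           wall_time_s = report$wall_time_s,
           config = config),
      file.path(outDir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
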