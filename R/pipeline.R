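## Run configuration and end-to-end orchestration. All stages communicate
## through TSV files in the output directory, so any stage can be re-run in
## isolation and a fixed seed reproduces every file bit-identically.

.defaultConfig <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    simulation = list(
      n_rois = 70L, network_sizes = rep(10L, 7L), n_frames = 150L,
      n_subjects = 20L, w_base = 0.45, b_base = 0.20, subject_sd = 0.02,
      ar_phi_baseline = 0.30, states = "default"),
    external = NULL,                 # list(manifest=, partition=) alternative
    metrics = list(window_width = 5L, n_null = 100L, pooling = "block",
                   fdr_family = "metric_level"))
}

.mergeConfig <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (!key %in% names(defaults) && !key %in% c("seed", "output_dir",
                                                 "external"))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- .mergeConfig(user[[key]], defaults[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML run configuration, fills defaults, and fails hard on unknown
#' keys, bad types, or a missing seed when simulation is requested. The
#' `simulation` block accepts the fields of [simulationConfig()] in
#' snake_case, with `states: default` standing for [defaultStates()];
#' alternatively an `external` block (`manifest`, `partition` file paths)
#' points at precomputed data.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return resolved configuration list (with `$simConfig` attached when
#'   simulation is requested).
#' @export
validateConfig <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  cfg <- .mergeConfig(user, .defaultConfig())
  if (is.null(cfg$external)) {
    if (is.null(cfg$seed))
      stop("configuration key 'seed' is required when simulation is requested")
    sim <- cfg$simulation
    states <- if (identical(sim$states, "default")) defaultStates()
              else do.call(rbind, lapply(sim$states, as.data.frame))
    need <- c("state", "class", "deltaWithin", "deltaBetween", "arPhi",
              "noiseScale")
    missingCols <- setdiff(need, names(states))
    if ("noiseScale" %in% missingCols) states$noiseScale <- 0
    if (length(setdiff(missingCols, "noiseScale")))
      stop("simulation.states entries need fields: ",
           paste(setdiff(need, "noiseScale"), collapse = ", "))
    cfg$simConfig <- simulationConfig(
      nRois = sim$n_rois, networkSizes = sim$network_sizes,
      nFrames = sim$n_frames, nSubjects = sim$n_subjects,
      wBase = sim$w_base, bBase = sim$b_base, subjectSd = sim$subject_sd,
      arPhiBaseline = sim$ar_phi_baseline, states = states,
      seed = .stageSeed(cfg$seed, "simulate"))
  } else {
    for (f in c("manifest", "partition"))
      if (is.null(cfg$external[[f]]) || !file.exists(cfg$external[[f]]))
        stop("external.", f, " must name an existing file")
    if (is.null(cfg$seed))
      stop("configuration key 'seed' is required (efficiency nulls are ",
           "stochastic)")
  }
  if (!cfg$metrics$pooling %in% c("block", "pairs"))
    stop("metrics.pooling must be 'block' or 'pairs'")
  if (!cfg$metrics$fdr_family %in% c("metric_level", "metric", "all", "none"))
    stop("metrics.fdr_family must be one of metric_level/metric/all/none")
  cfg
}

## one RNG stream per stage, derived from the master seed by a stable label
## so adding a stage never perturbs another stage's draws
.stageSeed <- function(seed, stage) {
  offs <- c(simulate = 101L, fc = 211L, efficiency = 307L, complexity = 401L,
            effects = 503L, rank = 601L, pca = 701L)
  as.integer(seed) * 1009L + offs[[stage]]
}

.pipelineStages <- c("simulate", "fc", "efficiency", "complexity", "effects",
                     "rank", "pca")

.writeTsv <- function(d, path)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the stage sequence simulate -> fc -> efficiency -> complexity ->
#' effects -> rank -> pca, each stage reading its inputs from, and writing
#' its outputs to, TSV files under `outDir` so that stages are individually
#' re-runnable. Outputs: `cohort/` (series, manifest, partition),
#' `metrics_fc.tsv`, `metrics_eff.tsv`, `metrics_cplx.tsv`, `effects.tsv`,
#' `composite_rank.tsv`, `rank_agreement.tsv`, `pca_scores.tsv`,
#' `pca_loadings_<metric>.tsv`, and `run_info.yaml` (resolved config, seed,
#' package version, per-stage timing).
#'
#' @param config path to a YAML configuration, or the list returned by
#'   [validateConfig()].
#' @param outDir output directory; defaults to the config's `output_dir`.
#' @param stages subset of the stage names to run (default: all).
#' @param verbose log stage progress and timing.
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL,
                        stages = .pipelineStages, verbose = FALSE) {
  resolved <- is.list(config) &&
    (!is.null(config$simConfig) || !is.null(config$external))
  cfg <- if (resolved) config else validateConfig(config)
  stages <- match.arg(stages, .pipelineStages, several.ok = TRUE)
  outDir <- outDir %||% cfg$output_dir %||%
    stop("no output directory (outDir argument or output_dir key)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohortDir <- file.path(outDir, "cohort")
  timing <- list()
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S"),
                                            " [", ..., "]")
  tick <- function(stage, expr) {
    say(stage)
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  if ("simulate" %in% stages) tick("simulate", {
    if (is.null(cfg$simConfig))
      stop("stage 'simulate' requested but the configuration is external")
    writeCohort(simulateCohort(cfg$simConfig), cohortDir)
  })

  loadCohort <- function() {
    if (!is.null(cfg$external))
      readCohort(dirname(cfg$external$manifest))
    else if (file.exists(file.path(cohortDir, "manifest.tsv")))
      readCohort(cohortDir)
    else stop("no cohort found; run the simulate stage first ",
              "(missing ", file.path(cohortDir, "manifest.tsv"), ")")
  }
  cohort <- NULL
  needCohort <- function() {
    if (is.null(cohort)) cohort <<- loadCohort()
    cohort
  }

  metricStage <- function(stage, metric, file) {
    tick(stage, {
      co <- needCohort()
      set.seed(.stageSeed(cfg$seed, stage))
      .writeTsv(cohortMetrics(co, metrics = metric,
                              width = cfg$metrics$window_width,
                              nNull = cfg$metrics$n_null,
                              pooling = cfg$metrics$pooling,
                              verbose = verbose),
                file.path(outDir, file))
    })
  }
  if ("fc" %in% stages) metricStage("fc", "FC", "metrics_fc.tsv")
  if ("efficiency" %in% stages)
    metricStage("efficiency", "EFF", "metrics_eff.tsv")
  if ("complexity" %in% stages)
    metricStage("complexity", "CPLX", "metrics_cplx.tsv")

  if ("effects" %in% stages) tick("effects", {
    files <- file.path(outDir, c("metrics_fc.tsv", "metrics_eff.tsv",
                                 "metrics_cplx.tsv"))
    have <- files[file.exists(files)]
    if (!length(have)) stop("no metrics_*.tsv found; run the metric stages")
    long <- do.call(rbind, lapply(have, read.delim,
                                  stringsAsFactors = FALSE))
    .writeTsv(buildEffectTable(long, fdrFamily = cfg$metrics$fdr_family),
              file.path(outDir, "effects.tsv"))
  })

  readEffects <- function() {
    f <- file.path(outDir, "effects.tsv")
    if (!file.exists(f)) stop("effects.tsv missing; run the effects stage")
    read.delim(f, stringsAsFactors = FALSE)
  }

  if ("rank" %in% stages) tick("rank", {
    eff <- readEffects()
    rt <- rankStates(eff)
    comp <- compositeRank(rt)
    cls <- unique(eff[c("state", "class")])
    comp$class <- cls$class[match(comp$state, cls$state)]
    .writeTsv(comp[c("state", "class", "meanRank")],
              file.path(outDir, "composite_rank.tsv"))
    .writeTsv(rankAgreement(rt, comp),
              file.path(outDir, "rank_agreement.tsv"))
  })

  if ("pca" %in% stages) tick("pca", {
    eff <- readEffects()
    pca <- pcaUncentered(buildFeatureMatrix(eff))
    sc <- data.frame(state = rownames(pca@scores),
                     PC1 = pca@scores[, 1L], PC2 = pca@scores[, 2L],
                     varExplained1 = pca@varExplained[1L],
                     varExplained2 = pca@varExplained[2L])
    cls <- unique(eff[c("state", "class")])
    sc$class <- cls$class[match(sc$state, cls$state)]
    .writeTsv(sc[c("state", "class", "PC1", "PC2", "varExplained1",
                   "varExplained2")], file.path(outDir, "pca_scores.tsv"))
    lm <- pc1LoadingMatrices(pca)
    for (m in names(lm))
      .writeTsv(cbind(network = rownames(lm[[m]]),
                      as.data.frame(lm[[m]])),
                file.path(outDir, paste0("pca_loadings_", m, ".tsv")))
  })

  info <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("BrainStates")),
               r_version = R.version.string,
               finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
               stages = stages, timing_seconds = timing,
               config = cfg[setdiff(names(cfg), "simConfig")])
  yaml::write_yaml(info, file.path(outDir, "run_info.yaml"))
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
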