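#' @include trait-space.R kde.R transgression.R hybrid-null.R synthetic-data.R learning-metrics.R
NULL

#' Build a full-analysis configuration
#'
#' Collects every knob of [runFullAnalysis()] with the study defaults:
#' contour level 0.95, 35 simulated hybrids per replicate for the brain
#' morphospace and 25 for the cognitive space, 100 replicate null
#' populations, sexes pooled for brain traits, females only for cognition.
#'
#' @param space which trait space(s) to analyse: "brain", "cognition" or
#'   "both".
#' @param traitTable path to a trait-table CSV (brain space input).
#' @param trialLog path to a trial-log CSV (cognitive space input).
#' @param syntheticMorph optional [morphGenConfig()] used instead of
#'   `traitTable`.
#' @param syntheticTrials optional [trialGenConfig()] used instead of
#'   `trialLog`.
#' @param level contour level for all KDE regions.
#' @param gridPoints per-axis grid resolution (NULL = 151 for d <= 2, 101
#'   for d = 3).
#' @param nSimBrain,nSimCognition simulated hybrids per replicate.
#' @param reps replicate null populations.
#' @param seed integer master seed (echoed in the report).
#' @param cognitionSexes which sexes enter the cognitive space (default "F",
#'   as only females could be scored for both tasks at study scale).
#' @return Validated config (list of class "AnalysisConfig").
#' @export
analysisConfig <- function(space = c("both", "brain", "cognition"),
                           traitTable = NULL, trialLog = NULL,
                           syntheticMorph = NULL, syntheticTrials = NULL,
                           level = 0.95, gridPoints = NULL,
                           nSimBrain = 35, nSimCognition = 25,
                           reps = 100, seed = 1,
                           cognitionSexes = "F") {
  space <- match.arg(space)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (reps < 1) stop("reps must be >= 1")
  cfg <- list(space = space, traitTable = traitTable, trialLog = trialLog,
              syntheticMorph = syntheticMorph,
              syntheticTrials = syntheticTrials,
              level = level, gridPoints = gridPoints,
              nSimBrain = nSimBrain, nSimCognition = nSimCognition,
              reps = as.integer(reps), seed = as.integer(seed),
              cognitionSexes = cognitionSexes)
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from JSON or YAML
#'
#' @param path config file; `.json` is parsed with jsonlite, `.yml`/`.yaml`
#'   with the yaml package (Suggests).
#' @return An [analysisConfig()] built from the file's fields.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysisConfig))
  do.call(analysisConfig, raw[intersect(names(raw), known)])
}

# Dispersion / transgression / geometry statistics for one trait space.
.analyzeSpace <- function(space, level, nSim, reps, seed, gridPoints) {
  labs <- groupLabels(space)
  if (!all(c("P1", "P2") %in% labs))
    stop("trait space must contain both parental groups")
  p1 <- traitValues(space)[labs == "P1", , drop = FALSE]
  p2 <- traitValues(space)[labs == "P2", , drop = FALSE]
  kdeP1 <- fitKde(p1, level = level, gridPoints = gridPoints)
  kdeP2 <- fitKde(p2, level = level, gridPoints = gridPoints)
  ens <- buildEnsemble(p1, p2, nSim = nSim, reps = reps, seed = seed,
                       level = level, gridPoints = gridPoints)
  est <- ensembleStats(ens)
  out <- list(
    d = nTraits(space),
    traits = traitNames(space),
    n = as.list(table(labs)),
    parental_hypervolumes = list(P1 = hypervolume(kdeP1),
                                 P2 = hypervolume(kdeP2)),
    simulated_hybrids = list(nSim = nSim, reps = reps, seed = seed),
    groups = list())
  for (g in intersect(.hybridGroups(), unique(labs))) {
    hyb <- traitValues(space)[labs == g, , drop = FALSE]
    kdeH <- fitKde(hyb, level = level, gridPoints = gridPoints)
    tr <- classifyTransgressive(hyb, kdeP1, kdeP2, group = g)
    geo <- hybridGeometry(colMeans(hyb), colMeans(p1), colMeans(p2))
    hv <- hypervolume(kdeH)
    out$groups[[g]] <- list(
      n = nrow(hyb),
      hypervolume = hv,
      hypervolume_percentile = percentileOf(hv, est$hypervolume),
      transgression = list(n = tr@n, n_transgressive = tr@nTransgressive,
                           proportion = tr@proportion),
      parental_bias = geo@parentalBias,
      bias_direction = geo@biasDirection,
      bias_percentile = percentileOf(geo@parentalBias, est$parental_bias),
      phenotypic_mismatch = geo@phenotypicMismatch,
      mismatch_percentile = percentileOf(geo@phenotypicMismatch,
                                         est$phenotypic_mismatch),
      flags = transgressionFlags(tr))
  }
  list(summary = out, ensemble = ens, kdeP1 = kdeP1, kdeP2 = kdeP2)
}

#' Run the full variation-and-transgression analysis
#'
#' Orchestrates the complete pipeline: builds the requested trait space(s)
#' from files or synthetic configs, fits parental and hybrid 95% KDE
#' regions, measures dispersion hypervolumes, classifies transgressive
#' individuals, builds the midparent-resampled null ensemble, ranks each
#' hybrid group's dispersion / bias / mismatch within the null, and (for
#' cognition) scores the trial log into learning outcomes and success-rate
#' tables. When `outDir` is given, writes `report.json` plus tidy CSV tables
#' (transgression flags, ensemble statistics, learning outcomes,
#' exclusions). All seeds are echoed in the report and reruns with the same
#' config are identical.
#'
#' @param config an [analysisConfig()].
#' @param outDir optional output directory (created if absent).
#' @return The report (nested list), invisibly when written to disk.
#' @export
runFullAnalysis <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  report <- list(config = config[setdiff(names(config),
                                         c("syntheticMorph",
                                           "syntheticTrials"))],
                 seed = config$seed)
  outputs <- list()

  if (config$space %in% c("brain", "both")) {
    records <- if (!is.null(config$syntheticMorph)) {
      generateMorphometricCohort(config$syntheticMorph)
    } else if (!is.null(config$traitTable)) {
      readTraitTable(config$traitTable)
    } else stop("brain analysis requested but no trait input configured")
    space <- buildBrainMorphospace(records)
    res <- .analyzeSpace(space, config$level, config$nSimBrain,
                         config$reps, config$seed, config$gridPoints)
    report$brain <- res$summary
    report$brain$exclusions <- exclusionReport(space)
    outputs$brain <- res
  }

  if (config$space %in% c("cognition", "both")) {
    trials <- if (!is.null(config$syntheticTrials)) {
      generateTrialLog(config$syntheticTrials)
    } else if (!is.null(config$trialLog)) {
      readTrialLog(config$trialLog)
    } else stop("cognition analysis requested but no trial input configured")
    outcomes <- scoreTrialLog(trials)
    rates <- successRates(outcomes)
    keep <- if ("sex" %in% names(outcomes))
      outcomes$sex %in% config$cognitionSexes | is.na(outcomes$sex)
    else rep(TRUE, nrow(outcomes))
    space <- buildCognitiveSpace(outcomes[keep, ])
    res <- .analyzeSpace(space, config$level, config$nSimCognition,
                         config$reps, config$seed, config$gridPoints)
    report$cognition <- res$summary
    report$cognition$success_rates <- rates
    report$cognition$exclusions <- exclusionReport(space)
    outputs$cognition <- res
    outputs$outcomes <- outcomes
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReport(report, file.path(outDir, "report.json"))
    for (sp in intersect(c("brain", "cognition"), names(outputs))) {
      ens <- outputs[[sp]]$ensemble
      utils::write.csv(ensembleStats(ens),
                       file.path(outDir, paste0(sp, "_ensemble.csv")),
                       row.names = FALSE)
      for (g in names(report[[sp]]$groups)) {
        utils::write.csv(report[[sp]]$groups[[g]]$flags,
                         file.path(outDir,
                                   paste0(sp, "_transgression_", g, ".csv")),
                         row.names = FALSE)
      }
      ex <- report[[sp]]$exclusions
      if (!is.null(ex) && nrow(ex))
        utils::write.csv(ex, file.path(outDir, paste0(sp, "_exclusions.csv")),
                         row.names = FALSE)
    }
    if (!is.null(outputs$outcomes))
      utils::write.csv(outputs$outcomes,
                       file.path(outDir, "learning_outcomes.csv"),
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Write an analysis report to JSON
#'
#' @param report report list from [runFullAnalysis()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path) {
  # strip bulky per-individual flag tables into counts-only JSON
  slim <- report
  for (sp in intersect(c("brain", "cognition"), names(slim))) {
    for (g in names(slim[[sp]]$groups))
      slim[[sp]]$groups[[g]]$flags <- NULL
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  invisible(path)
}
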