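CONFIG_SECTIONS <- c("simulation", "caller", "neoantigen", "paths",
                     "seed", "log_level")

#' Build / read a pipeline configuration
#'
#' A pipeline configuration couples the simulation, caller and neoantigen
#' parameter objects with output paths, a seed and a log level. Unknown
#' keys are rejected, never ignored. `readPipelineConfig` loads the same
#' structure from a flat YAML file whose sections hold the constructor
#' arguments of [SimulationParams], [CallerParams] and
#' [NeoantigenParams].
#'
#' @param simulation a [SimulationParams-class] object.
#' @param caller a [CallerParams-class] object.
#' @param neoantigen a [NeoantigenParams-class] object.
#' @param paths list with at least `outputDir`.
#' @param seed integer seed (overrides the simulation seed).
#' @param logLevel one of `debug`, `info`, `warn`, `quiet`.
#' @return a `PipelineConfig` list object.
#' @export
pipelineConfig <- function(simulation = SimulationParams(),
                           caller = CallerParams(),
                           neoantigen = NeoantigenParams(),
                           paths = list(outputDir = tempfile("neoprofiler")),
                           seed = 1L, logLevel = "info") {
  stopifnot(is(simulation, "SimulationParams"), is(caller, "CallerParams"),
            is(neoantigen, "NeoantigenParams"))
  validObject(simulation); validObject(caller); validObject(neoantigen)
  if (is.null(paths$outputDir))
    stop("paths$outputDir is required", call. = FALSE)
  if (!logLevel %in% c("debug", "info", "warn", "quiet"))
    stop("unknown log level: ", logLevel, call. = FALSE)
  cfg <- list(simulation = simulation, caller = caller,
              neoantigen = neoantigen, paths = paths,
              seed = as.integer(seed), log_level = logLevel)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML configuration file.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  pipelineConfig(
    simulation = build(SimulationParams, raw$simulation),
    caller = build(CallerParams, raw$caller),
    neoantigen = build(NeoantigenParams, raw$neoantigen),
    paths = raw$paths %||% list(outputDir = tempfile("neoprofiler")),
    seed = raw$seed %||% 1L,
    logLevel = raw$log_level %||% "info")
}

#' Run the full neoantigen-profiling pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort:
#' simulate (reference panel + cohort, both derived from the seed), call
#' somatic variants per patient, classify them, compute each patient's
#' neoantigen load, assemble cohort profiles, and compute the cohort
#' statistics report. All stage outputs are written under
#' `paths$outputDir` with fixed float formatting, so an identical
#' configuration and seed reproduce byte-identical tables; a JSON run
#' manifest records the package version, seed, configuration hash, input
#' checksums and timestamp.
#'
#' @param config a `PipelineConfig` from [pipelineConfig] /
#'   [readPipelineConfig].
#' @param reference optional pre-built reference panel (default: generated
#'   from the seed).
#' @param nGenes,cdsLengthRange reference panel shape when generating.
#' @param predictor affinity predictor (default [toyPredictor]).
#' @return list with `manifest`, `profiles`, `report`, `loads` (per
#'   patient record data.frames), and `outputDir`.
#' @export
runPipeline <- function(config, reference = NULL, nGenes = 40L,
                        cdsLengthRange = c(300L, 900L),
                        predictor = toyPredictor()) {
  stopifnot(inherits(config, "PipelineConfig"))
  oldOpt <- options(neoprofiler.log_level = config$log_level)
  on.exit(options(oldOpt), add = TRUE)
  outDir <- config$paths$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    sim <- config$simulation
    sim@seed <- .childSeed(config$seed, 1L)
    if (is.null(reference))
      reference <- generateReference(nGenes, cdsLengthRange,
                                     seed = .childSeed(config$seed, 2L))
    cohort <- simulateCohort(reference, sim)
    cohortDir <- file.path(outDir, "cohort")
    writeCohortDir(cohort, cohortDir)
    writeReferencePanel(reference, file.path(outDir, "reference.fasta"),
                        file.path(outDir, "reference.tsv"))
    stage <- "call"
    calls <- lapply(cohort, function(p)
      callSomaticVariants(alleleCounts(p), config$caller))
    stage <- "classify"
    classified <- lapply(calls, classifyVariants, reference = reference)
    for (i in seq_along(cohort))
      writeVariantsVcf(classified[[i]],
                       file.path(outDir, paste0(patientId(cohort[[i]]),
                                                ".vcf")))
    stage <- "neoantigens"
    loads <- lapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      neoantigenLoad(classified[[i]], reference, hlaAlleles(p),
                     rnaReadCounts(p), config$neoantigen,
                     predictor = predictor)
    })
    stage <- "profiles"
    profiles <- data.frame(
      patient_id = vapply(cohort, patientId, ""),
      subtype = vapply(cohort, subtype, ""),
      tnbc_flag = vapply(cohort, subtype, "") == "TNBC",
      n_exonic = vapply(classified, nrow, 0L),
      n_nssnv = vapply(classified, function(v)
        sum(v$mutation_class == "nsSNV"), 0L),
      n_predicted_binders = vapply(loads, function(l)
        l$nPredictedBinders, 0L),
      neoantigen_load = vapply(loads, function(l) l$load, 0L))
    .writeTsv(profiles, file.path(outDir, "profiles.tsv"))
    stage <- "cohort-stats"
    report <- if (nrow(profiles) >= 3L) cohortReport(profiles) else NULL
    if (!is.null(report))
      .writeTsv(report, file.path(outDir, "cohort_report.tsv"))
    summary <- list(
      n_patients = length(cohort),
      total_called = sum(profiles$n_exonic),
      total_nssnv = sum(profiles$n_nssnv),
      mean_load = mean(profiles$neoantigen_load))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(cohort = cohort, classified = classified, loads = loads,
         profiles = profiles, report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  cfgFile <- file.path(outDir, "config.yaml")
  yaml::write_yaml(.configAsList(config), cfgFile)
  inputs <- file.path(outDir, "cohort",
                      list.files(file.path(outDir, "cohort")))
  manifest <- list(
    tool = "neoprofiler",
    version = as.character(packageVersion("neoprofiler")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    input_md5 = as.list(tools::md5sum(sort(inputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  c(result, list(manifest = manifest, outputDir = outDir))
}

# flatten a PipelineConfig into plain lists for YAML serialisation
.configAsList <- function(config) {
  s4ToList <- function(x) {
    sl <- lapply(slotNames(class(x)), function(nm) slot(x, nm))
    names(sl) <- slotNames(class(x))
    sl
  }
  list(simulation = s4ToList(config$simulation),
       caller = s4ToList(config$caller),
       neoantigen = s4ToList(config$neoantigen),
       paths = config$paths, seed = config$seed,
       log_level = config$log_level)
}
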