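#' Pipeline configuration
#'
#' Exactly one input source must be given: a cohort manifest file
#' (`input`) or a synthetic [CohortSpec-class] (`spec`).
#'
#' @slot input path to a cohort manifest, or `NA_character_`.
#' @slot spec a [CohortSpec-class] or `NULL`.
#' @slot weightMode `"r2"` (default), `"r"` or `"abs_r"`.
#' @slot nNull null-ensemble size (default 100).
#' @slot kSd plateau-selection SD multiplier (default 4).
#' @slot fdrQ FDR level for the variability CV mask (default 0.05).
#' @slot masterSeed integer seed driving the null ensemble.
#' @slot outputDir run directory.
#' @export
setClass("PipelineConfig", representation(
  input = "character", spec = "ANY", weightMode = "character",
  nNull = "integer", kSd = "numeric", fdrQ = "numeric",
  masterSeed = "integer", outputDir = "character"
))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  hasInput <- !is.na(object@input)
  hasSpec <- !is.null(object@spec)
  if (hasInput == hasSpec)
    msgs <- c(msgs, "exactly one of input manifest / synthetic spec required")
  if (hasSpec && !is(object@spec, "CohortSpec"))
    msgs <- c(msgs, "spec must be a CohortSpec")
  if (!object@weightMode %in% c("r2", "r", "abs_r"))
    msgs <- c(msgs, "weightMode must be r2, r or abs_r")
  if (object@nNull < 0L) msgs <- c(msgs, "nNull must be >= 0")
  if (object@kSd <= 0) msgs <- c(msgs, "kSd must be > 0")
  if (object@fdrQ <= 0 || object@fdrQ >= 1) msgs <- c(msgs, "fdrQ must be in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PipelineConfig-class
#' @param input,spec,weightMode,nNull,kSd,fdrQ,masterSeed,outputDir see
#'   the class slots.
#' @return a validated `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir, input = NA_character_, spec = NULL,
                           weightMode = "r2", nNull = 100L, kSd = 4,
                           fdrQ = 0.05, masterSeed = 1L) {
  cfg <- new("PipelineConfig", input = as.character(input), spec = spec,
             weightMode = weightMode, nNull = as.integer(nNull),
             kSd = as.numeric(kSd), fdrQ = as.numeric(fdrQ),
             masterSeed = as.integer(masterSeed),
             outputDir = as.character(outputDir))
  validObject(cfg)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `output_dir`, `input_manifest`, `synthetic`
#' (sub-keys: `n_subjects`, `n_timepoints`, `module_sizes`, `topology`,
#' `r_within`, `r_between`, `subject_noise_sd`, `seed`), `weight_mode`,
#' `n_null`, `k_sd`, `fdr_q`, `master_seed`.
#'
#' @param path YAML file path.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    sizes <- as.integer(s$module_sizes)
    ends <- cumsum(sizes)
    modules <- mapply(seq.int, ends - sizes + 1L, ends, SIMPLIFY = FALSE)
    names(modules) <- paste0("M", seq_along(modules))
    spec <- cohortSpec(
      nSubjects = s$n_subjects, nTimepoints = s$n_timepoints,
      modules = modules,
      topology = if (is.null(s$topology)) "chain" else s$topology,
      rWithin = if (is.null(s$r_within)) 0.6 else s$r_within,
      rBetween = if (is.null(s$r_between)) 0.1 else s$r_between,
      subjectNoiseSd = if (is.null(s$subject_noise_sd)) 0.1 else s$subject_noise_sd,
      seed = if (is.null(s$seed)) 1L else s$seed)
  }
  pipelineConfig(
    outputDir = y$output_dir,
    input = if (is.null(y$input_manifest)) NA_character_ else y$input_manifest,
    spec = spec,
    weightMode = if (is.null(y$weight_mode)) "r2" else y$weight_mode,
    nNull = if (is.null(y$n_null)) 100L else y$n_null,
    kSd = if (is.null(y$k_sd)) 4 else y$k_sd,
    fdrQ = if (is.null(y$fdr_q)) 0.05 else y$fdr_q,
    masterSeed = if (is.null(y$master_seed)) 1L else y$master_seed)
}

.writeLabelledMatrix <- function(m, labels, path) {
  dimnames(m) <- list(labels, labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
}

.writeTable <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full scaffold-analysis pipeline
#'
#' Executes, in order: cohort input (read or synthesize), per-subject
#' correlation, Fisher group averaging, inter-subject variability maps,
#' spectrum-preserving null ensemble, percolation of the real and every
#' null weight matrix, plateau-significance threshold selection,
#' thresholded snapshots, Maximum Spanning Forest, Maximum Spanning Tree
#' and degree profiles. All artifacts are written to the output directory
#' as delimited text (graphs additionally as GraphML) together with a
#' machine-readable `report.json` and a `log.txt` with stage timings and
#' seeds. Reruns with the same configuration produce byte-identical
#' numeric artifacts.
#'
#' @param config a [PipelineConfig-class] or path to a YAML configuration.
#' @return the run report, invisibly (a list; also in `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  out <- config@outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(out, "log.txt")
  cat(sprintf("run started %s\n", format(Sys.time())), file = logFile)
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile,
                               append = TRUE)
  stageName <- "init"
  stage <- function(name, expr) {
    stageName <<- name
    t0 <- proc.time()[["elapsed"]]
    v <- withCallingHandlers(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logLine("stage %-12s %7.2fs", name, proc.time()[["elapsed"]] - t0)
    v
  }
  if (config@nNull > 0L && config@nNull < 10L)
    warning("plateau-selection SD is unstable below 10 null curves ",
            "(nNull = ", config@nNull, ")", call. = FALSE)

  cohort <- stage("input", {
    if (!is.na(config@input)) readCohort(config@input)
    else generateCohort(config@spec)
  })
  stack <- stage("correlate", correlationStack(cohort))
  group <- stage("average", fisherAverage(stack))
  .writeLabelledMatrix(groupR(group), roiLabels(group),
                       file.path(out, "group_r.tsv"))
  .writeLabelledMatrix(groupW(group), roiLabels(group),
                       file.path(out, "group_w.tsv"))

  vmaps <- NULL
  if (nSubjects(stack) >= 3L) {
    vmaps <- stage("variability", variabilityMaps(stack, config@fdrQ))
    .writeLabelledMatrix(vmaps@mean, roiLabels(group),
                         file.path(out, "variability_mean.tsv"))
    .writeLabelledMatrix(vmaps@sd, roiLabels(group),
                         file.path(out, "variability_sd.tsv"))
    .writeLabelledMatrix(vmaps@cv, roiLabels(group),
                         file.path(out, "variability_cv.tsv"))
  } else {
    logLine("stage variability skipped (fewer than 3 subjects)")
  }

  nulls <- stage("nulls", ensembleGenerate(group, config@nNull,
                                           config@masterSeed))
  writeEnsemble(nulls, file.path(out, "nulls"))
  logLine("null ensemble: %d members, spectrum hash %s",
          length(nulls@matrices), spectrumHash(nulls@sourceSpectrum))

  w <- groupWeights(group, config@weightMode)
  curve <- stage("percolate", percolate(w))
  .writeTable(percolationEvents(curve), file.path(out, "percolation_curve.tsv"))
  plat <- plateauLengths(curve)
  .writeTable(plateauTable(plat), file.path(out, "plateaus.tsv"))

  nullPlats <- stage("null_percolation", lapply(nulls@matrices, function(m)
    plateauLengths(percolate(groupWeights(m, config@weightMode)))))
  thr <- NULL
  if (length(nullPlats) >= 2L) {
    thr <- stage("thresholds",
                 selectThresholds(plat, nullPlats, config@kSd))
    thrTab <- data.frame(
      threshold_w = as.numeric(thr),
      threshold_r = if (config@weightMode == "r2") sqrt(as.numeric(thr))
      else as.numeric(thr))
    .writeTable(thrTab, file.path(out, "thresholds.tsv"))
    snapDir <- file.path(out, "snapshots")
    dir.create(snapDir, showWarnings = FALSE)
    stage("snapshots", for (k in seq_along(thr)) {
      g <- snapshotGraph(w, thr[k], labels = roiLabels(group))
      base <- file.path(snapDir, sprintf("snapshot_%02d", k))
      igraph::write_graph(g, paste0(base, ".graphml"), format = "graphml")
      el <- igraph::as_data_frame(g, what = "edges")
      .writeTable(el, paste0(base, "_edges.tsv"))
    })
  } else {
    logLine("stage thresholds skipped (fewer than 2 null curves)")
  }

  forest <- stage("msf", msfRowMax(w, labels = roiLabels(group)))
  .writeTable(forestArcs(forest), file.path(out, "msf_arcs.tsv"))
  .writeTable(componentSummary(forest), file.path(out, "msf_components.tsv"))
  igraph::write_graph(asGraph(forest), file.path(out, "msf.graphml"),
                      format = "graphml")
  tree <- stage("mst", mstComplete(forest, w))
  .writeTable(treeEdges(tree), file.path(out, "mst_edges.tsv"))
  igraph::write_graph(asGraph(tree), file.path(out, "mst.graphml"),
                      format = "graphml")

  profF <- degreeProfiles(forest)
  profT <- degreeProfiles(tree)
  .writeTable(data.frame(in_degree = as.integer(names(profF@histogram)),
                         count = as.integer(profF@histogram),
                         fraction = as.numeric(profF@fractions)),
              file.path(out, "degree_msf.tsv"))
  .writeTable(data.frame(degree = as.integer(names(profT@histogram)),
                         count = as.integer(profT@histogram),
                         fraction = as.numeric(profT@fractions)),
              file.path(out, "degree_mst.tsv"))

  nullMaxIndeg <- vapply(nulls@matrices, function(m) {
    degreeProfiles(msfRowMax(groupWeights(m, config@weightMode)))@maxDegree
  }, integer(1))

  report <- list(
    n_rois = nRois(group),
    n_subjects = nSubjects(stack),
    weight_mode = config@weightMode,
    master_seed = config@masterSeed,
    spectrum_hash = spectrumHash(nulls@sourceSpectrum),
    msf = list(
      n_components = length(unique(forest@membership)),
      component_sizes = as.integer(table(forest@membership)),
      n_reciprocated_pairs = nrow(forest@reciprocated),
      max_in_degree = profF@maxDegree,
      chain_score = profF@chainScore,
      in_degree_histogram = as.list(profF@histogram)),
    mst = list(
      total_weight = tree@totalWeight,
      max_degree = profT@maxDegree,
      chain_score = profT@chainScore,
      degree_histogram = as.list(profT@histogram)),
    percolation = list(
      initial_components = curve@initialComponents,
      n_plateaus = length(plat@lengths),
      max_plateau = if (length(plat@lengths)) max(plat@lengths) else NA,
      null_max_plateau = if (length(nullPlats))
        max(unlist(lapply(nullPlats, function(p) p@lengths)), 0) else NA),
    thresholds = if (!is.null(thr)) list(
      n_selected = length(thr),
      weights = as.numeric(thr),
      correlation_scale = if (config@weightMode == "r2")
        sqrt(as.numeric(thr)) else as.numeric(thr),
      null_mean = attr(thr, "nullMean"),
      null_sd = attr(thr, "nullSd"),
      comparison = attr(thr, "comparison")) else NULL,
    null_ensemble = list(
      n = length(nulls@matrices),
      max_msf_in_degree_mean = if (length(nullMaxIndeg))
        mean(nullMaxIndeg) else NA,
      seeds = nulls@seeds))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logLine("run finished %s", format(Sys.time()))
  invisible(report)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [runPipeline()] output directory and prints a
#' human-readable summary: MSF component count and size distribution,
#' reciprocated pairs, selected thresholds on both the analysis and the
#' correlation scale, MST hubs (top-5 degree) and the real-versus-null
#' maximum plateau comparison.
#'
#' @param runDir a completed run directory.
#' @return the parsed report with a `mst_hubs` element, invisibly.
#' @export
reportSummary <- function(runDir) {
  required <- c("report.json", "group_r.tsv", "percolation_curve.tsv",
                "msf_arcs.tsv", "mst_edges.tsv")
  missing <- required[!file.exists(file.path(runDir, required))]
  if (length(missing))
    stop("incomplete run directory ", runDir, "; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rep <- jsonlite::read_json(file.path(runDir, "report.json"),
                             simplifyVector = TRUE)
  mst <- utils::read.delim(file.path(runDir, "mst_edges.tsv"))
  deg <- sort(table(c(mst$node1, mst$node2)), decreasing = TRUE)
  hubs <- utils::head(deg, 5L)
  cat(sprintf("MSF: %d components (sizes %s), %d reciprocated pairs\n",
              rep$msf$n_components,
              paste(sort(rep$msf$component_sizes, decreasing = TRUE),
                    collapse = ","),
              rep$msf$n_reciprocated_pairs))
  cat(sprintf("MSF max in-degree %d, chain score %.3f\n",
              rep$msf$max_in_degree, rep$msf$chain_score))
  if (!is.null(rep$thresholds))
    cat(sprintf("Selected thresholds (n=%d): w = %s | r = %s\n",
                rep$thresholds$n_selected,
                paste(sprintf("%.4f", rep$thresholds$weights), collapse = " "),
                paste(sprintf("%.4f", rep$thresholds$correlation_scale),
                      collapse = " ")))
  cat(sprintf("MST total weight %.4f, max degree %d; hubs: %s\n",
              rep$mst$total_weight, rep$mst$max_degree,
              paste(sprintf("%s(%d)", names(hubs), as.integer(hubs)),
                    collapse = " ")))
  cat(sprintf("Max plateau: real %.4f vs null %.4f\n",
              rep$percolation$max_plateau, rep$percolation$null_max_plateau))
  rep$mst_hubs <- hubs
  invisible(rep)
}
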