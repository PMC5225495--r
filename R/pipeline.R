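## End-to-end orchestration: filter -> phase -> {sFC, dFC, metastability}
## -> surrogates -> group inference, with per-stage artifacts and a
## manifest that suffices to reproduce every output.

logStage <- function(stage, detail = "", t0 = NULL) {
  elapsed <- if (is.null(t0)) "" else
    sprintf(" (%.1fs)", as.numeric(proc.time()["elapsed"]) - t0)
  message(sprintf("[phasedyn] %-12s %s%s", stage, detail, elapsed))
}

nbsToList <- function(res) {
  list(
    threshold_f = res@thresholdF,
    n_perm = res@nPerm,
    seed = res@seed,
    statistic = res@statistic,
    components = lapply(res@components, function(co)
      list(edges = co$edges, size = co$size, intensity = co$intensity,
           p = co$p)),
    node_f_sums = as.numeric(res@nodeFSums)
  )
}

#' Run the full phase-based connectivity pipeline
#'
#' Executes, in order: band-pass filter, analytic phase with end trim,
#' static FC (regularized partial correlation + Fisher z), dynamic FC
#' (pairwise coupling CV) and metastability, the whole-brain and
#' per-edge surrogate dynamics tests, and covariate-adjusted group
#' inference (metastability multinomial logit; NBS on sFC and dFC;
#' pairwise edgewise logistic regressions). Writes per-stage CSV/JSON
#' artifacts and a manifest to `config$out_dir`. Deterministic given the
#' seeds in the config, so a rerun reproduces every output byte for
#' byte.
#'
#' @param config named list, see [readPipelineConfig()]; requires
#'   `panels_dir`, `cohort_csv` and `out_dir`.
#' @return invisibly, a list with the in-memory results (`sfc`, `dfc`,
#'   `summary`, `wholeBrain`, `edgeDynamics`, `multinomial`, `nbsSfc`,
#'   `nbsDfc`, `edgewise`, `manifest`).
#' @export
runPipeline <- function(config) {
  for (k in c("panels_dir", "cohort_csv", "out_dir"))
    if (is.null(config[[k]])) stop("config is missing ", k)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()["elapsed"])

  panel <- readPanels(config$panels_dir)
  cohort <- readCohort(config$cohort_csv)
  cohort <- cohort[match(subjectIds(panel), cohort$subject_id), ]
  if (anyNA(cohort$subject_id))
    stop("cohort table does not cover all panel subjects")
  logStage("load", sprintf("%d subjects, %d nodes, %d timepoints",
                           nSubjects(panel), nNodes(panel),
                           nTimepoints(panel)), t0)

  lowHz <- config$band_low_hz; highHz <- config$band_high_hz
  trim <- as.integer(config$trim)
  sdType <- config$sd_convention

  stage <- "sfc"
  res <- tryCatch({
    sfc <- sfcCohort(panel, lambda = config$lambda, cohort = cohort)
    writeEdgeMatrix(sfc, file.path(outDir, "sfc_edges.csv"))
    logStage("sfc", sprintf("%d edges, lambda = %g", nrow(sfc),
                            config$lambda), t0)

    stage <- "phase"
    filt <- bandpassFilter(panel, lowHz, highHz)
    phasePanel <- analyticPhase(filt, trim = trim)
    logStage("phase", sprintf("%d usable timepoints after trim %d",
                              nTimepoints(phasePanel), trim), t0)

    stage <- "dfc"
    dyn <- dynamicsCohort(phasePanel, cohort = cohort, sdType = sdType)
    writeEdgeMatrix(dyn$dfc, file.path(outDir, "dfc_edges.csv"))
    smry <- dyn$summary
    txt <- data.frame(subject_id = smry$subject_id,
                      metastability = fmtNum(smry$metastability),
                      dfc_sum = fmtNum(smry$dfc_sum))
    utils::write.csv(txt, file.path(outDir, "metastability.csv"),
                     row.names = FALSE, quote = FALSE)
    logStage("dfc", sprintf("%d subjects summarized", nrow(smry)), t0)

    stage <- "surrogate"
    ref <- cohort$subject_id[cohort$group == config$reference_group]
    if (length(ref) < 2L)
      stop("reference group '", config$reference_group,
           "' has fewer than 2 subjects")
    ens <- surrogateEnsemble(panel,
                             nSurrogates = as.integer(config$n_surrogates),
                             lowHz = lowHz, highHz = highHz, trim = trim,
                             sdType = sdType,
                             seed = as.integer(config$seed_surrogate),
                             refSubjects = ref)
    wb <- wholeBrainDynamicsCurve(smry$dfc_sum, ens)
    refDfcReal <- edgeValues(dyn$dfc)[ref, , drop = FALSE]
    ed <- edgeDynamicsTest(refDfcReal, ens)
    jsonlite::write_json(list(mu = wb$mu, t = wb$tStat, p = wb$p),
                         file.path(outDir, "surrogate_whole_brain.json"),
                         digits = NA)
    utils::write.csv(ed, file.path(outDir, "surrogate_edge_p.csv"),
                     row.names = FALSE, quote = FALSE)
    logStage("surrogate", sprintf("%d surrogates, seed %d",
                                  ens@nSurrogates, ens@seed), t0)

    stage <- "inference"
    design <- groupDesign(cohort, reference = config$reference_group)
    groups <- levels(design@outcome)
    mn <- if (nlevels(design@outcome) >= 2 &&
              all(table(design@outcome) >= 2))
      metastabilityMultinomial(smry$metastability, design)
    else NULL
    nbsArgs <- list(design = design,
                    primaryP = config$primary_p,
                    nPerm = as.integer(config$n_perm),
                    seed = as.integer(config$seed_nbs))
    nbsSfc <- nbsDfc <- NULL
    edgewise <- list()
    if (nlevels(design@outcome) >= 2) {
      if (all(table(design@outcome) >= 3)) {
        nbsSfc <- do.call(nbs, c(list(x = sfc), nbsArgs))
        nbsDfc <- do.call(nbs, c(list(x = dyn$dfc), nbsArgs))
        jsonlite::write_json(nbsToList(nbsSfc),
                             file.path(outDir, "nbs_sfc.json"),
                             digits = NA, auto_unbox = TRUE)
        jsonlite::write_json(nbsToList(nbsDfc),
                             file.path(outDir, "nbs_dfc.json"),
                             digits = NA, auto_unbox = TRUE)
      }
      pairsDx <- utils::combn(groups, 2, simplify = FALSE)
      for (pd in pairsDx) {
        key <- paste(pd, collapse = "_vs_")
        edgewise[[key]] <- list(
          sfc = edgewiseLogistic(sfc, design, pd),
          dfc = edgewiseLogistic(dyn$dfc, design, pd))
        utils::write.csv(edgewise[[key]]$dfc,
                         file.path(outDir,
                                   sprintf("edgewise_dfc_%s.csv", key)),
                         row.names = FALSE, quote = FALSE)
      }
    } else {
      message("single diagnosis group: group-level tests skipped")
    }
    if (!is.null(mn))
      jsonlite::write_json(
        list(coefficients = mn$coefficients, pseudo_r2 = mn$pseudoR2,
             log_likelihood = mn$logLik),
        file.path(outDir, "multinomial.json"), digits = NA,
        auto_unbox = TRUE, dataframe = "columns")
    logStage("inference", sprintf("%d group(s)", nlevels(design@outcome)),
             t0)

    list(sfc = sfc, dfc = dyn$dfc, summary = smry, wholeBrain = wb,
         edgeDynamics = ed, multinomial = mn, nbsSfc = nbsSfc,
         nbsDfc = nbsDfc, edgewise = edgewise)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  cfgPath <- file.path(outDir, "config.txt")
  writePipelineConfig(config, cfgPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phasedyn")),
    config_md5 = unname(tools::md5sum(cfgPath)),
    n_subjects = nSubjects(panel),
    n_nodes = nNodes(panel),
    n_timepoints = nTimepoints(panel),
    usable_timepoints = nTimepoints(panel) - 2L * trim,
    n_edges = nEdges(nNodes(panel)),
    scan_duration_seconds = scanDuration(panel),
    outputs = sort(setdiff(list.files(outDir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
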