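#' Constructors for the core containers
#'
#' `timeSeriesPanel()` bundles per-subject node x time matrices with their
#' sampling interval; `simulationConfig()` collects the study-design
#' parameters consumed by the simulators; `edgeVector()` wraps a vector of
#' edge values in canonical upper-triangle order.
#'
#' @param values list of node x time numeric matrices, one per subject.
#' @param trSeconds sampling interval in seconds.
#' @param nodeLabels optional node names (default `node_1..node_N`).
#' @param subjectIds optional subject ids (default `sub_001..`).
#' @return A validated S4 object of the corresponding class.
#' @examples
#' p <- timeSeriesPanel(list(matrix(rnorm(40), 4, 10)), trSeconds = 2.638)
#' nNodes(p); nTimepoints(p)
#' @export
timeSeriesPanel <- function(values, trSeconds, nodeLabels = NULL,
                            subjectIds = NULL) {
  if (is.matrix(values)) values <- list(values)
  stopifnot(is.list(values), length(values) >= 1L)
  values <- lapply(values, function(m) {
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(values[[1]])
  if (is.null(nodeLabels)) nodeLabels <- sprintf("node_%d", seq_len(n))
  if (is.null(subjectIds))
    subjectIds <- sprintf("sub_%03d", seq_along(values))
  new("TimeSeriesPanel", values = values, trSeconds = as.numeric(trSeconds),
      nodeLabels = as.character(nodeLabels),
      subjectIds = as.character(subjectIds))
}

#' @rdname timeSeriesPanel
#' @param nSubjects subjects per group.
#' @param nNodes node count.
#' @param nTimepoints retained volumes per subject.
#' @param freqBand oscillator band in Hz, `c(low, high)`.
#' @param couplingByGroup named numeric, global coupling K per group label,
#'   in decreasing-health order of the emulated design. The defaults sit on
#'   the supercritical branch of the coupled-oscillator model, where
#'   metastability decreases as K grows, so group-mean metastability is
#'   ordered SCI > MCI > AD.
#' @param noiseSd measurement noise SD added to the emitted signal.
#' @param phaseNoiseSd phase-diffusion SD in rad/sqrt(s).
#' @param seed base integer seed.
#' @export
simulationConfig <- function(nSubjects = 26L, nNodes = 26L,
                             nTimepoints = 202L, trSeconds = 2.638,
                             freqBand = c(0.04, 0.07),
                             couplingByGroup = c(SCI = 0.12, MCI = 0.18,
                                                 AD = 0.24),
                             noiseSd = 0.2, phaseNoiseSd = 0.25,
                             seed = 1L) {
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), nNodes = as.integer(nNodes),
      nTimepoints = as.integer(nTimepoints),
      trSeconds = as.numeric(trSeconds), freqBand = as.numeric(freqBand),
      couplingByGroup = couplingByGroup, noiseSd = as.numeric(noiseSd),
      phaseNoiseSd = as.numeric(phaseNoiseSd), seed = as.integer(seed))
}

#' @rdname timeSeriesPanel
#' @param x numeric vector of edge values.
#' @param metric metric tag, e.g. `"sfc_z"` or `"dfc_cv"`.
#' @param nNodes node count implied by the edge vector.
#' @export
edgeVector <- function(x, metric = "raw", nNodes) {
  new("EdgeVector", values = as.numeric(x), metric = metric,
      nNodes = as.integer(nNodes))
}

#' Accessors for phasedyn containers
#'
#' Dimension, label and value accessors shared by [TimeSeriesPanel-class],
#' [PhasePanel-class], [EdgeVector-class], [ConnectivityExperiment-class]
#' and [DynamicState-class] objects.
#'
#' @param x a phasedyn object.
#' @name accessors
#' @aliases nNodes nSubjects nTimepoints trSeconds subjectIds nodeLabels
#'   panelValues phases envelopes edgeValues edgeMetric
NULL

#' @rdname accessors
setMethod("nNodes", "TimeSeriesPanel", function(x) nrow(x@values[[1]]))
#' @rdname accessors
setMethod("nSubjects", "TimeSeriesPanel", function(x) length(x@values))
#' @rdname accessors
setMethod("nTimepoints", "TimeSeriesPanel", function(x) ncol(x@values[[1]]))
#' @rdname accessors
setMethod("trSeconds", "TimeSeriesPanel", function(x) x@trSeconds)
#' @rdname accessors
setMethod("subjectIds", "TimeSeriesPanel", function(x) x@subjectIds)
#' @rdname accessors
setMethod("nodeLabels", "TimeSeriesPanel", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("panelValues", "TimeSeriesPanel", function(x) x@values)

#' @rdname accessors
setMethod("nNodes", "PhasePanel", function(x) nrow(x@phase[[1]]))
#' @rdname accessors
setMethod("nSubjects", "PhasePanel", function(x) length(x@phase))
#' @rdname accessors
setMethod("nTimepoints", "PhasePanel", function(x) ncol(x@phase[[1]]))
#' @rdname accessors
setMethod("trSeconds", "PhasePanel", function(x) x@trSeconds)
#' @rdname accessors
setMethod("subjectIds", "PhasePanel", function(x) x@subjectIds)
#' @rdname accessors
setMethod("nodeLabels", "PhasePanel", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("phases", "PhasePanel", function(x) x@phase)
#' @rdname accessors
setMethod("envelopes", "PhasePanel", function(x) x@envelope)

#' @rdname accessors
setMethod("nNodes", "EdgeVector", function(x) x@nNodes)
#' @rdname accessors
setMethod("edgeValues", "EdgeVector", function(x) x@values)
#' @rdname accessors
setMethod("edgeMetric", "EdgeVector", function(x) x@metric)

#' @rdname accessors
setMethod("nNodes", "CouplingTrajectory", function(x) x@nNodes)

#' @rdname accessors
setMethod("nNodes", "ConnectivityExperiment",
          function(x) S4Vectors::metadata(x)$nNodes)
#' @rdname accessors
setMethod("nSubjects", "ConnectivityExperiment", function(x) ncol(x))
#' @rdname accessors
setMethod("subjectIds", "ConnectivityExperiment", function(x) colnames(x))
#' @rdname accessors
setMethod("edgeMetric", "ConnectivityExperiment",
          function(x) S4Vectors::metadata(x)$metric)
#' @rdname accessors
setMethod("edgeValues", "ConnectivityExperiment", function(x)
  t(SummarizedExperiment::assay(x)))

#' @rdname accessors
setMethod("nNodes", "DynamicState", function(x) x@nNodes)
#' @rdname accessors
setMethod("subjectIds", "DynamicState", function(x) x@subjectId)

#' Total scan duration in seconds
#'
#' Number of retained volumes times the sampling interval; e.g. 202
#' volumes at TR 2.638 s span 532.876 s.
#'
#' @param x a [TimeSeriesPanel-class] or [SimulationConfig-class].
#' @return duration in seconds.
#' @examples
#' scanDuration(simulationConfig(nSubjects = 1))
#' @name scanDuration
NULL

#' @rdname scanDuration
setMethod("scanDuration", "TimeSeriesPanel",
          function(x) nTimepoints(x) * trSeconds(x))
#' @rdname scanDuration
setMethod("scanDuration", "SimulationConfig",
          function(x) x@nTimepoints * x@trSeconds)

setMethod("show", "TimeSeriesPanel", function(object) {
  cat(sprintf("TimeSeriesPanel: %d subject(s), %d nodes x %d timepoints, TR %.3f s (%.3f s total)\n",
              nSubjects(object), nNodes(object), nTimepoints(object),
              trSeconds(object), scanDuration(object)))
})

setMethod("show", "PhasePanel", function(object) {
  cat(sprintf("PhasePanel: %d subject(s), %d nodes x %d timepoints (trim %d per end), TR %.3f s\n",
              nSubjects(object), nNodes(object), nTimepoints(object),
              object@trim, trSeconds(object)))
})

setMethod("show", "EdgeVector", function(object) {
  cat(sprintf("EdgeVector <%s>: %d edges over %d nodes\n", object@metric,
              length(object@values), object@nNodes))
  cat("  head:", paste(signif(head(object@values, 5), 4), collapse = ", "),
      "\n")
})

setMethod("show", "DynamicState", function(object) {
  cat(sprintf("DynamicState [%s]: %d timepoints, metastability = %.4f\n",
              object@subjectId, length(object@orderParameter),
              object@metastability))
})

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf("SurrogateEnsemble: %d surrogates x %d subjects (edge-level kept for %d reference subjects)\n",
              object@nSurrogates, ncol(object@dfcSums),
              length(object@refSubjects)))
})

setMethod("show", "NBSResult", function(object) {
  sig <- sum(vapply(object@components, function(co) co$p < 0.05, logical(1)))
  cat(sprintf("NBSResult: %d nodes, F threshold %.3f, %d suprathreshold component(s), %d with FWE p < 0.05 (%d permutations)\n",
              object@nNodes, object@thresholdF, length(object@components),
              sig, object@nPerm))
})
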