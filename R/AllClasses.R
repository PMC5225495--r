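## Central containers. Per-subject node-by-time matrices are kept as a list
## (one matrix per subject) under a shared sampling interval; cohort-level
## edge matrices live in a SummarizedExperiment subclass so that covariates
## travel with the connectivity values.

#' SimulationConfig: study-design parameters for the cohort simulators
#'
#' Holds the dimensions and noise levels of a simulated resting-state
#' cohort: nodes, timepoints, sampling interval (TR), the narrowband of
#' interest, per-group global coupling strengths and noise levels.
#'
#' @slot nSubjects integer, subjects per group.
#' @slot nNodes integer, number of network nodes (default 26).
#' @slot nTimepoints integer, number of retained volumes (default 202).
#' @slot trSeconds numeric, sampling interval in seconds (default 2.638).
#' @slot freqBand numeric(2), oscillator band in Hz (default 0.04-0.07).
#' @slot couplingByGroup named numeric, global coupling strength K per group.
#' @slot noiseSd numeric, measurement noise SD on the emitted signal.
#' @slot phaseNoiseSd numeric, SD of the Wiener phase noise (rad/sqrt(s)).
#' @slot seed integer, base seed for reproducibility.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    nNodes = "integer",
    nTimepoints = "integer",
    trSeconds = "numeric",
    freqBand = "numeric",
    couplingByGroup = "numeric",
    noiseSd = "numeric",
    phaseNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (object@nTimepoints <= 40L)
    msg <- c(msg, "nTimepoints must exceed twice the end-trim length (2 x 20)")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  nyq <- 1 / (2 * object@trSeconds)
  if (length(object@freqBand) != 2L ||
      !(0 < object@freqBand[1] && object@freqBand[1] < object@freqBand[2] &&
        object@freqBand[2] < nyq))
    msg <- c(msg, sprintf(
      "freqBand must satisfy 0 < low < high < Nyquist (%.4f Hz)", nyq))
  if (any(object@couplingByGroup < 0))
    msg <- c(msg, "coupling strengths must be nonnegative")
  if (is.null(names(object@couplingByGroup)) ||
      any(!nzchar(names(object@couplingByGroup))))
    msg <- c(msg, "couplingByGroup must be a named vector (one K per group)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@phaseNoiseSd < 0) msg <- c(msg, "phaseNoiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' TimeSeriesPanel: per-subject node-by-time signal matrices
#'
#' The pipeline's raw input: one node x time real matrix per subject, all
#' sharing node count, timepoint count and sampling interval.
#'
#' @slot values list of node x time numeric matrices, one per subject.
#' @slot trSeconds numeric, sampling interval in seconds.
#' @slot nodeLabels character, node names.
#' @slot subjectIds character, subject identifiers.
#' @slot band numeric(2), band-pass edges in Hz already applied to the
#'   values, or `NA` if the panel is unfiltered.
#' @exportClass TimeSeriesPanel
setClass("TimeSeriesPanel",
  representation(
    values = "list",
    trSeconds = "numeric",
    nodeLabels = "character",
    subjectIds = "character",
    band = "numeric"
  ),
  prototype(band = c(NA_real_, NA_real_))
)

setValidity("TimeSeriesPanel", function(object) {
  msg <- character()
  if (length(object@values) == 0L) msg <- c(msg, "panel has no subjects")
  if (length(object@values) != length(object@subjectIds))
    msg <- c(msg, "one subject id per matrix required")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subject ids must be unique")
  dims <- vapply(object@values, dim, integer(2))
  if (length(object@values) &&
      (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L))
    msg <- c(msg, "all subjects must share node and timepoint counts")
  if (length(object@values) && dims[1, 1] != length(object@nodeLabels))
    msg <- c(msg, "nodeLabels must match the node dimension")
  if (!all(vapply(object@values, function(m) all(is.finite(m)), logical(1))))
    msg <- c(msg, "panel values must be finite")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PhasePanel: instantaneous phases and envelopes
#'
#' Output of the analytic-signal transform: wrapped instantaneous phase
#' phi_k(t) in (-pi, pi] and nonnegative envelope a_k(t) per node, with
#' `trim` points removed from each end of the series.
#'
#' @slot phase list of node x time phase matrices (radians).
#' @slot envelope list of node x time envelope matrices (>= 0).
#' @slot trim integer, points removed from each end.
#' @slot trSeconds numeric, sampling interval in seconds.
#' @slot nodeLabels character.
#' @slot subjectIds character.
#' @exportClass PhasePanel
setClass("PhasePanel",
  representation(
    phase = "list",
    envelope = "list",
    trim = "integer",
    trSeconds = "numeric",
    nodeLabels = "character",
    subjectIds = "character"
  )
)

setValidity("PhasePanel", function(object) {
  msg <- character()
  if (length(object@phase) != length(object@envelope) ||
      length(object@phase) != length(object@subjectIds))
    msg <- c(msg, "phase, envelope and subjectIds must align")
  okPhase <- all(vapply(object@phase, function(m)
    all(is.finite(m)) && all(m > -pi - 1e-12) && all(m <= pi + 1e-12),
    logical(1)))
  if (!okPhase) msg <- c(msg, "phases must be finite and wrapped to (-pi, pi]")
  okEnv <- all(vapply(object@envelope, function(m)
    all(is.finite(m)) && all(m >= 0), logical(1)))
  if (!okEnv) msg <- c(msg, "envelopes must be finite and nonnegative")
  if (object@trim < 0L) msg <- c(msg, "trim must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' EdgeVector: connectivity values in canonical upper-triangle order
#'
#' A length n(n-1)/2 vector over the unique node pairs of an n-node
#' network, in 1-based row-major upper-triangle order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @slot values numeric vector of edge values (NA allowed for flagged edges).
#' @slot metric character, one of "sfc_z", "dfc_cv" (or "raw").
#' @slot nNodes integer, node count n.
#' @exportClass EdgeVector
setClass("EdgeVector",
  representation(values = "numeric", metric = "character", nNodes = "integer")
)

setValidity("EdgeVector", function(object) {
  n <- object@nNodes
  msg <- character()
  if (n < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (length(object@values) != n * (n - 1L) / 2L)
    msg <- c(msg, "values length must be nNodes*(nNodes-1)/2")
  if (any(is.infinite(object@values)))
    msg <- c(msg, "edge values must not be infinite")
  if (length(object@metric) != 1L)
    msg <- c(msg, "metric must be a single tag")
  if (length(msg)) msg else TRUE
})

#' DynamicState: whole-brain synchrony trace and metastability
#'
#' The Kuramoto order parameter R(t) (modulus of the mean unit phasor over
#' nodes, in [0,1]) and its temporal standard deviation (metastability)
#' for one subject.
#'
#' @slot orderParameter numeric, R(t) per timepoint.
#' @slot metastability numeric(1), sample SD of R(t).
#' @slot nNodes integer.
#' @slot subjectId character.
#' @exportClass DynamicState
setClass("DynamicState",
  representation(
    orderParameter = "numeric",
    metastability = "numeric",
    nNodes = "integer",
    subjectId = "character"
  )
)

setValidity("DynamicState", function(object) {
  msg <- character()
  r <- object@orderParameter
  if (any(r < -1e-12 | r > 1 + 1e-12)) msg <- c(msg, "R(t) must lie in [0,1]")
  if (object@metastability < 0 || object@metastability > 0.5 + 1e-12)
    msg <- c(msg, "metastability must lie in [0, 0.5]")
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' CouplingTrajectory: instantaneous pairwise phase coupling over time
#'
#' Edge x time matrix of C_ij(t) = 1 - delta_phi_ij(t)/pi, where
#' delta_phi is the circular distance between the instantaneous phases of
#' nodes i and j (in [0, pi]), so C lies in [0, 1].
#'
#' @slot coupling numeric matrix, edges x timepoints, canonical edge order.
#' @slot nNodes integer.
#' @exportClass CouplingTrajectory
setClass("CouplingTrajectory",
  representation(coupling = "matrix", nNodes = "integer")
)

setValidity("CouplingTrajectory", function(object) {
  n <- object@nNodes
  msg <- character()
  if (nrow(object@coupling) != n * (n - 1L) / 2L)
    msg <- c(msg, "coupling must have one row per unique node pair")
  if (any(object@coupling < -1e-12 | object@coupling > 1 + 1e-12))
    msg <- c(msg, "coupling values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ConnectivityExperiment: cohort edge matrices with covariates
#'
#' A SummarizedExperiment whose assay holds one column per subject and one
#' row per unique node pair (canonical upper-triangle order); rowData maps
#' edges to node pairs, colData carries the cohort covariates
#' (group, age, sex, headcoil, motion).
#'
#' @exportClass ConnectivityExperiment
setClass("ConnectivityExperiment",
  contains = "SummarizedExperiment"
)

setValidity("ConnectivityExperiment", function(object) {
  msg <- character()
  n <- S4Vectors::metadata(object)$nNodes
  if (is.null(n)) return("metadata nNodes is required")
  if (nrow(object) != n * (n - 1L) / 2L)
    msg <- c(msg, "row count must equal nNodes*(nNodes-1)/2")
  if (is.null(S4Vectors::metadata(object)$metric))
    msg <- c(msg, "metadata metric tag is required")
  if (length(msg)) msg else TRUE
})

#' SurrogateEnsemble: dFC summaries of phase-randomized surrogate cohorts
#'
#' For each of S surrogate datasets (phase-randomized copies of an input
#' cohort, filtered and phase-processed through the identical downstream
#' pipeline as the real data): the per-subject sum of all unique dFC
#' coefficient-of-variation values, and, for a designated reference subset
#' of subjects, the full subject x edge dFC matrices.
#'
#' @slot dfcSums numeric matrix, surrogates x subjects.
#' @slot refDfc numeric array, surrogates x reference-subjects x edges.
#' @slot refSubjects character, ids of the retained reference subjects.
#' @slot nSurrogates integer.
#' @slot seed integer, generator seed.
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
  representation(
    dfcSums = "matrix",
    refDfc = "array",
    refSubjects = "character",
    nSurrogates = "integer",
    seed = "integer"
  )
)

setValidity("SurrogateEnsemble", function(object) {
  msg <- character()
  if (nrow(object@dfcSums) != object@nSurrogates)
    msg <- c(msg, "dfcSums must have one row per surrogate")
  if (length(object@refSubjects) &&
      dim(object@refDfc)[2] != length(object@refSubjects))
    msg <- c(msg, "refDfc second dimension must match refSubjects")
  if (length(msg)) msg else TRUE
})

#' GroupDesign: outcome and covariates for group inference
#'
#' Diagnosis labels plus the confound set used throughout the group-level
#' models: sex, age, head-coil dummy (1 = 8-channel) and mean relative
#' motion.
#'
#' @slot outcome factor, diagnosis per subject (reference level first).
#' @slot covariates data.frame with columns sex, age, headcoil, motion.
#' @slot reference character, reference diagnosis label.
#' @exportClass GroupDesign
setClass("GroupDesign",
  representation(
    outcome = "factor",
    covariates = "data.frame",
    reference = "character"
  )
)

setValidity("GroupDesign", function(object) {
  msg <- character()
  if (length(object@outcome) != nrow(object@covariates))
    msg <- c(msg, "outcome and covariates must have one row per subject")
  need <- c("sex", "age", "headcoil", "motion")
  miss <- setdiff(need, colnames(object@covariates))
  if (length(miss))
    msg <- c(msg, paste0("missing covariate column(s): ",
                         paste(miss, collapse = ", ")))
  else if (!all(complete.cases(object@covariates)) || anyNA(object@outcome))
    msg <- c(msg, "design must have no missing values")
  else {
    hc <- object@covariates$headcoil
    if (!all(hc %in% c(0, 1)))
      msg <- c(msg, "headcoil must be a 0/1 dummy (1 = 8-channel)")
  }
  if (!object@reference %in% levels(object@outcome))
    msg <- c(msg, "reference must be one of the outcome levels")
  if (length(msg)) msg else TRUE
})

#' NBSResult: network-based statistic inference output
#'
#' Per-edge ANCOVA F statistics for the group factor, the primary F
#' threshold, the suprathreshold connected components with their
#' permutation family-wise-error corrected p-values, and per-node summed-F
#' contributions.
#'
#' @slot fStats numeric, per-edge F (canonical edge order).
#' @slot thresholdF numeric(1), F threshold from the primary p-level.
#' @slot components list; each element has `edges` (edge indices), `size`,
#'   `intensity` (sum of F) and `p` (FWE-corrected).
#' @slot nodeFSums numeric, per-node sum of F over significant components.
#' @slot nNodes integer.
#' @slot nPerm integer.
#' @slot seed integer.
#' @slot statistic character, "extent" or "intensity".
#' @exportClass NBSResult
setClass("NBSResult",
  representation(
    fStats = "numeric",
    thresholdF = "numeric",
    components = "list",
    nodeFSums = "numeric",
    nNodes = "integer",
    nPerm = "integer",
    seed = "integer",
    statistic = "character"
  )
)

setValidity("NBSResult", function(object) {
  msg <- character()
  ps <- vapply(object@components, function(co) co$p, numeric(1))
  if (length(ps) && any(ps < 0 | ps > 1))
    msg <- c(msg, "component p-values must lie in [0,1]")
  if (length(object@nodeFSums) != object@nNodes)
    msg <- c(msg, "nodeFSums must have one entry per node")
  if (length(msg)) msg else TRUE
})
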