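## Phase-based dynamics: whole-brain synchrony R(t), metastability,
## instantaneous pairwise coupling C(t) and its coefficient of variation.

#' Kuramoto order parameter
#'
#' Instantaneous whole-brain synchronization:
#' `R(t) = | (1/N) sum_k exp(i phi_k(t)) |`, the modulus of the mean unit
#' phasor over the N nodes at each timepoint. R = 1 means full phase
#' alignment, R = 0 balanced incoherence.
#'
#' @param x node x time phase matrix in radians, or a [PhasePanel-class]
#'   (one trace per subject).
#' @return numeric R(t) in \[0,1\] per timepoint (or a named list for a
#'   panel).
#' @examples
#' kuramotoOrder(rbind(c(0, 0), c(pi / 2, 0)))
#' @name kuramotoOrder
NULL

#' @rdname kuramotoOrder
setMethod("kuramotoOrder", "matrix", function(x) {
  if (nrow(x) < 2L)
    stop("at least 2 nodes required (R is identically 1 for one node)")
  r <- Mod(colMeans(exp(1i * x)))
  pmin(r, 1)
})

#' @rdname kuramotoOrder
setMethod("kuramotoOrder", "PhasePanel", function(x) {
  out <- lapply(x@phase, kuramotoOrder)
  names(out) <- subjectIds(x)
  out
})

#' Metastability: temporal variability of whole-brain synchrony
#'
#' The sample standard deviation of the Kuramoto order parameter R(t).
#' High values indicate flexible switching between synchronized and
#' desynchronized whole-network states; R(t) constant in time gives 0.
#'
#' @param x numeric R(t) trace (>= 2 timepoints), a [PhasePanel-class]
#'   (per-subject values) or a [DynamicState-class] (stored value).
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return nonnegative metastability value(s).
#' @examples
#' metastability(rep(c(0.4, 0.6), 100))
#' @name metastability
NULL

sdBy <- function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  s <- sd(x)
  if (sdType == "population") s <- s * sqrt((length(x) - 1) / length(x))
  s
}

#' @rdname metastability
setMethod("metastability", "numeric", function(x, sdType = "sample") {
  if (length(x) < 2L) stop("metastability needs >= 2 timepoints")
  sdBy(x, sdType)
})

#' @rdname metastability
setMethod("metastability", "PhasePanel", function(x, sdType = "sample") {
  vapply(kuramotoOrder(x), metastability, numeric(1), sdType = sdType)
})

#' @rdname metastability
setMethod("metastability", "DynamicState", function(x) x@metastability)

## Circular distance between two wrapped phases, in [0, pi].
circularDistance <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Instantaneous pairwise phase coupling C(t)
#'
#' For each timepoint and node pair (i, j), the phase difference
#' `delta_phi_ij(t)` is the circular distance between `phi_i(t)` and
#' `phi_j(t)` (in \[0, pi\]), normalized to a coupling value
#' `C_ij(t) = 1 - delta_phi_ij(t) / pi` in \[0, 1\]: 1 = in phase,
#' 0 = anti-phase.
#'
#' @param x node x time phase matrix (wrapped), or a [PhasePanel-class].
#' @return a [CouplingTrajectory-class] (edges x time, canonical order),
#'   or a named list of them for a panel.
#' @examples
#' pairwiseCoupling(rbind(c(0, 0), c(pi / 2, pi)))
#' @name pairwiseCoupling
NULL

#' @rdname pairwiseCoupling
setMethod("pairwiseCoupling", "matrix", function(x) {
  n <- nrow(x)
  pairs <- edgePairs(n)
  d <- circularDistance(x[pairs[, 1], , drop = FALSE],
                        x[pairs[, 2], , drop = FALSE])
  new("CouplingTrajectory", coupling = 1 - d / pi, nNodes = as.integer(n))
})

#' @rdname pairwiseCoupling
setMethod("pairwiseCoupling", "PhasePanel", function(x) {
  out <- lapply(x@phase, pairwiseCoupling)
  names(out) <- subjectIds(x)
  out
})

#' Per-edge dynamic-connectivity metric: coefficient of variation of C(t)
#'
#' For each edge, the temporal standard deviation of C_ij(t) divided by
#' its temporal mean. An edge whose coupling never varies scores 0; an
#' edge with a near-zero mean coupling (below `tol`) is flagged undefined
#' and reported as `NA`, never silently zero.
#'
#' @param trajectory a [CouplingTrajectory-class].
#' @param sdType SD convention, see [metastability()].
#' @param tol minimum temporal mean for the CV to be defined.
#' @return an [EdgeVector-class] with metric `"dfc_cv"`.
#' @examples
#' tr <- pairwiseCoupling(rbind(runif(50, -pi, pi), runif(50, -pi, pi)))
#' dfcCV(tr)
#' @export
dfcCV <- function(trajectory, sdType = "sample", tol = 1e-6) {
  stopifnot(is(trajectory, "CouplingTrajectory"))
  C <- trajectory@coupling
  mu <- rowMeans(C)
  nt <- ncol(C)
  s <- sqrt(rowSums((C - mu)^2) / (nt - 1))
  if (sdType == "population") s <- s * sqrt((nt - 1) / nt)
  cv <- s / mu
  bad <- mu <= tol
  if (any(bad)) {
    warning(sprintf("%d edge(s) have temporal mean coupling <= %g; CV undefined (NA)",
                    sum(bad), tol))
    cv[bad] <- NA_real_
  }
  edgeVector(cv, metric = "dfc_cv", nNodes = trajectory@nNodes)
}

#' Cohort-level phase dynamics
#'
#' Runs the whole-brain and edgewise dynamics for every subject of a
#' phase panel: Kuramoto order parameter trace and metastability
#' ([DynamicState-class]), the per-edge dFC coefficient of variation
#' (stacked into a [ConnectivityExperiment-class]), and the per-subject
#' sum of all unique dFC values (a general whole-brain dFC summary).
#'
#' @param phasePanel a [PhasePanel-class].
#' @param cohort optional covariate table (see [connectivityExperiment()]).
#' @param sdType SD convention, see [metastability()].
#' @return list with `states` (list of [DynamicState-class]), `summary`
#'   (data.frame `subject_id`, `metastability`, `dfc_sum`) and `dfc`
#'   (a [ConnectivityExperiment-class], metric `"dfc_cv"`).
#' @export
dynamicsCohort <- function(phasePanel, cohort = NULL, sdType = "sample") {
  stopifnot(is(phasePanel, "PhasePanel"))
  ns <- nSubjects(phasePanel)
  n <- nNodes(phasePanel)
  states <- vector("list", ns)
  dfc <- matrix(NA_real_, ns, nEdges(n))
  for (s in seq_len(ns)) {
    ph <- phasePanel@phase[[s]]
    r <- kuramotoOrder(ph)
    states[[s]] <- new("DynamicState", orderParameter = r,
                       metastability = metastability(r, sdType = sdType),
                       nNodes = as.integer(n),
                       subjectId = subjectIds(phasePanel)[s])
    dfc[s, ] <- edgeValues(dfcCV(pairwiseCoupling(ph), sdType = sdType))
  }
  names(states) <- subjectIds(phasePanel)
  rownames(dfc) <- subjectIds(phasePanel)
  summary <- data.frame(
    subject_id = subjectIds(phasePanel),
    metastability = vapply(states, metastability, numeric(1)),
    dfc_sum = rowSums(dfc),
    row.names = NULL
  )
  list(states = states, summary = summary,
       dfc = connectivityExperiment(dfc, metric = "dfc_cv", nNodes = n,
                                    cohort = cohort))
}
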