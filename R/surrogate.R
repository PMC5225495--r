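## Multivariate phase-randomized Fourier surrogates and the two
## surrogate-based tests for genuine temporal dynamics.
##
## A surrogate dataset is built from the UNFILTERED series: one random
## phase sequence per subject per surrogate is added to ALL nodes'
## Fourier phases at each positive frequency (common rotation), with
## conjugate symmetry enforced and DC/Nyquist untouched. This preserves
## every node's amplitude spectrum exactly and all cross-spectra (hence
## lag cross-correlations), while destroying any genuine time-varying
## coupling. Each surrogate dataset is then filtered, phase-transformed
## and summarized through the identical downstream pipeline as the real
## data.

## One common-rotation draw for a node x time matrix; RNG assumed set.
rotatePhasesCommon <- function(x) {
  nt <- ncol(x)
  half <- (nt - 1L) %/% 2L            # positive non-Nyquist frequencies
  rot <- complex(modulus = rep(1, nt))
  if (half >= 1L) {
    phi <- runif(half, 0, 2 * pi)
    rot[2:(half + 1L)] <- exp(1i * phi)
    rot[nt:(nt - half + 1L)] <- Conj(rot[2:(half + 1L)])
  }
  xf <- mvfft(t(x)) * rot
  t(Re(mvfft(xf, inverse = TRUE)) / nt)
}

#' Phase-randomized Fourier surrogates of a panel
#'
#' Returns `nSurrogates` surrogate copies of the panel; within each
#' subject the same random phase rotation is applied to all nodes
#' (preserving cross-correlations between nodes), with independent draws
#' across subjects and surrogates. Surrogates must be built from
#' unfiltered series and filtered afterwards like the real data.
#'
#' @param panel a [TimeSeriesPanel-class] of real-valued series.
#' @param nSurrogates number of surrogate datasets.
#' @param seed integer seed (deterministic stream).
#' @return list of `nSurrogates` [TimeSeriesPanel-class] objects. For
#'   large ensembles prefer [surrogateEnsemble()], which streams the
#'   surrogates through the dFC pipeline without storing them.
#' @examples
#' p <- timeSeriesPanel(list(matrix(rnorm(80), 4, 20)), 2.638)
#' s <- phaseRandomize(p, 2, seed = 1)
#' @export
phaseRandomize <- function(panel, nSurrogates, seed) {
  stopifnot(is(panel, "TimeSeriesPanel"))
  if (!anyNA(panel@band))
    warning("panel is already band-passed; surrogates should be built ",
            "from the unfiltered series")
  set.seed(as.integer(seed))
  lapply(seq_len(nSurrogates), function(s) {
    initialize(panel, values = lapply(panel@values, rotatePhasesCommon))
  })
}

#' One pass of the dFC pipeline over a panel
#'
#' The single downstream path shared by real and surrogate data:
#' band-pass filter, analytic phase with end trim, pairwise coupling
#' C(t), per-edge coefficient of variation, metastability, and the
#' per-subject sum of all unique dFC values.
#'
#' @param panel a [TimeSeriesPanel-class] (unfiltered).
#' @param lowHz,highHz band edges in Hz.
#' @param trim end trim for [analyticPhase()].
#' @param sdType SD convention, see [metastability()].
#' @return list with `dfc` (subject x edge matrix), `dfcSums` and
#'   `metastability` (named numerics).
#' @export
dfcSummary <- function(panel, lowHz = 0.04, highHz = 0.07, trim = 10L,
                       sdType = "sample") {
  nyq <- 1 / (2 * trSeconds(panel))
  if (!(0 < lowHz && lowHz < highHz && highHz < nyq))
    stop(sprintf(
      "band (%g, %g) Hz must lie strictly inside (0, Nyquist = %.4f Hz)",
      lowHz, highHz, nyq))
  gain2 <- filterGain2Band(lowHz, highHz, trSeconds(panel),
                           nTimepoints(panel))
  dfcSummaryCore(panel@values, subjectIds(panel), gain2, trim, sdType)
}

## The single downstream computation shared by real data and every
## surrogate: filter gain application, analytic phase, trim, pairwise
## coupling CV, metastability, dFC sums.
dfcSummaryCore <- function(values, ids, gain2, trim, sdType) {
  trim <- as.integer(trim)
  nt <- ncol(values[[1]])
  if (nt <= 2L * trim)
    stop(sprintf("series too short: %d timepoints with 2 x %d trimmed",
                 nt, trim))
  keep <- (trim + 1L):(nt - trim)
  n <- nrow(values[[1]])
  pairs <- edgePairs(n)
  ns <- length(values)
  dfc <- matrix(NA_real_, ns, nrow(pairs), dimnames = list(ids, NULL))
  meta <- setNames(numeric(ns), ids)
  ntk <- length(keep)
  sdFac <- if (identical(sdType, "population"))
    sqrt((ntk - 1) / ntk) else 1
  for (s in seq_len(ns)) {
    filt <- applyGainCols(detrendCols(t(values[[s]])), gain2)
    z <- analyticCols(filt)[keep, , drop = FALSE]
    phi <- t(Arg(z))
    r <- pmin(Mod(colMeans(exp(1i * phi))), 1)
    meta[s] <- sd(r) * sdFac
    d <- abs(phi[pairs[, 1], , drop = FALSE] -
               phi[pairs[, 2], , drop = FALSE]) %% (2 * pi)
    C <- 1 - pmin(d, 2 * pi - d) / pi
    mu <- rowMeans(C)
    sdv <- sqrt(rowSums((C - mu)^2) / (ntk - 1)) * sdFac
    cv <- sdv / mu
    cv[mu <= 1e-6] <- NA_real_
    dfc[s, ] <- cv
  }
  list(dfc = dfc, dfcSums = rowSums(dfc), metastability = meta)
}

#' Build a surrogate ensemble of dFC summaries
#'
#' Generates `nSurrogates` phase-randomized copies of the cohort (common
#' rotation across nodes within a subject, independent across subjects)
#' and pushes each through [dfcSummary()] - the same pipeline applied to
#' the real data. Per-subject dFC sums are kept for all subjects; full
#' subject x edge dFC matrices are kept only for `refSubjects` (the
#' reference group of the per-edge test) to bound memory.
#'
#' @param panel a [TimeSeriesPanel-class] (unfiltered).
#' @param nSurrogates surrogate count (1000 is a practical default; the
#'   full-scale analysis uses 10000).
#' @param lowHz,highHz,trim,sdType downstream pipeline settings.
#' @param seed integer seed.
#' @param refSubjects subject ids whose edge-level surrogate dFC is kept
#'   (default: all subjects).
#' @return a [SurrogateEnsemble-class].
#' @export
surrogateEnsemble <- function(panel, nSurrogates = 1000L, lowHz = 0.04,
                              highHz = 0.07, trim = 10L, sdType = "sample",
                              seed = 1L,
                              refSubjects = subjectIds(panel)) {
  stopifnot(is(panel, "TimeSeriesPanel"))
  if (!anyNA(panel@band))
    warning("panel is already band-passed; surrogates should be built ",
            "from the unfiltered series")
  nSurrogates <- as.integer(nSurrogates)
  refIdx <- match(refSubjects, subjectIds(panel))
  if (anyNA(refIdx)) stop("unknown reference subject id(s)")
  ns <- nSubjects(panel)
  ne <- nEdges(nNodes(panel))
  gain2 <- filterGain2Band(lowHz, highHz, trSeconds(panel),
                           nTimepoints(panel))
  dfcSums <- matrix(NA_real_, nSurrogates, ns,
                    dimnames = list(NULL, subjectIds(panel)))
  refDfc <- array(NA_real_, c(nSurrogates, length(refIdx), ne))
  set.seed(as.integer(seed))
  ids <- subjectIds(panel)
  for (s in seq_len(nSurrogates)) {
    vals <- lapply(panel@values, rotatePhasesCommon)
    smry <- dfcSummaryCore(vals, ids, gain2, trim, sdType)
    dfcSums[s, ] <- smry$dfcSums
    refDfc[s, , ] <- smry$dfc[refIdx, , drop = FALSE]
  }
  new("SurrogateEnsemble", dfcSums = dfcSums, refDfc = refDfc,
      refSubjects = subjectIds(panel)[refIdx],
      nSurrogates = nSurrogates, seed = as.integer(seed))
}

## internal: gain vector for the configured band (shared with filter.R)
filterGain2Band <- function(lowHz, highHz, trSec, nt, order = 4L) {
  bf <- butterBand(lowHz, highHz, trSec, order)
  filterGain2(bf$b, bf$a, nt)
}

oneSampleT <- function(x, mu = 0) {
  n <- length(x)
  (mean(x) - mu) / (sd(x) / sqrt(n))
}

#' Whole-brain surrogate test: detection-probability curve
#'
#' For each population mean `mu` on a grid from 0 (weak dynamics) to the
#' maximum surrogate dFC sum (strong dynamics), a one-sample t statistic
#' `T(mu)` of the real per-subject dFC sums against `mu` is compared with
#' the matching surrogate statistics `T*_s(mu)`; the p-value at `mu` is
#' 1 minus the fraction of surrogates with `T > T*` (strict inequality).
#' Small p across the grid indicates genuine temporal dynamics
#' detectable at that effect size.
#'
#' @param dfcSums numeric, per-subject dFC sums of the real cohort.
#' @param surrogateSums surrogate x subject matrix of dFC sums, or a
#'   [SurrogateEnsemble-class].
#' @param muGrid increasing grid of population means; default 50 points
#'   spanning `[0, max(surrogateSums)]`.
#' @return data.frame with `mu`, `tStat` and `p`.
#' @export
wholeBrainDynamicsCurve <- function(dfcSums, surrogateSums,
                                    muGrid = NULL) {
  if (is(surrogateSums, "SurrogateEnsemble"))
    surrogateSums <- surrogateSums@dfcSums
  if (length(dfcSums) < 2L) stop("need >= 2 subjects")
  if (is.null(muGrid))
    muGrid <- seq(0, max(surrogateSums), length.out = 50L)
  if (length(muGrid) == 0L) stop("muGrid must be non-empty")
  if (is.unsorted(muGrid)) stop("muGrid must be increasing")
  n <- length(dfcSums)
  m <- mean(dfcSums); se <- sd(dfcSums) / sqrt(n)
  ms <- rowMeans(surrogateSums)
  ses <- apply(surrogateSums, 1, sd) / sqrt(ncol(surrogateSums))
  tReal <- (m - muGrid) / se
  p <- vapply(seq_along(muGrid), function(i) {
    tSur <- (ms - muGrid[i]) / ses
    1 - mean(tReal[i] > tSur)
  }, numeric(1))
  data.frame(mu = muGrid, tStat = tReal, p = p)
}

#' Per-edge surrogate test for temporal dynamics in a reference group
#'
#' For each edge, a one-sample t statistic of the reference group's dFC
#' values against 0 is computed in the real data (`T_e`) and in every
#' surrogate dataset (`T*_es`); the per-edge p-value is 1 minus the
#' proportion of surrogates with `T_e > T*_es`. (The test against a mean
#' of zero makes every |T| large for a positive-valued metric; the
#' discriminative content is the comparison of T with its surrogate
#' distribution.)
#'
#' @param groupDfc subject x edge dFC matrix for the reference group
#'   (e.g. the healthiest subjects), or a [ConnectivityExperiment-class].
#' @param surrogateDfc surrogate x subject x edge array for the same
#'   subjects, or a [SurrogateEnsemble-class] whose `refSubjects` cover
#'   the group.
#' @return data.frame with `edge`, `tStat` and `p` (NA with a warning at
#'   zero-variance edges).
#' @export
edgeDynamicsTest <- function(groupDfc, surrogateDfc) {
  if (is(groupDfc, "ConnectivityExperiment"))
    groupDfc <- edgeValues(groupDfc)
  if (is(surrogateDfc, "SurrogateEnsemble")) {
    ens <- surrogateDfc
    if (!is.null(rownames(groupDfc)) &&
        all(rownames(groupDfc) %in% ens@refSubjects)) {
      keep <- match(rownames(groupDfc), ens@refSubjects)
      surrogateDfc <- ens@refDfc[, keep, , drop = FALSE]
    } else {
      surrogateDfc <- ens@refDfc
    }
  }
  if (dim(surrogateDfc)[3] != ncol(groupDfc) ||
      dim(surrogateDfc)[2] != nrow(groupDfc))
    stop("surrogate array must be surrogate x subject x edge, matching ",
         "the real group matrix")
  n <- nrow(groupDfc)
  mu <- colMeans(groupDfc)
  sdv <- apply(groupDfc, 2, sd)
  tReal <- mu / (sdv / sqrt(n))
  bad <- sdv == 0
  if (any(bad)) {
    warning(sprintf("%d edge(s) have zero within-group variance; p undefined",
                    sum(bad)))
    tReal[bad] <- NA_real_
  }
  xp <- aperm(surrogateDfc, c(2, 1, 3))               # subj x S x E
  muS <- colMeans(xp)                                 # S x E
  sdS <- sqrt(pmax(colSums(xp^2) - n * muS^2, 0) / (n - 1))
  tSur <- muS / (sdS / sqrt(n))
  p <- 1 - colMeans(sweep(tSur, 2, tReal, function(ts, tr) tr > ts))
  p[bad] <- NA_real_
  data.frame(edge = seq_along(tReal), tStat = tReal, p = p)
}
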