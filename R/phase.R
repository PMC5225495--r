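## Analytic-signal (Hilbert) transform and instantaneous phase/envelope.

## Analytic signal per column (time in rows): z = x + i * H[x], computed
## by zeroing negative frequencies in the DFT (factor 2 on positive
## frequencies; DC and Nyquist untouched).
analyticCols <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2L == 0L) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and envelope via the analytic signal
#'
#' Extends each node series x(t) to its analytic signal
#' z(t) = x(t) + i H\[x(t)\] (H the Hilbert transform, computed by FFT),
#' so that x(t) = a(t) cos(phi(t)) with envelope a(t) = |z(t)| and phase
#' phi(t) = arg z(t) wrapped to (-pi, pi]. The first and last `trim`
#' timepoints (default 10) are removed from both phase and envelope to
#' minimize transform border effects.
#'
#' The decomposition is only physically meaningful for narrowband input;
#' a warning is issued if the panel has not passed through
#' [bandpassFilter()].
#'
#' @param x a [TimeSeriesPanel-class].
#' @param trim points removed from each end (default 10).
#' @return a [PhasePanel-class] with `nTimepoints(x) - 2 * trim` points.
#' @examples
#' tt <- seq(0, by = 2.638, length.out = 300)
#' p <- timeSeriesPanel(list(rbind(cos(2 * pi * 0.05 * tt))), 2.638)
#' ph <- suppressWarnings(analyticPhase(p))
#' @name analyticPhase
NULL

#' @rdname analyticPhase
setMethod("analyticPhase", "TimeSeriesPanel", function(x, trim = 10L) {
  trim <- as.integer(trim)
  if (trim < 0L) stop("trim must be nonnegative")
  if (nTimepoints(x) <= 2L * trim)
    stop(sprintf("series too short: %d timepoints with 2 x %d trimmed",
                 nTimepoints(x), trim))
  if (anyNA(x@band))
    warning("panel does not record a band-pass; the analytic-signal ",
            "decomposition assumes narrowband input")
  keep <- (trim + 1L):(nTimepoints(x) - trim)
  ph <- vector("list", nSubjects(x))
  env <- vector("list", nSubjects(x))
  for (s in seq_len(nSubjects(x))) {
    z <- analyticCols(t(x@values[[s]]))
    z <- t(z)[, keep, drop = FALSE]
    ph[[s]] <- Arg(z)
    env[[s]] <- Mod(z)
  }
  new("PhasePanel", phase = ph, envelope = env, trim = trim,
      trSeconds = trSeconds(x), nodeLabels = nodeLabels(x),
      subjectIds = subjectIds(x))
})

#' Temporal signal-to-noise ratio
#'
#' tSNR = temporal mean / temporal standard deviation, per node, with the
#' per-subject value the mean over nodes. Zero-variance nodes are
#' excluded from the subject mean with a warning. A data-quality index
#' computed on the raw (unfiltered) series.
#'
#' @param x a [TimeSeriesPanel-class].
#' @return a list with `perNode` (subject x node matrix) and `perSubject`
#'   (named numeric).
#' @examples
#' p <- timeSeriesPanel(list(rbind(100 + rnorm(200, sd = 10))), 2.638)
#' tsnr(p)$perSubject
#' @name tsnr
NULL

#' @rdname tsnr
setMethod("tsnr", "TimeSeriesPanel", function(x) {
  perNode <- do.call(rbind, lapply(x@values, function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    out <- mu / sdv
    out[sdv == 0] <- NA_real_
    out
  }))
  dimnames(perNode) <- list(subjectIds(x), nodeLabels(x))
  if (anyNA(perNode))
    warning("zero-variance node(s) excluded from subject-mean tSNR")
  list(perNode = perNode,
       perSubject = rowMeans(perNode, na.rm = TRUE))
})

## Wrap angles to (-pi, pi].
wrapPhase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
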