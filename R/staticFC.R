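## Session-averaged coupling: L1-regularized partial correlations.
##
## The sparse precision (inverse covariance) matrix is estimated by the
## graphical lasso:
##   max_Theta  log det Theta - tr(S Theta) - lambda ||Theta||_1
## solved by block coordinate descent over columns (each column update is
## a lasso regression solved by coordinate descent). Partial correlations
## follow as p_ij = -Theta_ij / sqrt(Theta_ii Theta_jj).

## One lasso subproblem: minimize 1/2 b' W11 b - s12' b + lambda |b|_1.
lassoCD <- function(W11, s12, lambda, beta0, tol = 1e-8, maxit = 1000L) {
  p <- length(s12)
  beta <- beta0
  for (it in seq_len(maxit)) {
    delta <- 0
    for (k in seq_len(p)) {
      r <- s12[k] - sum(W11[k, -k] * beta[-k])
      bk <- sign(r) * max(abs(r) - lambda, 0) / W11[k, k]
      delta <- max(delta, abs(bk - beta[k]))
      beta[k] <- bk
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical-lasso precision estimate
#'
#' L1-penalized Gaussian maximum-likelihood estimate of the inverse
#' covariance matrix (all entries penalized), via Friedman-style block
#' coordinate descent. At `lambda = 0` the estimate reduces to the direct
#' inverse of `S` (rejected if singular).
#'
#' @param S sample covariance (or correlation) matrix.
#' @param lambda nonnegative L1 penalty.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance (relative to the average off-diagonal of `S`).
#' @param maxit maximum outer sweeps.
#' @return list with `precision` (Theta) and `covariance` (its inverse W).
#' @export
graphicalLasso <- function(S, lambda, tol = 1e-6, maxit = 200L) {
  p <- nrow(S)
  stopifnot(isSymmetric(unname(S), tol = 1e-8), lambda >= 0)
  if (lambda == 0) {
    Theta <- tryCatch(solve(S), error = function(e)
      stop("covariance is singular at lambda = 0; increase the penalty ",
           "or supply more timepoints"))
    return(list(precision = Theta, covariance = S))
  }
  W <- S + lambda * diag(p)
  B <- matrix(0, p - 1L, p)   # lasso coefficients per column
  sOff <- mean(abs(S[upper.tri(S)]))
  thresh <- tol * max(sOff, .Machine$double.eps)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      beta <- lassoCD(W[idx, idx, drop = FALSE], S[idx, j], lambda, B[, j])
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - Wold)[upper.tri(W)]) < thresh) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(
      "graphical lasso did not converge in %d sweeps at lambda = %g",
      maxit, lambda))
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta22
    Theta[idx, j] <- -B[, j] * theta22
  }
  Theta <- (Theta + t(Theta)) / 2
  list(precision = Theta, covariance = W)
}

precisionToPartial <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 1
  P
}

#' Regularized partial correlations of one subject's node series
#'
#' Standardizes each node series to zero mean and unit variance, estimates
#' a sparse precision matrix by [graphicalLasso()], and converts it to
#' partial correlations p_ij = -Theta_ij / sqrt(Theta_ii Theta_jj). The
#' L1 penalty forces small, potentially noisy conditional associations to
#' exactly zero.
#'
#' @param x node x time numeric matrix, or a [TimeSeriesPanel-class]
#'   (one [EdgeVector-class] per subject).
#' @param lambda nonnegative L1 penalty on the standardized scale
#'   (default 0.1).
#' @param ... passed to [graphicalLasso()].
#' @return an [EdgeVector-class] of partial correlations in canonical
#'   upper-triangle order (or a list of them for a panel).
#' @examples
#' x <- matrix(rnorm(4 * 500), 4, 500)
#' partialCorrelation(x, lambda = 0)
#' @name partialCorrelation
NULL

#' @rdname partialCorrelation
setMethod("partialCorrelation", "matrix", function(x, lambda = 0.1, ...) {
  n <- nrow(x)
  nt <- ncol(x)
  if (nt <= n)
    warning(sprintf(
      "only %d timepoints for %d nodes; the covariance may be unstable",
      nt, n))
  xs <- x - rowMeans(x)
  sdv <- sqrt(rowSums(xs^2) / (nt - 1))
  if (any(sdv == 0)) stop("zero-variance node; cannot standardize")
  xs <- xs / sdv
  S <- tcrossprod(xs) / (nt - 1)
  Theta <- graphicalLasso(S, lambda, ...)$precision
  P <- precisionToPartial(Theta)
  edgeVector(symToEdge(P), metric = "pcor", nNodes = n)
})

#' @rdname partialCorrelation
setMethod("partialCorrelation", "TimeSeriesPanel",
  function(x, lambda = 0.1, ...) {
    out <- lapply(x@values, partialCorrelation, lambda = lambda, ...)
    names(out) <- subjectIds(x)
    out
  })

#' Fisher z transformation
#'
#' `z = atanh(r)`: the variance-stabilizing standardization applied to
#' (partial) correlations before group modelling. Odd and monotone;
#' rejects |r| >= 1.
#'
#' @param r correlation value(s) in (-1, 1).
#' @return transformed value(s).
#' @examples
#' fisherZ(c(0, 0.5, -0.9))
#' @export
fisherZ <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1))
    stop("fisherZ requires |r| < 1")
  atanh(r)
}

#' Assemble a cohort's ConnectivityExperiment
#'
#' `connectivityExperiment()` packs a subject x edge matrix plus cohort
#' covariates into a [ConnectivityExperiment-class] (edges in rows,
#' subjects in columns). `sfcCohort()` computes it from raw series: one
#' regularized partial-correlation fit per subject, Fisher z applied, in
#' canonical edge order (325 edges for 26 nodes).
#'
#' @param edgeMatrix subject x edge numeric matrix.
#' @param metric metric tag (`"sfc_z"`, `"dfc_cv"`).
#' @param nNodes node count.
#' @param cohort optional data.frame with `subject_id`, `group` and the
#'   covariates `age`, `sex`, `headcoil`, `motion` (rows matched to the
#'   edge matrix by position).
#' @return a [ConnectivityExperiment-class].
#' @export
connectivityExperiment <- function(edgeMatrix, metric, nNodes,
                                   cohort = NULL) {
  nNodes <- as.integer(nNodes)
  if (ncol(edgeMatrix) != nEdges(nNodes))
    stop(sprintf("expected %d edge columns for %d nodes, got %d",
                 nEdges(nNodes), nNodes, ncol(edgeMatrix)))
  pairs <- edgePairs(nNodes)
  rd <- S4Vectors::DataFrame(node_i = pairs[, 1], node_j = pairs[, 2])
  rownames(rd) <- sprintf("edge_%04d", seq_len(nrow(pairs)))
  cd <- if (is.null(cohort)) {
    S4Vectors::DataFrame(row.names = rownames(edgeMatrix))
  } else {
    if (nrow(cohort) != nrow(edgeMatrix))
      stop("cohort table and edge matrix disagree on subject count")
    S4Vectors::DataFrame(cohort, row.names = cohort$subject_id)
  }
  a <- t(edgeMatrix)
  rownames(a) <- rownames(rd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(a), metric), rowData = rd, colData = cd,
    metadata = list(metric = metric, nNodes = nNodes))
  new("ConnectivityExperiment", se)
}

#' @rdname connectivityExperiment
#' @param panel a [TimeSeriesPanel-class].
#' @param lambda L1 penalty for [partialCorrelation()].
#' @export
sfcCohort <- function(panel, lambda = 0.1, cohort = NULL) {
  stopifnot(is(panel, "TimeSeriesPanel"))
  pc <- partialCorrelation(panel, lambda = lambda)
  z <- do.call(rbind, lapply(pc, function(ev) {
    v <- edgeValues(ev)
    ## regularized partial correlations can hit +-1 only in degenerate
    ## duplicated-node data; clip just inside the domain
    v <- pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)
    fisherZ(v)
  }))
  rownames(z) <- subjectIds(panel)
  connectivityExperiment(z, metric = "sfc_z", nNodes = nNodes(panel),
                         cohort = cohort)
}
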