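## Synthetic cohorts with known ground truth.
##
## Two generators: (1) noisy Kuramoto phase oscillators with natural
## frequencies inside the band of interest and a global coupling strength
## that controls synchrony (and thereby metastability); (2) a stationary
## multivariate linear Gaussian AR(1) process whose distribution is
## invariant to Fourier phase randomization, i.e. a process with matched
## auto-/cross-correlation but no genuine time-varying coupling.

## Integrate one subject's phases by Euler-Maruyama and emit
## x_k(t) = sin(theta_k(t)) + measurement noise, sampled every TR.
## Assumes the RNG state is already set by the caller.
simulateKuramotoSubject <- function(nNodes, nTimepoints, trSec, freqBand,
                                    couplingMatrix, noiseSd, phaseNoiseSd,
                                    nSubsteps = 20L) {
  dt <- trSec / nSubsteps
  omega <- 2 * pi * runif(nNodes, freqBand[1], freqBand[2])
  theta <- runif(nNodes, -pi, pi)
  sqdt <- sqrt(dt)
  x <- matrix(NA_real_, nNodes, nTimepoints)
  hasCoupling <- any(couplingMatrix != 0)
  for (t in seq_len(nTimepoints)) {
    for (s in seq_len(nSubsteps)) {
      if (hasCoupling) {
        st <- sin(theta); ct <- cos(theta)
        drift <- omega + ct * drop(couplingMatrix %*% st) -
          st * drop(couplingMatrix %*% ct)
      } else {
        drift <- omega
      }
      theta <- theta + dt * drift
      if (phaseNoiseSd > 0)
        theta <- theta + phaseNoiseSd * sqdt * rnorm(nNodes)
    }
    x[, t] <- sin(theta)
  }
  if (noiseSd > 0)
    x <- x + noiseSd * matrix(rnorm(length(x)), nrow(x))
  x
}

checkCouplingMatrix <- function(couplingMatrix, nNodes) {
  if (!is.matrix(couplingMatrix) || nrow(couplingMatrix) != nNodes ||
      ncol(couplingMatrix) != nNodes)
    stop("coupling matrix must be nNodes x nNodes")
  if (!isSymmetric(unname(couplingMatrix), tol = 1e-10))
    stop("coupling matrix must be symmetric")
  if (any(couplingMatrix < 0))
    stop("coupling weights must be nonnegative")
  if (any(diag(couplingMatrix) != 0))
    stop("coupling matrix must have a zero diagonal")
  invisible(TRUE)
}

## All-to-all coupling at global strength K with the mean-field 1/N scaling.
uniformCoupling <- function(K, nNodes) {
  m <- matrix(K / nNodes, nNodes, nNodes)
  diag(m) <- 0
  m
}

#' Simulate a cohort of coupled phase oscillators
#'
#' Integrates `dtheta_k/dt = omega_k + sum_j K_kj sin(theta_j - theta_k)`
#' plus Wiener phase noise by Euler-Maruyama at an internal step of
#' TR/`nSubsteps`, with natural frequencies drawn uniformly so that
#' `omega_k / 2pi` lies in the configured band, and emits
#' `x_k(t) = sin(theta_k(t))` plus Gaussian measurement noise at every TR.
#' Global coupling K tunes synchrony: K = 0 leaves independent drifting
#' oscillators, very large K locks all phases (order parameter near 1,
#' metastability near 0), and intermediate K near the critical coupling
#' maximizes metastability.
#'
#' @param config a [SimulationConfig-class].
#' @param couplingMatrix nonnegative symmetric node x node weight matrix
#'   with zero diagonal; default: all-to-all at the first configured
#'   group's K with 1/N scaling.
#' @param seed integer seed (deterministic output).
#' @param nSubsteps internal integration substeps per TR; must be >= 10
#'   (an internal step above TR/10 under-resolves the band's cycles and
#'   is rejected).
#' @return a [TimeSeriesPanel-class] with `config@nSubjects` subjects.
#' @examples
#' cfg <- simulationConfig(nSubjects = 2, nNodes = 4, nTimepoints = 60)
#' simulateKuramotoPanel(cfg, seed = 1)
#' @export
simulateKuramotoPanel <- function(config, couplingMatrix = NULL,
                                  seed = config@seed, nSubsteps = 20L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (nSubsteps < 10L)
    stop("internal step exceeds TR/10; use nSubsteps >= 10")
  if (is.null(couplingMatrix))
    couplingMatrix <- uniformCoupling(config@couplingByGroup[1],
                                      config@nNodes)
  checkCouplingMatrix(couplingMatrix, config@nNodes)
  set.seed(as.integer(seed))
  vals <- lapply(seq_len(config@nSubjects), function(s)
    simulateKuramotoSubject(config@nNodes, config@nTimepoints,
                            config@trSeconds, config@freqBand,
                            couplingMatrix, config@noiseSd,
                            config@phaseNoiseSd, nSubsteps))
  timeSeriesPanel(vals, trSeconds = config@trSeconds)
}

#' Simulate a stationary linear null cohort
#'
#' A multivariate Gaussian AR(1) process: innovations with instantaneous
#' cross-covariance `(1 - a^2) * Sigma` so the stationary cross-covariance
#' is exactly `Sigma`, and lag-1 autocorrelation `a` per node. Being a
#' stationary linear Gaussian process, its distribution is invariant to
#' Fourier phase randomization - it carries matched auto- and
#' cross-correlations but no genuine time-varying coupling, making it the
#' null cohort for the surrogate-based dynamics tests.
#'
#' @param config a [SimulationConfig-class].
#' @param crossCovariance symmetric positive-definite node x node matrix
#'   (default identity).
#' @param arCoefficient AR(1) coefficient in (-1, 1).
#' @param seed integer seed.
#' @return a [TimeSeriesPanel-class] with `config@nSubjects` subjects.
#' @examples
#' cfg <- simulationConfig(nSubjects = 2, nNodes = 4, nTimepoints = 60)
#' simulateStationaryNull(cfg, seed = 1)
#' @export
simulateStationaryNull <- function(config, crossCovariance = NULL,
                                   arCoefficient = 0.3,
                                   seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (abs(arCoefficient) >= 1)
    stop("arCoefficient must lie in (-1, 1)")
  n <- config@nNodes
  if (is.null(crossCovariance)) crossCovariance <- diag(n)
  if (!isSymmetric(unname(crossCovariance), tol = 1e-10))
    stop("cross-covariance must be symmetric")
  L <- tryCatch(chol(crossCovariance), error = function(e)
    stop("cross-covariance must be positive definite"))
  set.seed(as.integer(seed))
  nt <- config@nTimepoints
  innovScale <- sqrt(1 - arCoefficient^2)
  vals <- lapply(seq_len(config@nSubjects), function(s) {
    x <- matrix(NA_real_, n, nt)
    state <- drop(crossprod(L, rnorm(n)))   # stationary start
    for (t in seq_len(nt)) {
      state <- arCoefficient * state +
        innovScale * drop(crossprod(L, rnorm(n)))
      x[, t] <- state
    }
    x
  })
  timeSeriesPanel(vals, trSeconds = config@trSeconds)
}

groupAgeMeans <- function(groups) {
  known <- c(AD = 71.5, MCI = 63.5, SCI = 63.6)
  if (all(groups %in% names(known))) return(known[groups])
  setNames(seq(64, 72, length.out = length(groups)), groups)[groups]
}

groupAgeSds <- function(groups) {
  known <- c(AD = 7.9, MCI = 11.1, SCI = 9.6)
  if (all(groups %in% names(known))) return(known[groups])
  setNames(rep(9, length(groups)), groups)[groups]
}

#' Generate a full synthetic cohort with covariates
#'
#' One Kuramoto panel per subject, with each subject's global coupling K
#' drawn around its group's configured strength (10% Gaussian jitter),
#' plus a covariate table emulating a memory-clinic study design:
#' group-dependent age means (71.5 / 63.5 / 63.6 years for AD / MCI /
#' SCI), balanced sex, a mostly 8-channel head-coil dummy and log-normal
#' in-scanner motion. The age imbalance deliberately exercises downstream
#' covariate adjustment.
#'
#' @param config a [SimulationConfig-class]; one panel group per entry of
#'   `couplingByGroup`, each with `config@nSubjects` subjects.
#' @param seed integer seed.
#' @param nSubsteps see [simulateKuramotoPanel()].
#' @return list with `panel` (a [TimeSeriesPanel-class]) and `cohort`
#'   (data.frame `subject_id`, `group`, `age`, `sex`, `headcoil`,
#'   `motion`).
#' @examples
#' cfg <- simulationConfig(nSubjects = 3, nNodes = 6, nTimepoints = 80)
#' co <- generateCohort(cfg, seed = 7)
#' table(co$cohort$group)
#' @export
generateCohort <- function(config, seed = config@seed, nSubsteps = 20L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  groups <- names(config@couplingByGroup)
  if (length(groups) == 0L || config@nSubjects < 1L)
    stop("couplingByGroup must name at least one non-empty group")
  set.seed(as.integer(seed))
  ageMu <- groupAgeMeans(groups)
  ageSd <- groupAgeSds(groups)
  vals <- list()
  rows <- list()
  idx <- 0L
  for (g in groups) {
    K <- config@couplingByGroup[[g]]
    for (s in seq_len(config@nSubjects)) {
      idx <- idx + 1L
      Ks <- max(0, K * (1 + 0.1 * rnorm(1)))
      vals[[idx]] <- simulateKuramotoSubject(
        config@nNodes, config@nTimepoints, config@trSeconds,
        config@freqBand, uniformCoupling(Ks, config@nNodes),
        config@noiseSd, config@phaseNoiseSd, nSubsteps)
      rows[[idx]] <- data.frame(
        subject_id = sprintf("sub_%03d", idx),
        group = g,
        age = rnorm(1, ageMu[[g]], ageSd[[g]]),
        sex = rbinom(1, 1, 0.5),
        headcoil = rbinom(1, 1, 0.73),
        motion = rlnorm(1, log(0.1), 0.4)
      )
    }
  }
  cohort <- do.call(rbind, rows)
  panel <- timeSeriesPanel(vals, trSeconds = config@trSeconds,
                           subjectIds = cohort$subject_id)
  list(panel = panel, cohort = cohort)
}
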