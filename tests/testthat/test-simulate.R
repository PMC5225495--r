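# Coupled-oscillator and stationary-null generators.

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nNodes = 1), "nNodes")
  expect_error(simulationConfig(nTimepoints = 30), "trim")
  expect_error(simulationConfig(freqBand = c(0.04, 0.3)), "Nyquist|freqBand")
  expect_error(simulationConfig(couplingByGroup = c(A = -1)), "nonnegative")
  expect_error(simulationConfig(couplingByGroup = 0.5), "named")
  expect_error(simulationConfig(noiseSd = -0.1), "noiseSd")
})

test_that("simulators are deterministic given a seed", {
  cfg <- simulationConfig(nSubjects = 2, nNodes = 5, nTimepoints = 60)
  a <- simulateKuramotoPanel(cfg, seed = 41)
  b <- simulateKuramotoPanel(cfg, seed = 41)
  expect_identical(panelValues(a), panelValues(b))
  expect_false(identical(panelValues(simulateKuramotoPanel(cfg, seed = 42)),
                         panelValues(a)))
  n1 <- simulateStationaryNull(cfg, seed = 43)
  n2 <- simulateStationaryNull(cfg, seed = 43)
  expect_identical(panelValues(n1), panelValues(n2))
})

test_that("uncoupled noiseless oscillators emit pure in-band sinusoids", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 2, nTimepoints = 500,
                          couplingByGroup = c(G = 0), noiseSd = 0,
                          phaseNoiseSd = 0)
  pan <- simulateKuramotoPanel(cfg, seed = 44)
  ph <- suppressWarnings(analyticPhase(pan, trim = 10))
  for (k in 1:2) {
    env <- envelopes(ph)[[1]][k, ]
    keep <- interior(length(env), 20)
    expect_lt(max(abs(env[keep] - 1)), 0.02)           # constant amplitude
    dphi <- diff(phases(ph)[[1]][k, ])
    slope <- mean((dphi + pi) %% (2 * pi) - pi) / TR
    expect_gt(slope / (2 * pi), 0.039)                 # frequency in band
    expect_lt(slope / (2 * pi), 0.071)
    expect_lt(sd((dphi + pi) %% (2 * pi) - pi), 0.01)  # constant frequency
  }
})

test_that("identical frequencies with strong coupling reach full synchrony", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 8, nTimepoints = 202,
                          freqBand = c(0.0549, 0.0551),
                          couplingByGroup = c(G = 3), noiseSd = 0,
                          phaseNoiseSd = 0)
  pan <- simulateKuramotoPanel(cfg, seed = 45, nSubsteps = 40)
  ph <- suppressWarnings(analyticPhase(pan, trim = 10))
  r <- kuramotoOrder(ph)[[1]]
  late <- r[(length(r) %/% 2):length(r)]               # past the transient
  expect_gt(mean(late), 0.99)
  expect_lt(metastability(late), 0.01)
})

test_that("near-critical coupling maximizes metastability over replicates", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 26, nTimepoints = 202)
  meta <- sapply(c(0, 0.12, 1.2), function(K) {
    vapply(1:20, function(s) {
      pan <- simulateKuramotoPanel(cfg, phasedyn:::uniformCoupling(K, 26),
                                   seed = 7000 + 61 * s + round(100 * K))
      dfcSummary(pan)$metastability
    }, numeric(1))
  })
  expect_gt(mean(meta[, 2]), mean(meta[, 1]))          # above K = 0
  expect_gt(mean(meta[, 2]), mean(meta[, 3]))          # above 10x critical
})

test_that("coupling matrix and step-size preconditions are enforced", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 3, nTimepoints = 60)
  asym <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(simulateKuramotoPanel(cfg, asym), "symmetric")
  neg <- matrix(-0.1, 3, 3); diag(neg) <- 0
  expect_error(simulateKuramotoPanel(cfg, neg), "nonnegative")
  dg <- matrix(0, 3, 3); diag(dg) <- 1
  expect_error(simulateKuramotoPanel(cfg, dg), "diagonal")
  expect_error(simulateKuramotoPanel(cfg, nSubsteps = 5), "TR/10")
})

test_that("stationary null matches its target second-order structure", {
  # white noise: near-zero cross-correlations at study length
  cfg <- simulationConfig(nSubjects = 1, nNodes = 26, nTimepoints = 202)
  w <- panelValues(simulateStationaryNull(cfg, arCoefficient = 0,
                                          seed = 46))[[1]]
  cc <- cor(t(w))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.22)
  # AR(1): lag-1 autocorrelation ~ 0.9 at 5000 points
  cfgL <- simulationConfig(nSubjects = 1, nNodes = 4, nTimepoints = 5000)
  x <- panelValues(simulateStationaryNull(cfgL, arCoefficient = 0.9,
                                          seed = 47))[[1]]
  ac1 <- vapply(1:4, function(i) cor(x[i, -1], x[i, -5000]), numeric(1))
  expect_true(all(abs(ac1 - 0.9) < 0.1))
  # instantaneous cross-covariance: r(1,2) ~ 0.5 at 5000 points
  Sig <- diag(4); Sig[1, 2] <- Sig[2, 1] <- 0.5
  y <- panelValues(simulateStationaryNull(cfgL, crossCovariance = Sig,
                                          arCoefficient = 0.3,
                                          seed = 48))[[1]]
  expect_lt(abs(cor(y[1, ], y[2, ]) - 0.5), 0.1)
  expect_lt(max(abs(cor(y[3, ], y[4, ]))), 0.1)
})

test_that("non-positive-definite cross-covariance is rejected", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 3, nTimepoints = 60)
  bad <- matrix(1, 3, 3)                               # rank 1
  expect_error(simulateStationaryNull(cfg, crossCovariance = bad),
               "positive definite")
})

test_that("generateCohort produces grouped panels with covariates", {
  cfg <- simulationConfig(nSubjects = 4, nNodes = 6, nTimepoints = 80)
  co <- generateCohort(cfg, seed = 49)
  expect_identical(nSubjects(co$panel), 12L)
  expect_identical(sort(unique(co$cohort$group)), c("AD", "MCI", "SCI"))
  expect_identical(co$cohort$subject_id, subjectIds(co$panel))
  expect_true(all(is.finite(co$cohort$age)))
  expect_true(all(co$cohort$motion > 0))
  expect_true(all(co$cohort$headcoil %in% 0:1))
  # deterministic regeneration
  co2 <- generateCohort(cfg, seed = 49)
  expect_identical(panelValues(co$panel), panelValues(co2$panel))
  expect_identical(co$cohort, co2$cohort)
  # AD group is older on average by design (check at larger n)
  cfg2 <- simulationConfig(nSubjects = 40, nNodes = 2, nTimepoints = 50)
  big <- generateCohort(cfg2, seed = 50)
  mu <- tapply(big$cohort$age, big$cohort$group, mean)
  expect_gt(mu["AD"], mu["MCI"])
})

test_that("single-group cohorts are built but group tests refuse them", {
  cfg <- simulationConfig(nSubjects = 4, nNodes = 4, nTimepoints = 80,
                          couplingByGroup = c(ONLY = 0.1))
  co <- generateCohort(cfg, seed = 51)
  expect_identical(unique(co$cohort$group), "ONLY")
  expect_error(groupDesign(co$cohort, reference = "SCI"), "not present")
  des <- groupDesign(co$cohort, reference = "ONLY")
  expect_error(nbs(matrix(rnorm(4 * 6), 4), des, nPerm = 100),
               "two diagnosis groups")
  expect_error(metastabilityMultinomial(rnorm(4), des),
               "two diagnosis groups")
})

test_that("genuinely dynamic cohorts deflate dFC sums versus matched nulls", {
  # coupling episodes raise mean C(t), so the CV-based dFC of a truly
  # dynamic cohort sits BELOW a correlation-matched stationary null
  cfg <- simulationConfig(nSubjects = 4, nNodes = 12, nTimepoints = 202)
  diffs <- vapply(1:10, function(r) {
    pan <- simulateKuramotoPanel(cfg, phasedyn:::uniformCoupling(0.14, 12),
                                 seed = 300 + r)
    km <- mean(dfcSummary(pan)$dfcSums)
    S <- Reduce(`+`, lapply(panelValues(pan), function(m) cov(t(m)))) / 4
    ar <- mean(vapply(panelValues(pan), function(m)
      mean(vapply(1:12, function(i) cor(m[i, -1], m[i, -202]), numeric(1))),
      numeric(1)))
    nul <- simulateStationaryNull(cfg, crossCovariance = S,
                                  arCoefficient = ar, seed = 600 + r)
    km - mean(dfcSummary(nul)$dfcSums)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.8)
})
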