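# Kuramoto order parameter, metastability, pairwise coupling, dFC CV.

test_that("Kuramoto order parameter hits its closed-form values", {
  expect_equal(kuramotoOrder(cbind(c(0.7, 0.7, 0.7))), 1)       # aligned
  expect_equal(kuramotoOrder(cbind(c(0, pi / 2, pi, 3 * pi / 2))), 0,
               tolerance = 1e-12)                               # balanced
  expect_equal(kuramotoOrder(cbind(c(0, pi / 2))), sqrt(2) / 2,
               tolerance = 1e-12)                               # |1+i|/2
  expect_error(kuramotoOrder(matrix(0, 1, 5)), "2 nodes")
})

test_that("metastability is the sample SD of R(t)", {
  expect_identical(metastability(rep(0.7, 50)), 0)
  r <- rep(c(0.4, 0.6), 100)
  expect_equal(metastability(r), sd(r))
  expect_equal(metastability(r), 0.1003, tolerance = 1e-3)
  set.seed(31)
  expect_equal(metastability(r), metastability(sample(r)))      # order-free
  expect_error(metastability(0.5), "2 timepoints")
  rp <- rep(c(0.4, 0.6), 100)
  expect_equal(metastability(rp, sdType = "population"),
               sd(rp) * sqrt(199 / 200))
})

test_that("pairwise coupling C = 1 - dphi/pi with circular distance", {
  C1 <- pairwiseCoupling(cbind(c(1.2, 1.2)))@coupling
  expect_equal(C1[1, 1], 1)                                     # in phase
  C0 <- pairwiseCoupling(cbind(c(0, pi)))@coupling
  expect_equal(C0[1, 1], 0)                                     # anti-phase
  Ch <- pairwiseCoupling(cbind(c(0, pi / 2)))@coupling
  expect_equal(Ch[1, 1], 0.5)
  # wrap-around: phases -3 and 3 are 2*pi - 6 apart, not 6
  Cw <- pairwiseCoupling(cbind(c(-3, 3)))@coupling
  expect_equal(Cw[1, 1], 1 - (2 * pi - 6) / pi, tolerance = 1e-12)
  expect_equal(Cw[1, 1], 0.9099, tolerance = 1e-4)
})

test_that("coupling is symmetric in the pair and invariant to global shift", {
  set.seed(32)
  phi <- matrix(runif(5 * 40, -pi, pi), 5, 40)
  tr1 <- pairwiseCoupling(phi)@coupling
  # pair symmetry: swapping node labels permutes edges consistently
  perm <- c(2, 1, 3, 4, 5)
  tr2 <- pairwiseCoupling(phi[perm, ])@coupling
  pairs <- edgePairs(5)
  remap <- edgeIndex(pmin(perm[pairs[, 1]], perm[pairs[, 2]]),
                     pmax(perm[pairs[, 1]], perm[pairs[, 2]]), 5)
  expect_equal(tr2[remap, ], tr1, tolerance = 1e-12)
  # global phase shift leaves both C and R unchanged
  shifted <- phasedyn:::wrapPhase(phi + 1.234)
  expect_lt(max(abs(pairwiseCoupling(shifted)@coupling - tr1)), 1e-10)
  expect_lt(max(abs(kuramotoOrder(shifted) - kuramotoOrder(phi))), 1e-10)
  expect_true(all(tr1 >= 0 & tr1 <= 1))
  expect_true(all(kuramotoOrder(phi) >= 0 & kuramotoOrder(phi) <= 1))
})

test_that("dFC coefficient of variation matches closed forms", {
  n <- 4
  constC <- new("CouplingTrajectory",
                coupling = matrix(0.8, nEdges(n), 100), nNodes = 4L)
  expect_equal(edgeValues(dfcCV(constC)), rep(0, nEdges(n)))
  alt <- matrix(rep(c(0.5, 1), 91), nEdges(n), 182, byrow = TRUE)
  altC <- new("CouplingTrajectory", coupling = alt, nNodes = 4L)
  got <- edgeValues(dfcCV(altC))
  oracle <- sd(rep(c(0.5, 1), 91)) / 0.75
  expect_equal(got, rep(oracle, nEdges(n)), tolerance = 1e-12)
  expect_equal(oracle, 0.3343, tolerance = 1e-3)
  # near-zero mean coupling is NA, never silently zero
  zeroC <- new("CouplingTrajectory",
               coupling = matrix(1e-9, nEdges(n), 50), nNodes = 4L)
  expect_warning(bad <- dfcCV(zeroC), "undefined")
  expect_true(all(is.na(edgeValues(bad))))
})

test_that("phase-locked oscillators have near-zero dFC CV", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 4, nTimepoints = 202,
                          freqBand = c(0.0549, 0.0551),
                          couplingByGroup = c(G = 3), noiseSd = 0,
                          phaseNoiseSd = 0)
  pan <- simulateKuramotoPanel(cfg, seed = 33, nSubsteps = 40)
  d <- dfcSummary(pan)
  expect_lt(max(d$dfc), 0.02)
})

test_that("dynamicsCohort stacks states, edges and sums consistently", {
  set.seed(34)
  x <- matrix(rnorm(26 * 202), 26, 202)
  panel <- timeSeriesPanel(list(x, x), TR)
  ph <- analyticPhase(bandpassFilter(panel))
  dyn <- dynamicsCohort(ph)
  expect_identical(ncol(edgeValues(dyn$dfc)), 325L)
  expect_identical(edgeMetric(dyn$dfc), "dfc_cv")
  expect_equal(dyn$summary$dfc_sum,
               unname(rowSums(edgeValues(dyn$dfc))))   # definition
  expect_equal(dyn$summary$metastability[1], dyn$summary$metastability[2])
  expect_equal(edgeValues(dyn$dfc)[1, ], edgeValues(dyn$dfc)[2, ])
  st <- dyn$states[[1]]
  expect_s4_class(st, "DynamicState")
  expect_true(all(st@orderParameter >= 0 & st@orderParameter <= 1))
  expect_equal(metastability(st), dyn$summary$metastability[1])
})

test_that("dFC carries information beyond sFC on stationary data", {
  # the CV metric falls monotonically with signed phase coupling, so a
  # weak-to-moderate negative edgewise association with sFC is intrinsic;
  # the check is that dFC is far from redundant with sFC (shared variance
  # well below half), not that the two are exactly orthogonal
  cfg <- simulationConfig(nSubjects = 10, nNodes = 12, nTimepoints = 202)
  pan <- simulateStationaryNull(cfg, arCoefficient = 0.3, seed = 35)
  sfc <- sfcCohort(pan, lambda = 0.05)
  dfc <- dfcSummary(pan)$dfc
  rs <- vapply(seq_len(nSubjects(pan)), function(s)
    cor(edgeValues(sfc)[s, ], dfc[s, ]), numeric(1))
  expect_lt(median(rs), 0)                # in-phase coupling deflates CV
  expect_lt(abs(median(rs)), 0.6)
  expect_lt(median(rs^2), 0.3)            # shared variance stays minor
})

test_that("metastability peaks at intermediate coupling", {
  cfg <- simulationConfig(nSubjects = 1, nNodes = 16, nTimepoints = 202)
  Ks <- c(0, 0.06, 0.12, 0.5, 1.2)
  meanMeta <- vapply(Ks, function(K) {
    mean(vapply(1:10, function(s) {
      pan <- simulateKuramotoPanel(cfg, phasedyn:::uniformCoupling(K, 16),
                                   seed = 5000 + 97 * s + round(1000 * K))
      dfcSummary(pan)$metastability
    }, numeric(1)))
  }, numeric(1))
  peak <- which.max(meanMeta)
  expect_true(peak > 1 && peak < length(Ks))          # interior maximum
  expect_gt(meanMeta[peak], meanMeta[1])
  expect_gt(meanMeta[peak], meanMeta[length(Ks)])
})
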