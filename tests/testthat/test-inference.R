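# Edgewise logistic regression, multinomial logit, NBS, node sums.

test_that("group designs validate their covariate structure", {
  set.seed(80)
  co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 5))
  d <- groupDesign(co)
  expect_identical(levels(d@outcome)[1], "SCI")
  expect_error(groupDesign(co[, -3], "SCI"), "age")
  expect_error(groupDesign(co, reference = "HC"), "not present")
  co2 <- co; co2$headcoil[1] <- 2
  expect_error(groupDesign(co2), "dummy")
  co3 <- co; co3$motion[2] <- NA
  expect_error(groupDesign(co3), "missing")
})

test_that("edgewise logistic finds a planted edge and flags degeneracy", {
  set.seed(81)
  hits <- vapply(1:20, function(r) {
    co <- makeCohort(rep(c("AD", "SCI"), each = 15))
    x <- matrix(rnorm(30 * 20), 30, 20)
    x[co$group == "AD", 1] <- x[co$group == "AD", 1] + 3   # 3 SD shift
    res <- edgewiseLogistic(x, groupDesign(co), c("SCI", "AD"))
    which.min(res$p) == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # constant edge is flagged, not estimated
  co <- makeCohort(rep(c("AD", "SCI"), each = 8))
  x <- matrix(rnorm(16 * 3), 16, 3); x[, 2] <- 7
  res <- edgewiseLogistic(x, groupDesign(co), c("SCI", "AD"))
  expect_true(is.na(res$estimate[2]) && !res$converged[2])
  expect_false(anyNA(res$estimate[c(1, 3)]))
  # perfectly separating edge reported as non-converged
  xs <- x; xs[, 1] <- ifelse(co$group == "AD", 10, -10) + rnorm(16, 0, .01)
  rs <- edgewiseLogistic(xs, groupDesign(co), c("SCI", "AD"))
  expect_false(rs$converged[1])
})

test_that("edgewise logistic p-values are uniform under label permutation", {
  set.seed(82)
  co <- makeCohort(rep(c("AD", "SCI"), each = 20))
  x <- matrix(rnorm(40 * 150), 40, 150)
  co$group <- sample(co$group)                     # break any association
  res <- edgewiseLogistic(x, groupDesign(co), c("SCI", "AD"))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("multinomial logit reduces to binary logistic on two groups", {
  set.seed(83)
  co <- makeCohort(rep(c("AD", "SCI"), each = 20))
  mets <- rnorm(40, ifelse(co$group == "AD", 0.9, 1.1), 0.4)
  d <- groupDesign(co)
  mn <- metastabilityMultinomial(mets, d)
  df <- cbind(co, metastability = mets,
              y = as.integer(co$group == "AD"))
  gl <- glm(y ~ metastability + sex + age + headcoil + motion,
            data = df, family = binomial())
  cf <- mn$coefficients
  expect_equal(cf$estimate[match(c("(Intercept)", "metastability"),
                                 cf$term)],
               unname(coef(gl)[c("(Intercept)", "metastability")]),
               tolerance = 1e-4)
  # McFadden pseudo-R2 agrees with the binomial deviance version
  glNull <- glm(y ~ 1, data = df, family = binomial())
  expect_equal(mn$pseudoR2, 1 - as.numeric(logLik(gl) / logLik(glNull)),
               tolerance = 1e-6)
  # and the edge-level LR p of a two-class design agrees with drop1 on glm

})

test_that("duplicating subjects keeps estimates and shrinks SEs", {
  set.seed(84)
  co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 10))
  mets <- rnorm(30, 1 + 0.2 * (co$group == "SCI") -
                  0.2 * (co$group == "AD"), 0.5)
  d1 <- groupDesign(co)
  m1 <- metastabilityMultinomial(mets, d1)
  co2 <- rbind(co, co); co2$subject_id <- sprintf("s%03d", 1:60)
  d2 <- groupDesign(co2)
  m2 <- metastabilityMultinomial(c(mets, mets), d2)
  expect_equal(m2$coefficients$estimate, m1$coefficients$estimate,
               tolerance = 1e-3)
  expect_equal(m2$coefficients$se / m1$coefficients$se,
               rep(1 / sqrt(2), nrow(m1$coefficients)), tolerance = 0.02)
  sub <- c(1:10, 11, 21:30)                        # single MCI subject
  expect_error(metastabilityMultinomial(
    mets[sub], groupDesign(co[sub, ])), ">= 2 subjects")
})

test_that("multinomial metastability test is calibrated under the null", {
  set.seed(85)
  rej <- vapply(1:50, function(r) {
    co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 15))
    mets <- rnorm(45, 0.12, 0.03)                  # independent of group
    mn <- metastabilityMultinomial(mets, groupDesign(co))
    any(subset(mn$coefficients, term == "metastability")$p < 0.05)
  }, logical(1))
  # two contrasts tested at 0.05 -> familywise null rate <~ 0.10;
  # 50 draws give a generous binomial envelope
  expect_lte(sum(rej), 12)
})

test_that("exhaustive NBS p-values sit on the enumeration grid", {
  set.seed(86)
  n <- 8
  co <- makeCohort(c("A", "A", "A", "B", "B", "B", "C", "C"))
  d <- groupDesign(co, reference = "A")
  x <- matrix(rnorm(n * nEdges(4)), n)
  x[co$group == "A", c(1, 2)] <- x[co$group == "A", c(1, 2)] + 4
  res <- nbs(x, d, primaryP = 0.3, nPerm = 100, seed = 1,
             permType = "exhaustive")
  expect_gt(length(res@components), 0)
  ps <- vapply(res@components, `[[`, numeric(1), "p")
  nf <- factorial(8)
  expect_true(all(ps >= 1 / nf))                   # identity included
  expect_true(all(abs(ps * nf - round(ps * nf)) < 1e-6))
  res2 <- nbs(x, d, primaryP = 0.3, nPerm = 100, seed = 99,
              permType = "exhaustive")             # seed-independent
  expect_identical(ps, vapply(res2@components, `[[`, numeric(1), "p"))
})

test_that("NBS is seed-deterministic and rejects bad designs", {
  set.seed(87)
  co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 5))
  d <- groupDesign(co)
  x <- matrix(rnorm(15 * nEdges(6)), 15)
  r1 <- nbs(x, d, nPerm = 200, seed = 9)
  r2 <- nbs(x, d, nPerm = 200, seed = 9)
  expect_identical(r1@fStats, r2@fStats)
  expect_identical(vapply(r1@components, `[[`, numeric(1), "p"),
                   vapply(r2@components, `[[`, numeric(1), "p"))
  expect_error(nbs(x, d, nPerm = 50), ">= 100")
  few <- c(1:2, 6:8, 11:13)                        # only 2 AD
  expect_error(nbs(x[few, ], groupDesign(co[few, ]), nPerm = 100),
               ">= 3 subjects")
  coBad <- co; coBad$headcoil <- 1                 # collinear with intercept
  expect_error(nbs(x, groupDesign(coBad), nPerm = 100), "rank-deficient")
})

test_that("NBS component p-values are invariant to node relabeling", {
  set.seed(88)
  co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 6))
  d <- groupDesign(co)
  nn <- 6
  x <- matrix(rnorm(18 * nEdges(nn)), 18)
  idx <- edgeIndex(c(1, 1, 2), c(2, 3, 3), nn)
  x[co$group == "AD", idx] <- x[co$group == "AD", idx] + 2.5
  r1 <- nbs(x, d, nPerm = 300, seed = 10)
  perm <- c(4, 6, 1, 3, 2, 5)                      # node relabeling
  pairs <- edgePairs(nn)
  remap <- edgeIndex(pmin(perm[pairs[, 1]], perm[pairs[, 2]]),
                     pmax(perm[pairs[, 1]], perm[pairs[, 2]]), nn)
  x2 <- x; x2[, remap] <- x
  r2 <- nbs(x2, d, nPerm = 300, seed = 10)
  expect_equal(sort(r1@fStats), sort(r2@fStats), tolerance = 1e-10)
  expect_identical(sort(vapply(r1@components, `[[`, numeric(1), "p")),
                   sort(vapply(r2@components, `[[`, numeric(1), "p")))
})

test_that("empty suprathreshold sets give an explicit empty result", {
  set.seed(89)
  co <- makeCohort(rep(c("AD", "MCI", "SCI"), each = 5))
  x <- matrix(rnorm(15 * 10, sd = 1e-3), 15)
  # force no suprathreshold edge by thresholding at a tiny primary p
  r <- nbs(x, groupDesign(co), primaryP = 1e-9, nPerm = 100, seed = 2)
  expect_length(r@components, 0)
  expect_equal(r@nodeFSums, rep(0, 5))
  expect_message(nodeContribution(r), "no significant component")
})

test_that("node contributions add F over incident significant edges", {
  mk <- function(edges, f, n, p = 0.01) {
    fs <- numeric(nEdges(n)); fs[edges] <- f
    new("NBSResult", fStats = fs, thresholdF = 1,
        components = list(list(edges = edges, size = length(edges),
                               intensity = sum(f), p = p)),
        nodeFSums = numeric(n), nNodes = as.integer(n), nPerm = 100L,
        seed = 1L, statistic = "extent")
  }
  # single edge (1,2) with F = 10
  r1 <- mk(edgeIndex(1, 2, 5), 10, 5)
  expect_equal(unname(nodeContribution(r1)), c(10, 10, 0, 0, 0))
  # star at node 2: edges (1,2), (2,3), (2,4) with F = 2, 3, 4
  r2 <- mk(edgeIndex(c(1, 2, 2), c(2, 3, 4), 5), c(2, 3, 4), 5)
  nc <- unname(nodeContribution(r2))
  expect_equal(nc[2], 9)                           # additivity at the hub
  expect_equal(sum(nc), 2 * 9)                     # handshake identity
  # averaging across metrics (e.g. sFC and dFC runs)
  avg <- nodeContribution(list(r1, r2))
  expect_equal(unname(avg), (unname(nodeContribution(r1)) + nc) / 2)
})
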