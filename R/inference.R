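## Covariate-adjusted group inference: edgewise pairwise logistic
## regressions, the metastability multinomial logit, and the
## network-based statistic (NBS) with permutation FWE control.

#' Group design: diagnosis outcome plus confound set
#'
#' Bundles the diagnosis labels with the standard confound set (sex, age,
#' head-coil dummy coded 1 for 8-channel, mean relative motion) used by
#' all group-level models.
#'
#' @param cohort data.frame with columns `group`, `sex`, `age`,
#'   `headcoil`, `motion` (e.g. from [generateCohort()]).
#' @param reference reference diagnosis label (default `"SCI"`).
#' @return a [GroupDesign-class].
#' @examples
#' co <- data.frame(group = rep(c("AD", "MCI", "SCI"), each = 4),
#'                  sex = rbinom(12, 1, 0.5), age = rnorm(12, 65, 8),
#'                  headcoil = rbinom(12, 1, 0.7),
#'                  motion = rlnorm(12, -2, 0.4))
#' groupDesign(co)
#' @export
groupDesign <- function(cohort, reference = "SCI") {
  need <- c("group", "sex", "age", "headcoil", "motion")
  miss <- setdiff(need, colnames(cohort))
  if (length(miss))
    stop(paste0("cohort table is missing column(s): ",
                paste(miss, collapse = ", ")))
  outcome <- factor(cohort$group)
  if (!reference %in% levels(outcome))
    stop(sprintf("reference group '%s' not present in the cohort",
                 reference))
  outcome <- stats::relevel(outcome, ref = reference)
  new("GroupDesign", outcome = outcome,
      covariates = data.frame(sex = cohort$sex, age = cohort$age,
                              headcoil = cohort$headcoil,
                              motion = cohort$motion),
      reference = reference)
}

designFrame <- function(design) {
  cbind(data.frame(outcome = design@outcome), design@covariates)
}

#' Edgewise pairwise logistic regressions
#'
#' For one diagnosis pair (e.g. AD vs SCI), fits one logistic regression
#' per edge: outcome = diagnosis, predictors = the edge's connectivity
#' value plus sex, age, headcoil and motion. Reported p-values are
#' unadjusted Wald tests; no multiple-testing correction is applied at
#' this stage (Bonferroni-adjusted significance can be judged from the
#' returned `p` against `0.05 / nEdges`). Degenerate edges (no variance)
#' and perfectly separated fits are flagged instead of reported as
#' converged estimates.
#'
#' The reported p is the likelihood-ratio test of the edge term (robust
#' where strong effects push Wald statistics into the Hauck-Donner
#' regime); the coefficient and its Wald SE are reported alongside.
#'
#' @param x subject x edge matrix or [ConnectivityExperiment-class].
#' @param design a [GroupDesign-class] covering the same subjects.
#' @param pair character(2), the two diagnosis labels to contrast; the
#'   second is modelled as the "positive" class.
#' @return data.frame with `edge`, `estimate`, `se`, `p`, `converged`.
#' @export
edgewiseLogistic <- function(x, design, pair) {
  if (is(x, "ConnectivityExperiment")) x <- edgeValues(x)
  stopifnot(is(design, "GroupDesign"), length(pair) == 2L)
  keep <- design@outcome %in% pair
  if (!all(pair %in% design@outcome))
    stop("both diagnosis labels must be present")
  y <- as.integer(design@outcome[keep] == pair[2])
  if (length(unique(y)) != 2L) stop("need subjects in both classes")
  df <- design@covariates[keep, , drop = FALSE]
  df$y <- y
  X <- x[keep, , drop = FALSE]
  out <- data.frame(edge = seq_len(ncol(X)), estimate = NA_real_,
                    se = NA_real_, p = NA_real_, converged = FALSE)
  fit0 <- suppressWarnings(
    glm(y ~ sex + age + headcoil + motion, data = df,
        family = binomial(), control = list(maxit = 100)))
  for (e in seq_len(ncol(X))) {
    v <- X[, e]
    if (sd(v) == 0) next   # no information at this edge
    df$edge <- v
    fit <- suppressWarnings(
      glm(y ~ edge + sex + age + headcoil + motion, data = df,
          family = binomial(), control = list(maxit = 100)))
    separated <- any(fit$fitted.values > 1 - 1e-8) ||
      any(fit$fitted.values < 1e-8)
    cf <- suppressWarnings(coef(summary(fit)))
    if (!"edge" %in% rownames(cf)) next
    out$estimate[e] <- cf["edge", "Estimate"]
    out$se[e] <- cf["edge", "Std. Error"]
    out$p[e] <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                              lower.tail = FALSE)
    out$converged[e] <- fit$converged && !separated
  }
  out
}

#' Multinomial logit of diagnosis on metastability
#'
#' Fits diagnosis ~ metastability + sex + age + headcoil + motion by
#' multinomial logistic regression with the chosen reference group, and
#' reports per-contrast coefficients, standard errors, Wald p-values,
#' McFadden's pseudo-R-squared and the model log-likelihood.
#'
#' @param metastability per-subject metastability values.
#' @param design a [GroupDesign-class].
#' @param reference reference diagnosis (default the design's).
#' @return list with `coefficients` (data.frame `contrast`, `term`,
#'   `estimate`, `se`, `p`), `pseudoR2`, `logLik` and `fit` (the
#'   underlying `nnet::multinom` object).
#' @export
metastabilityMultinomial <- function(metastability, design,
                                     reference = design@reference) {
  stopifnot(is(design, "GroupDesign"))
  df <- designFrame(design)
  df$outcome <- stats::relevel(df$outcome, ref = reference)
  df$metastability <- metastability
  tab <- table(df$outcome)
  if (nlevels(df$outcome) < 2L)
    stop("group tests need at least two diagnosis groups")
  if (any(tab < 2L))
    stop("every diagnosis class needs >= 2 subjects")
  fit <- nnet::multinom(
    outcome ~ metastability + sex + age + headcoil + motion,
    data = df, trace = FALSE, maxit = 10000, reltol = 1e-14)
  if (fit$convergence != 0)
    warning("multinomial logit hit its iteration limit; ",
            "estimates may be unstable (quasi-separated data?)")
  sm <- summary(fit)
  cf <- sm$coefficients
  se <- sm$standard.errors
  if (is.null(dim(cf))) {   # two outcome classes: single contrast
    cf <- matrix(cf, 1, dimnames = list(setdiff(levels(df$outcome),
                                                reference), names(cf)))
    se <- matrix(se, 1, dimnames = dimnames(cf))
  }
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  coefTab <- data.frame(
    contrast = rep(rownames(cf), ncol(cf)),
    term = rep(colnames(cf), each = nrow(cf)),
    estimate = as.vector(cf), se = as.vector(se), p = as.vector(p),
    row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  null <- nnet::multinom(outcome ~ 1, data = df, trace = FALSE,
                         maxit = 1000, reltol = 1e-12)
  list(coefficients = coefTab,
       pseudoR2 = 1 - ll / as.numeric(stats::logLik(null)),
       logLik = ll, fit = fit)
}

## Max connected-component statistic over suprathreshold edges via
## union-find (fast enough to sit inside the permutation loop).
maxComponentStat <- function(pairs, f, supra, statistic) {
  idx <- which(supra)
  if (!length(idx)) return(0)
  p <- pairs[idx, , drop = FALSE]
  parent <- seq_len(max(p))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(p))) {
    a <- find(p[r, 1]); b <- find(p[r, 2])
    if (a != b) parent[a] <- b
  }
  root <- vapply(p[, 1], find, integer(1))
  if (statistic == "extent") {
    max(tabulate(root))
  } else {
    max(tapply(f[idx], root, sum))
  }
}

allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

ancovaF <- function(Y, qrZ, qrX, q, df2) {
  rss0 <- colSums(qr.resid(qrZ, Y)^2)
  rss1 <- colSums(qr.resid(qrX, Y)^2)
  ((rss0 - rss1) / q) / (rss1 / df2)
}

#' Network-based statistic (NBS) with permutation FWE control
#'
#' Per edge, an ANCOVA F statistic for the diagnosis factor adjusting for
#' sex, age, headcoil and motion; edges exceeding the F quantile at the
#' primary p-level are assembled into connected components over the node
#' graph, and the family-wise-error corrected p-value of each component
#' compares its size (extent; or summed F, intensity) with the null
#' distribution of the maximum component statistic under permutation.
#' Nuisance covariates are handled by Freedman-Lane residual permutation:
#' rows of the covariates-only residuals are permuted and the fitted
#' covariate part added back before refitting.
#'
#' Random-permutation p-values use the (1 + b) / (1 + m) convention
#' (never exactly zero); exhaustive enumeration (all n! row permutations,
#' for small n) reports the plain proportion including the identity.
#'
#' @param x subject x edge matrix or [ConnectivityExperiment-class].
#' @param design a [GroupDesign-class] (>= 3 subjects per class).
#' @param primaryP primary edge threshold p-level (default 0.05).
#' @param nPerm number of random permutations (>= 100; default 5000).
#' @param seed integer seed for the permutation stream.
#' @param statistic component statistic: `"extent"` (edge count, default)
#'   or `"intensity"` (sum of suprathreshold F).
#' @param permType `"random"` (default) or `"exhaustive"` (n <= 9).
#' @return an [NBSResult-class].
#' @export
nbs <- function(x, design, primaryP = 0.05, nPerm = 5000L, seed = 1L,
                statistic = c("extent", "intensity"),
                permType = c("random", "exhaustive")) {
  statistic <- match.arg(statistic)
  permType <- match.arg(permType)
  if (is(x, "ConnectivityExperiment")) x <- edgeValues(x)
  stopifnot(is(design, "GroupDesign"))
  tab <- table(design@outcome)
  if (nlevels(design@outcome) < 2L)
    stop("group tests need at least two diagnosis groups")
  if (any(tab < if (permType == "random") 3L else 2L))
    stop("NBS needs >= 3 subjects per group (>= 2 under exhaustive ",
         "enumeration)")
  n <- nrow(x)
  if (length(design@outcome) != n)
    stop("design and edge matrix disagree on subject count")
  ne <- ncol(x)
  nNodesX <- as.integer(round((1 + sqrt(1 + 8 * ne)) / 2))
  if (nEdges(nNodesX) != ne)
    stop("edge count does not correspond to a whole node count")
  pairs <- edgePairs(nNodesX)
  Z <- cbind(1, as.matrix(design@covariates))
  G <- stats::model.matrix(~outcome, data = designFrame(design))
  X1 <- cbind(Z, G[, -1, drop = FALSE])
  qrZ <- qr(Z)
  qrX <- qr(X1)
  if (qrX$rank < ncol(X1)) stop("covariate matrix is rank-deficient")
  q <- qrX$rank - qrZ$rank
  df2 <- n - qrX$rank
  fObs <- ancovaF(x, qrZ, qrX, q, df2)
  thresholdF <- qf(1 - primaryP, q, df2)
  supra <- fObs > thresholdF
  components <- list()
  if (any(supra)) {
    g <- igraph::graph_from_edgelist(pairs[supra, , drop = FALSE],
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    edgeComp <- memb[pairs[supra, 1]]
    supraIdx <- which(supra)
    components <- lapply(unique(edgeComp), function(cid) {
      ed <- supraIdx[edgeComp == cid]
      list(edges = ed, size = length(ed), intensity = sum(fObs[ed]),
           p = NA_real_)
    })
  }
  ## Freedman-Lane null of the maximum component statistic
  fitZ <- qr.fitted(qrZ, x)
  resZ <- x - fitZ
  if (permType == "random") {
    if (nPerm < 100L) stop("use >= 100 random permutations")
    set.seed(as.integer(seed))
    perms <- lapply(seq_len(nPerm), function(i) sample.int(n))
  } else {
    if (n > 9L) stop("exhaustive enumeration limited to n <= 9 subjects")
    pm <- allPermutations(n)
    perms <- lapply(seq_len(nrow(pm)), function(i) pm[i, ])
    nPerm <- length(perms)
  }
  nullMax <- vapply(perms, function(pr) {
    Yp <- fitZ + resZ[pr, , drop = FALSE]
    fp <- ancovaF(Yp, qrZ, qrX, q, df2)
    maxComponentStat(pairs, fp, fp > thresholdF, statistic)
  }, numeric(1))
  for (i in seq_along(components)) {
    obs <- if (statistic == "extent") components[[i]]$size
           else components[[i]]$intensity
    components[[i]]$p <- if (permType == "random") {
      (1 + sum(nullMax >= obs)) / (1 + nPerm)
    } else {
      mean(nullMax >= obs)
    }
  }
  nodeFSums <- numeric(nNodesX)
  for (co in components) {
    if (!is.na(co$p) && co$p < 0.05) {
      for (ed in co$edges) {
        nodeFSums[pairs[ed, 1]] <- nodeFSums[pairs[ed, 1]] + fObs[ed]
        nodeFSums[pairs[ed, 2]] <- nodeFSums[pairs[ed, 2]] + fObs[ed]
      }
    }
  }
  new("NBSResult", fStats = fObs, thresholdF = thresholdF,
      components = components, nodeFSums = nodeFSums,
      nNodes = nNodesX, nPerm = as.integer(nPerm),
      seed = as.integer(seed), statistic = statistic)
}

#' Per-node summed-F contributions of significant NBS components
#'
#' For each node, the sum of edge F statistics over
#' significant-component edges incident to it - a measure of the node's
#' contribution to the detected subnetwork. Summing over nodes gives
#' exactly twice the component F total (each edge touches two nodes).
#' A list of results (e.g. the sFC and dFC runs) is averaged node-wise.
#'
#' @param result an [NBSResult-class], or a list of them to average.
#' @param alpha FWE significance level selecting components (default
#'   0.05).
#' @return named numeric, one value per node (zeros, with a message, if
#'   no component is significant).
#' @export
nodeContribution <- function(result, alpha = 0.05) {
  if (is.list(result) && !is(result, "NBSResult")) {
    mats <- lapply(result, nodeContribution, alpha = alpha)
    return(Reduce(`+`, mats) / length(mats))
  }
  stopifnot(is(result, "NBSResult"))
  pairs <- edgePairs(result@nNodes)
  out <- numeric(result@nNodes)
  sig <- Filter(function(co) !is.na(co$p) && co$p < alpha,
                result@components)
  if (!length(sig)) {
    message("no significant component at alpha = ", alpha,
            "; returning zeros")
  }
  for (co in sig) {
    for (ed in co$edges) {
      out[pairs[ed, 1]] <- out[pairs[ed, 1]] + result@fStats[ed]
      out[pairs[ed, 2]] <- out[pairs[ed, 2]] + result@fStats[ed]
    }
  }
  names(out) <- sprintf("node_%d", seq_along(out))
  out
}
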