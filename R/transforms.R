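# The thirteen benchmarked transformations of a read-count matrix.
# Seq (raw counts), Rel, RMP, AST, CLR, CSS, UQ, TMM, RLE, GMPR, VST, QMP,
# ACS, addressable through transformCounts() by their canonical tags.

.METHOD_REGISTRY <- data.frame(
  method = c("Seq", "Rel", "RMP", "AST", "CLR", "CSS", "GMPR", "UQ", "RLE",
             "TMM", "VST", "QMP", "ACS"),
  technique = c("none", rep("computational", 10), "experimental",
                "experimental"),
  transformation = c("none", "relative", "relative", "relative",
                     "compositional", "compositional", "compositional",
                     "compositional", "compositional", "compositional",
                     "compositional", "quantitative", "quantitative"),
  rarefaction = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE, FALSE),
  diversitySuitable = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                        TRUE, TRUE, FALSE, TRUE, TRUE),
  diversityNote = c("", "0:1 range", "", "0:1 range", "negative values",
                    "rounding data", "rounding data", "rounding data",
                    "rounding data", "rounding data", "negative values",
                    "", ""),
  requiresRounding = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                       TRUE, TRUE, FALSE, TRUE, TRUE),
  mayBeNegative = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, FALSE, FALSE),
  unit = c("reads", "proportion", "reads", "transformed", "log-ratio",
           "normalized", "normalized", "normalized", "normalized",
           "normalized", "normalized", "cells/g", "cells/g"),
  stringsAsFactors = FALSE)

#' The thirteen registered transformation tags
#' @return character vector of method abbreviations.
#' @export
transformMethods <- function() .METHOD_REGISTRY$method

#' Capability flags of a transformation
#'
#' Reports each method's classification (computational/experimental;
#' relative/compositional/quantitative), whether it involves a rarefaction
#' step, its suitability for richness-type diversity indices (with the
#' reason when unsuitable), whether values must be rounded before diversity
#' estimation, whether values may be negative, and the output unit.
#'
#' @param method a method tag from [transformMethods()].
#' @return one-row list of flags.
#' @export
methodFlags <- function(method) {
  i <- match(method, .METHOD_REGISTRY$method)
  if (is.na(i)) stop("unknown method: ", method)
  as.list(.METHOD_REGISTRY[i, ])
}

# ---- rarefaction -----------------------------------------------------------

# Multivariate hypergeometric draw: subsample `target` items without
# replacement from a vector of integer counts.
.rarefyVec <- function(counts, target) {
  tot <- sum(counts)
  out <- numeric(length(counts))
  k <- target; rem <- tot
  for (j in seq_along(counts)) {
    if (k <= 0) break
    if (counts[j] > 0) {
      out[j] <- stats::rhyper(1, counts[j], rem - counts[j], k)
      k <- k - out[j]
    }
    rem <- rem - counts[j]
  }
  out
}

#' Rarefy read counts to target depths
#'
#' Randomly downsamples each sample's reads to the requested total. The
#' default draws without replacement (multivariate hypergeometric: per-cell
#' counts never exceed the originals); with replacement, reads are
#' redrawn multinomially from the observed proportions.
#'
#' @param x a `SequenceExperiment` or a taxa x samples count matrix.
#' @param targetDepths single total or per-sample totals.
#' @param withReplacement logical; resample with replacement instead.
#' @param seed optional integer seed.
#' @return object of the same kind as `x` with rarefied counts.
#' @export
rarefy <- function(x, targetDepths, withReplacement = FALSE, seed = NULL) {
  isSE <- is(x, "SequenceExperiment")
  m <- if (isSE) assay(x, "reads") else .checkCountMatrix(as.matrix(x),
                                                         "reads")
  ns <- ncol(m)
  targetDepths <- rep_len(targetDepths, ns)
  lib <- colSums(m)
  if (!withReplacement && any(targetDepths > lib))
    stop("target depth exceeds available reads for sample(s) ",
         paste(which(targetDepths > lib), collapse = ", "),
         " (without replacement)")
  .withSeed(seed)
  out <- vapply(seq_len(ns), function(i) {
    if (withReplacement)
      stats::rmultinom(1, targetDepths[i], m[, i] / lib[i])[, 1]
    else if (targetDepths[i] == lib[i]) m[, i]
    else .rarefyVec(m[, i], targetDepths[i])
  }, numeric(nrow(m)))
  dimnames(out) <- dimnames(m)
  if (!isSE) return(out)
  SequenceExperiment(out, loads = loads(x), groups = sampleGroups(x),
                     scenario = scenario(x), roles = taxonRoles(x))
}

# ---- the transformations ---------------------------------------------------

#' Raw sequencing baseline (identity transformation)
#' @param x a `SequenceExperiment`.
#' @return a [TransformedExperiment-class] tagged `"Seq"`.
#' @export
transformSeq <- function(x) {
  stopifnot(is(x, "SequenceExperiment"))
  .TransformedExperiment(assay(x, "reads"), x, "Seq")
}

#' Relative microbiome profiling: rarefy to the minimum library size
#' @param x a `SequenceExperiment`.
#' @param seed optional integer seed.
#' @return a [TransformedExperiment-class] tagged `"RMP"`.
#' @export
transformRMP <- function(x, seed = NULL) {
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  r <- rarefy(m, min(colSums(m)), seed = seed)
  .TransformedExperiment(r, x, "RMP")
}

#' Relative proportions (total-sum scaling)
#' @param x a `SequenceExperiment`.
#' @return a [TransformedExperiment-class] tagged `"Rel"`; rows of the
#'   sample-wise proportions sum to 1.
#' @export
transformRel <- function(x) {
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero-sum sample; proportions undefined")
  .TransformedExperiment(sweep(m, 2, tot, "/"), x, "Rel")
}

#' Arcsine square-root transformation of proportions
#' @param x a `SequenceExperiment`.
#' @return a [TransformedExperiment-class] tagged `"AST"`; values in
#'   `[0, pi/2]`.
#' @export
transformAST <- function(x) {
  p <- assay(transformRel(x), "values")
  .TransformedExperiment(asin(sqrt(p)), x, "AST")
}

# Bayesian-multiplicative zero replacement with a uniform Dirichlet prior of
# strength `t` per cell: zeros get their posterior expectation, nonzero
# counts are multiplicatively shrunk so the sample total is preserved.
.zReplace <- function(m, t = 0.5) {
  K <- nrow(m)
  out <- vapply(seq_len(ncol(m)), function(i) {
    x <- m[, i]
    z <- x == 0
    if (!any(z)) return(x)
    N <- sum(x)
    repl <- N * t / (N + t * K)
    x[z] <- repl
    x[!z] <- x[!z] * (1 - sum(z) * repl / N)
    x
  }, numeric(K))
  dimnames(out) <- dimnames(m)
  out
}

#' Centered log-ratio transformation
#'
#' Zeros are imputed by Bayesian-multiplicative replacement (Dirichlet prior
#' strength `priorStrength` per cell; sample totals preserved), then each
#' count is log-ratioed to the geometric mean of its sample.
#'
#' @param x a `SequenceExperiment`.
#' @param priorStrength Dirichlet prior mass per unobserved cell.
#' @return a [TransformedExperiment-class] tagged `"CLR"`; every sample's
#'   values sum to 0.
#' @export
transformCLR <- function(x, priorStrength = 0.5) {
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  if (any(colSums(m) == 0)) stop("all-zero sample; CLR undefined")
  r <- .zReplace(m, priorStrength)
  lg <- log(r)
  vals <- sweep(lg, 2, colMeans(lg), "-")
  dimnames(vals) <- dimnames(m)
  .TransformedExperiment(vals, x, "CLR")
}

# Data-driven CSS percentile: the smallest quantile at which the per-sample
# cumulative-sum profiles start to disagree (median relative deviation from
# the across-sample median exceeding `threshold`), searched on a coarse
# grid; falls back to 0.5 when the profiles never destabilize.
.cssPercentile <- function(m, threshold = 0.1, grid = seq(0.25, 0.95, 0.05)) {
  for (p in grid) {
    den <- .cssDenominators(m, p, inclusive = TRUE)
    md <- stats::median(den)
    if (md > 0 && stats::median(abs(den - md)) / md > threshold)
      return(p)
  }
  0.5
}

.cssDenominators <- function(m, p, inclusive = TRUE) {
  vapply(seq_len(ncol(m)), function(i) {
    x <- m[, i]
    nz <- x[x > 0]
    if (!length(nz)) stop("sample ", i, " has no nonzero counts")
    q <- .q7(nz, p)
    s <- if (inclusive) sum(x[x <= q]) else sum(x[x < q])
    if (s <= 0) stop("cumulative sum up to the chosen percentile is zero ",
                     "for sample ", i)
    s
  }, numeric(1))
}

#' Cumulative sum scaling
#'
#' Counts are divided by the cumulative sum of each sample's counts up to a
#' percentile of its nonzero-count distribution (type-7 quantile), times a
#' fixed constant. The percentile is chosen per matrix by a data-driven
#' instability search unless given. The cumulative sum includes counts equal
#' to the quantile (`inclusive = TRUE`, the default convention; the strict
#' reading is available for comparison).
#'
#' @param x a `SequenceExperiment`.
#' @param percentile fixed percentile in (0, 1], or `NULL` for the
#'   data-driven choice.
#' @param inclusive include counts equal to the percentile value in the
#'   cumulative sum.
#' @param scalingConstant multiplier applied after division (default 1000).
#' @return a [TransformedExperiment-class] tagged `"CSS"` with the chosen
#'   percentile in `metadata()$cssPercentile`.
#' @export
transformCSS <- function(x, percentile = NULL, inclusive = TRUE,
                         scalingConstant = 1000) {
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  if (is.null(percentile)) percentile <- .cssPercentile(m)
  den <- .cssDenominators(m, percentile, inclusive)
  out <- .TransformedExperiment(sweep(m, 2, den / scalingConstant, "/"),
                                x, "CSS")
  metadata(out)$cssPercentile <- percentile
  out
}

#' Variance-stabilizing transformation for overdispersed counts
#'
#' Counts are scaled by median-of-ratios (RLE) size factors; per-taxon
#' method-of-moments dispersions are fitted with the parametric trend
#' `alpha(mu) = a1 / mu + a0` by iteratively reweighted regression, and the
#' closed-form variance-stabilizing transform for that trend is applied.
#' Output is on the log2-like scale and may be negative. If the asymptotic
#' dispersion cannot be estimated (a0 <= 0) the Poisson square-root
#' transform is used with a warning.
#'
#' @param x a `SequenceExperiment`.
#' @return a [TransformedExperiment-class] tagged `"VST"` with the fitted
#'   trend in `metadata()$dispersionTrend`.
#' @export
transformVST <- function(x) {
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  if (ncol(m) < 2) stop("VST needs at least 2 samples")
  f <- sizeFactorsRLE(m)
  sc <- sweep(m, 2, f, "/")
  mu <- rowMeans(sc)
  v <- apply(sc, 1, stats::var)
  ok <- mu > 0 & v > 0
  disp <- (v[ok] - mu[ok]) / mu[ok]^2
  use <- disp > 1e-8
  fit <- .fitDispersionTrend(mu[ok][use], disp[use])
  vals <- if (is.null(fit)) {
    warning("dispersion trend fit failed; using the Poisson square-root ",
            "transform")
    2 * sqrt(sc)
  } else {
    a0 <- fit["a0"]; a1 <- fit["a1"]
    log2((1 + a1 + 2 * a0 * sc +
            2 * sqrt(a0 * sc * (1 + a1 + a0 * sc))) / (4 * a0))
  }
  dimnames(vals) <- dimnames(m)
  out <- .TransformedExperiment(vals, x, "VST")
  metadata(out)$dispersionTrend <- fit
  metadata(out)$sizeFactors <- f
  out
}

# Robust fit of alpha = a0 + a1/mu by iteratively reweighted least squares
# with outlier down-weighting on the dispersion-mean cloud.
.fitDispersionTrend <- function(mu, disp, maxIter = 10) {
  if (length(mu) < 10) return(NULL)
  x <- 1 / mu
  w <- rep(1, length(mu))
  co <- c(a0 = NA, a1 = NA)
  for (it in seq_len(maxIter)) {
    fit <- stats::lm.wfit(cbind(1, x), disp, w)
    co <- fit$coefficients
    pred <- pmax(cbind(1, x) %*% co, 1e-8)
    ratio <- disp / pred
    wNew <- as.numeric(ratio < stats::quantile(ratio, 0.99)) / pred^2
    if (all(abs(wNew - w) < 1e-12)) break
    w <- wNew
  }
  a0 <- unname(co[1]); a1 <- unname(co[2])
  if (!is.finite(a0) || a0 <= 0) return(NULL)
  c(a0 = a0, a1 = max(a1, 0))
}

#' Quantitative microbiome profiling
#'
#' Samples are first rarefied (without replacement) to even sampling depth:
#' the per-sample sampling depth is the library size divided by the
#' microbial load, and every sample is downsized to the minimum depth times
#' its load. Rarefied compositions are then scaled by the estimated
#' microbial loads, yielding cell-count-scale values.
#'
#' Evenness is computed against the true (synthetic) loads by default, as in
#' quantitative profiling of simulated data; set `rarefyBy = "estimated"`
#' to use the noisy estimates instead.
#'
#' @param x a `SequenceExperiment`.
#' @param loads a [LoadEstimates-class] aligned with `x`.
#' @param rarefyBy which loads define the sampling depth.
#' @param seed optional integer seed.
#' @return a [TransformedExperiment-class] tagged `"QMP"`; sample sums equal
#'   the estimated loads (up to samples emptied by rarefaction).
#' @export
transformQMP <- function(x, loads, rarefyBy = c("true", "estimated"),
                         seed = NULL) {
  stopifnot(is(x, "SequenceExperiment"), is(loads, "LoadEstimates"))
  rarefyBy <- match.arg(rarefyBy)
  m <- assay(x, "reads")
  est <- estimatedLoads(loads)
  ref <- if (rarefyBy == "true") loads@trueLoads else est
  stopifnot(length(ref) == ncol(m))
  lib <- colSums(m)
  rate <- lib / ref
  target <- pmin(lib, round(min(rate) * ref))
  if (any(target < 1))
    stop("even sampling depth implies fewer than one read for sample(s) ",
         paste(which(target < 1), collapse = ", "))
  r <- rarefy(m, target, seed = seed)
  tot <- colSums(r)
  vals <- sweep(sweep(r, 2, tot, "/"), 2, est, "*")
  .TransformedExperiment(vals, x, "QMP", estimatedLoads = est)
}

#' Absolute count scaling
#'
#' Relative sequencing proportions of each sample are multiplied directly by
#' its estimated microbial load; no downsizing step.
#'
#' @param x a `SequenceExperiment`.
#' @param loads a [LoadEstimates-class] aligned with `x`.
#' @return a [TransformedExperiment-class] tagged `"ACS"`; sample sums equal
#'   the estimated loads exactly.
#' @export
transformACS <- function(x, loads) {
  stopifnot(is(x, "SequenceExperiment"), is(loads, "LoadEstimates"))
  est <- estimatedLoads(loads)
  p <- assay(transformRel(x), "values")
  .TransformedExperiment(sweep(p, 2, est, "*"), x, "ACS",
                         estimatedLoads = est)
}

#' Apply a transformation by its registry tag
#'
#' Dispatches to the individual `transform*` / `normalizeByFactors`
#' implementations. The quantitative methods (`QMP`, `ACS`) require load
#' estimates.
#'
#' @param x a `SequenceExperiment`.
#' @param method a tag from [transformMethods()].
#' @param loads a [LoadEstimates-class]; required for QMP and ACS.
#' @param seed optional integer seed (used by the rarefying methods).
#' @param ... passed on to the specific implementation.
#' @return a [TransformedExperiment-class].
#' @export
transformCounts <- function(x, method, loads = NULL, seed = NULL, ...) {
  if (!method %in% transformMethods()) stop("unknown method: ", method)
  if (method %in% c("QMP", "ACS") && is.null(loads))
    stop(method, " requires load estimates")
  switch(method,
         Seq = transformSeq(x),
         Rel = transformRel(x),
         RMP = transformRMP(x, seed = seed),
         AST = transformAST(x),
         CLR = transformCLR(x, ...),
         CSS = transformCSS(x, ...),
         UQ = normalizeByFactors(x, method = "UQ"),
         TMM = normalizeByFactors(x, method = "TMM"),
         RLE = normalizeByFactors(x, method = "RLE"),
         GMPR = normalizeByFactors(x, method = "GMPR"),
         VST = transformVST(x),
         QMP = transformQMP(x, loads, seed = seed, ...),
         ACS = transformACS(x, loads))
}
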