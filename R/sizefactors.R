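# Per-sample scaling-factor normalizations: upper-quartile (UQ), trimmed
# mean of M-values (TMM), relative log expression / median-of-ratios (RLE)
# and geometric mean of pairwise ratios (GMPR). Each is implemented from
# its published formula; tests compare them against independently coded
# brute-force versions and against the edgeR implementations.

.readsMatrix <- function(x) {
  if (is(x, "SequenceExperiment")) assay(x, "reads")
  else .checkCountMatrix(as.matrix(x), "reads")
}

.sizeFactors <- function(f, method, samples) {
  structure(stats::setNames(f, samples), method = method)
}

#' Upper-quartile size factors
#'
#' The factor of a sample is the 75 percent quantile of its nonzero counts
#' divided by its library size, rescaled so the factors have geometric
#' mean 1.
#'
#' @param x a `SequenceExperiment` or a taxa x samples count matrix.
#' @param p the quantile (default 0.75).
#' @return named numeric vector of positive factors with attribute
#'   `"method"`.
#' @export
sizeFactorsUQ <- function(x, p = 0.75) {
  m <- .readsMatrix(x)
  lib <- colSums(m)
  f <- vapply(seq_len(ncol(m)), function(i) {
    nz <- m[m[, i] > 0, i]
    if (!length(nz)) stop("sample ", i, " has no nonzero counts")
    .q7(nz, p) / lib[i]
  }, numeric(1))
  .sizeFactors(f / .geoMean(f), "UQ", colnames(m))
}

#' Relative-log-expression (median-of-ratios) size factors
#'
#' The geometric mean of each taxon across samples is the reference profile;
#' a sample's factor is the median of its count-to-reference ratios, taken
#' over taxa with a positive reference and a positive count in that sample.
#'
#' @param x a `SequenceExperiment` or a taxa x samples count matrix.
#' @return named numeric vector of positive factors with attribute
#'   `"method"`.
#' @export
sizeFactorsRLE <- function(x) {
  m <- .readsMatrix(x)
  gm <- exp(rowMeans(log(m)))          # zero whenever a taxon has any zero
  usable <- is.finite(gm) & gm > 0
  if (!any(usable))
    stop("no taxon has nonzero counts in every sample; RLE undefined")
  f <- vapply(seq_len(ncol(m)), function(i) {
    r <- m[usable, i] / gm[usable]
    r <- r[r > 0]
    if (!length(r)) stop("sample ", i, " has an empty ratio set")
    stats::median(r)
  }, numeric(1))
  .sizeFactors(f, "RLE", colnames(m))
}

#' Trimmed-mean-of-M-values size factors
#'
#' The reference is the sample whose upper quartile of depth-scaled counts
#' is closest to the mean upper quartile. For every other sample, log2
#' abundance ratios to the reference (M values) are computed over taxa
#' nonzero in both, doubly trimmed (30 percent on M, 5 percent on average
#' log abundance A by default), and averaged with precision weights from
#' the binomial asymptotic variance. Factors are rescaled to geometric
#' mean 1.
#'
#' @param x a `SequenceExperiment` or a taxa x samples count matrix.
#' @param trimM,trimA two-sided trim fractions for M and A values.
#' @return named numeric vector of positive factors with attributes
#'   `"method"` and `"reference"` (the reference sample index).
#' @export
sizeFactorsTMM <- function(x, trimM = 0.30, trimA = 0.05) {
  m <- .readsMatrix(x)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(i) .q7(m[, i] / lib[i], 0.75), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(i) {
    if (i == ref) return(1)
    .tmmPairFactor(m[, i], m[, ref], lib[i], lib[ref], trimM, trimA)
  }, numeric(1))
  out <- .sizeFactors(f / .geoMean(f), "TMM", colnames(m))
  attr(out, "reference") <- ref
  out
}

# One-vs-reference TMM factor: doubly trimmed, precision-weighted mean M.
.tmmPairFactor <- function(obs, refc, libObs, libRef, trimM, trimA) {
  keep <- obs > 0 & refc > 0
  if (!any(keep)) {
    warning("no taxa shared with the reference; factor set to 1")
    return(1)
  }
  o <- obs[keep]; r <- refc[keep]
  M <- log2((o / libObs) / (r / libRef))
  A <- 0.5 * log2((o / libObs) * (r / libRef))
  v <- (libObs - o) / (libObs * o) + (libRef - r) / (libRef * r)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  rkM <- rank(M); rkA <- rank(A)
  sel <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
  if (!any(sel)) {
    warning("trimming removed all taxa; factor set to 1")
    return(1)
  }
  2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
}

#' Geometric-mean-of-pairwise-ratios size factors
#'
#' For each ordered sample pair (i, j), the median of the count ratios
#' `c_i / c_j` over taxa nonzero in both samples is computed; the factor of
#' sample i is the geometric mean of its medians against all other samples.
#' Designed for zero-inflated count matrices; the factors absorb sequencing
#' depth, so normalized values are counts divided by the factor.
#'
#' @param x a `SequenceExperiment` or a taxa x samples count matrix.
#' @param minShared minimum number of shared nonzero taxa for a pair to be
#'   used.
#' @return named numeric vector of positive factors with attribute
#'   `"method"`.
#' @export
sizeFactorsGMPR <- function(x, minShared = 1) {
  m <- .readsMatrix(x)
  ns <- ncol(m)
  if (ns < 2) stop("GMPR needs at least 2 samples")
  nzero <- m > 0
  f <- numeric(ns)
  for (i in seq_len(ns)) {
    meds <- rep(NA_real_, ns)
    for (j in seq_len(ns)) {
      if (j == i) next
      sh <- nzero[, i] & nzero[, j]
      if (sum(sh) >= minShared)
        meds[j] <- stats::median(m[sh, i] / m[sh, j])
    }
    meds <- meds[!is.na(meds)]
    if (!length(meds))
      stop("sample ", i, " shares no nonzero taxa with any other sample")
    f[i] <- .geoMean(meds)
  }
  .sizeFactors(f, "GMPR", colnames(m))
}

#' Normalize counts by per-sample size factors
#'
#' Shared scaling step of the factor-based methods. For the edgeR-style
#' factors (UQ, TMM) the divisor is the effective library size
#' `factor x library size` and values are reported per million reads; for
#' the count-scale factors (RLE, GMPR) counts are divided by the factor
#' directly, staying on the count scale.
#'
#' @param x a `SequenceExperiment`.
#' @param factors size factors as returned by the `sizeFactors*` functions;
#'   computed from `method` when `NULL`.
#' @param method one of `"UQ"`, `"TMM"`, `"RLE"`, `"GMPR"`.
#' @return a [TransformedExperiment-class].
#' @export
normalizeByFactors <- function(x, factors = NULL,
                               method = c("UQ", "TMM", "RLE", "GMPR")) {
  method <- match.arg(method)
  stopifnot(is(x, "SequenceExperiment"))
  m <- assay(x, "reads")
  if (is.null(factors))
    factors <- switch(method, UQ = sizeFactorsUQ(m), TMM = sizeFactorsTMM(m),
                      RLE = sizeFactorsRLE(m), GMPR = sizeFactorsGMPR(m))
  if (any(factors <= 0)) stop("size factors must be positive")
  div <- if (method %in% c("UQ", "TMM"))
    factors * colSums(m) / 1e6 else factors
  vals <- sweep(m, 2, div, "/")
  .TransformedExperiment(vals, x, method)
}
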