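# Brute-force reference implementations, written independently of the
# package internals (plain loops, no shared helpers), used to verify the
# normalization formulas, the BH step-up and the confusion metrics.

# small random count matrix (taxa x samples) with some zeros
randomCounts <- function(nTaxa = 8, nSamples = 5, lambda = 30,
                         zeroProb = 0.2) {
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples)
  m[matrix(runif(nTaxa * nSamples) < zeroProb, nTaxa, nSamples)] <- 0
  # keep every sample and the RLE reference usable
  m[1, ] <- pmax(m[1, ], 1)
  m[2, ] <- pmax(m[2, ], 1)
  dimnames(m) <- list(paste0("taxon_", seq_len(nTaxa)),
                      paste0("sample_", seq_len(nSamples)))
  m
}

seFromMatrix <- function(m) SequenceExperiment(m)

bfGeoMean <- function(x) exp(mean(log(x)))

bfUQ <- function(m, p = 0.75) {
  f <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    nz <- sort(m[m[, i] > 0, i])
    # type-7 quantile by hand
    h <- (length(nz) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    q <- nz[lo] + (h - lo) * (nz[hi] - nz[lo])
    f[i] <- q / sum(m[, i])
  }
  f / bfGeoMean(f)
}

bfRLE <- function(m) {
  gm <- numeric(nrow(m))
  for (k in seq_len(nrow(m))) gm[k] <- bfGeoMean(m[k, ])  # 0 if any zero
  f <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    ratios <- c()
    for (k in seq_len(nrow(m)))
      if (is.finite(gm[k]) && gm[k] > 0 && m[k, i] > 0)
        ratios <- c(ratios, m[k, i] / gm[k])
    f[i] <- median(ratios)
  }
  f
}

bfGMPR <- function(m) {
  ns <- ncol(m)
  f <- numeric(ns)
  for (i in seq_len(ns)) {
    meds <- c()
    for (j in seq_len(ns)) {
      if (j == i) next
      ratios <- c()
      for (k in seq_len(nrow(m)))
        if (m[k, i] > 0 && m[k, j] > 0)
          ratios <- c(ratios, m[k, i] / m[k, j])
      if (length(ratios)) meds <- c(meds, median(ratios))
    }
    f[i] <- bfGeoMean(meds)
  }
  f
}

bfTMM <- function(m, trimM = 0.30, trimA = 0.05) {
  lib <- colSums(m)
  f75 <- numeric(ncol(m))
  for (i in seq_len(ncol(m)))
    f75[i] <- quantile(m[, i] / lib[i], 0.75, type = 7, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    if (i == ref) { f[i] <- 1; next }
    M <- A <- v <- c()
    for (k in seq_len(nrow(m))) {
      if (m[k, i] > 0 && m[k, ref] > 0) {
        pi <- m[k, i] / lib[i]; pr <- m[k, ref] / lib[ref]
        M <- c(M, log2(pi / pr))
        A <- c(A, 0.5 * log2(pi * pr))
        v <- c(v, (lib[i] - m[k, i]) / (lib[i] * m[k, i]) +
                 (lib[ref] - m[k, ref]) / (lib[ref] * m[k, ref]))
      }
    }
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[i] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f / bfGeoMean(f)
}

bfCSSDenom <- function(m, p, inclusive = TRUE) {
  den <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    nz <- sort(m[m[, i] > 0, i])
    h <- (length(nz) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    q <- nz[lo] + (h - lo) * (nz[hi] - nz[lo])
    s <- 0
    for (k in seq_len(nrow(m))) {
      keep <- if (inclusive) m[k, i] <= q else m[k, i] < q
      if (keep) s <- s + m[k, i]
    }
    den[i] <- s
  }
  den
}

# Benjamini-Hochberg step-up, literal definition
bfBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# confusion counts by explicit enumeration over a pair universe
bfConfusion <- function(universe, refSig, refSign, testSig, testSign) {
  tp <- fp <- fn <- tn <- disc <- 0
  for (u in universe) {
    rs <- refSig[[u]]; ts <- testSig[[u]]
    if (rs && ts) {
      if (!is.na(refSign[[u]]) && !is.na(testSign[[u]]) &&
          refSign[[u]] != testSign[[u]]) disc <- disc + 1 else tp <- tp + 1
    } else if (!rs && ts) fp <- fp + 1
    else if (rs && !ts) fn <- fn + 1
    else tn <- tn + 1
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn, discordant = disc,
       precision = tp / (tp + fp + disc),
       sensitivity = tp / (tp + fn + disc),
       fpr = (fp + disc) / (fp + disc + tn))
}

# tiny deterministic community for fast pipeline tests
tinyCommunity <- function(seed = 1, nSamples = 60, nTaxa = 40) {
  withr::with_seed(seed, {
    corr <- generateCorrelationMatrix(nTaxa, 0.9, c(0.05, 0.5))
    nb <- sampleNBParams(nTaxa)
    X <- sampleCopulaCommunity(corr, nb, nSamples)
    sc <- scaleToLoadRange(X)
    CommunityExperiment(t(sc$counts), scenario = "blooming",
                        loadScale = sc$scale)
  })
}
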