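# Closed-form examples and contracts of the thirteen transformations.

test_that("the method registry reproduces the published capability table", {
  expect_identical(transformMethods(),
                   c("Seq", "Rel", "RMP", "AST", "CLR", "CSS", "GMPR", "UQ",
                     "RLE", "TMM", "VST", "QMP", "ACS"))
  suitable <- vapply(transformMethods(),
                     function(m) methodFlags(m)$diversitySuitable,
                     logical(1))
  expect_identical(suitable[c("Seq", "RMP", "CSS", "RLE", "UQ", "TMM",
                              "GMPR", "QMP", "ACS")],
                   setNames(rep(TRUE, 9), c("Seq", "RMP", "CSS", "RLE", "UQ",
                                            "TMM", "GMPR", "QMP", "ACS")))
  expect_identical(suitable[c("Rel", "AST", "CLR", "VST")],
                   setNames(rep(FALSE, 4), c("Rel", "AST", "CLR", "VST")))
  expect_identical(methodFlags("CLR")$diversityNote, "negative values")
  expect_identical(methodFlags("Rel")$diversityNote, "0:1 range")
  expect_identical(methodFlags("CSS")$diversityNote, "rounding data")
  expect_true(methodFlags("VST")$mayBeNegative)
  expect_identical(methodFlags("QMP")$unit, "cells/g")
  expect_error(methodFlags("XYZ"), "unknown method")
})

test_that("rarefaction meets target depths and the hypergeometric mean", {
  m <- matrix(c(6, 3, 1, 10, 5, 5), 3, 2)
  se <- seFromMatrix(m)
  # identity at full depth
  r0 <- rarefy(m, colSums(m), seed = 1)
  expect_identical(r0, m)
  r <- rarefy(se, 5, seed = 2)
  expect_identical(unname(colSums(SummarizedExperiment::assay(r, "reads"))),
                   c(5, 5))
  expect_true(all(SummarizedExperiment::assay(r, "reads") <= m))
  expect_error(rarefy(m, 100), "exceeds")
  # multivariate hypergeometric expectation for (6,3,1) at depth 5
  draws <- vapply(1:4000, function(s)
    rarefy(matrix(c(6, 3, 1), 3, 1), 5, seed = s)[, 1], numeric(3))
  expect_equal(rowMeans(draws), c(3, 1.5, 0.5), tolerance = 0.04)
  # with replacement: multinomial resampling at any depth
  rw <- rarefy(m, 50, withReplacement = TRUE, seed = 3)
  expect_identical(unname(colSums(rw)), c(50, 50))
})

test_that("RMP rarefies to the minimum library size", {
  m <- randomCounts(10, 4, lambda = 60)
  tm <- transformRMP(seFromMatrix(m), seed = 4)
  expect_identical(unname(colSums(SummarizedExperiment::assay(tm, "values"))),
                   rep(min(colSums(m)), 4))
})

test_that("Rel and AST match their closed forms", {
  m <- matrix(c(2, 2, 1, 3), 2, 2)
  rel <- SummarizedExperiment::assay(transformRel(seFromMatrix(m)), "values")
  expect_equal(unname(rel[, 1]), c(0.5, 0.5))
  expect_equal(unname(colSums(rel)), c(1, 1))
  ast <- SummarizedExperiment::assay(transformAST(seFromMatrix(m)), "values")
  expect_equal(unname(ast[1, 1]), asin(sqrt(0.5)))
  # p = 0.25 -> pi/6; boundaries 0 and pi/2
  m2 <- matrix(c(1, 3, 0, 4), 2, 2)
  ast2 <- SummarizedExperiment::assay(transformAST(seFromMatrix(m2)), "values")
  expect_equal(unname(ast2[1, 1]), pi / 6)
  expect_equal(unname(ast2[, 2]), c(0, pi / 2))
  # scale invariance of proportions
  m3 <- m; m3[, 2] <- m3[, 2] * 7
  expect_equal(SummarizedExperiment::assay(transformRel(seFromMatrix(m3)),
                                           "values"), rel)
})

test_that("CLR matches the hand-computed example and sums to zero", {
  m <- matrix(c(1, 2, 4), 3, 1)
  clr <- SummarizedExperiment::assay(transformCLR(seFromMatrix(m)), "values")
  expect_equal(unname(clr[, 1]), c(-log(2), 0, log(2)))
  mz <- randomCounts(12, 6)
  clrz <- SummarizedExperiment::assay(transformCLR(seFromMatrix(mz)),
                                      "values")
  expect_equal(unname(colSums(clrz)), rep(0, 6), tolerance = 1e-9)
  # zero-free input: replacement is a no-op
  mnz <- matrix(c(3, 5, 9, 2, 8, 4), 3, 2)
  expect_equal(SummarizedExperiment::assay(transformCLR(seFromMatrix(mnz)),
                                           "values"),
               apply(mnz, 2, function(x) log(x) - mean(log(x))),
               ignore_attr = TRUE)
  # zero replacement preserves sample totals
  repl <- qmpbench:::.zReplace(mz, 0.5)
  expect_equal(colSums(repl), colSums(mz))
  expect_true(all(repl > 0))
})

test_that("CSS resolves the quantile convention against brute force", {
  x <- c(1, 2, 3, 4, 100)
  m <- matrix(x, 5, 1)
  # type-7 median of the nonzero counts is 3
  expect_equal(quantile(x, 0.5, type = 7, names = FALSE), 3)
  denInc <- qmpbench:::.cssDenominators(m, 0.5, inclusive = TRUE)
  denExc <- qmpbench:::.cssDenominators(m, 0.5, inclusive = FALSE)
  expect_equal(denInc, 6)   # counts <= 3
  expect_equal(denExc, 3)   # counts < 3 (the strict reading)
  mm <- randomCounts(9, 5)
  expect_equal(qmpbench:::.cssDenominators(mm, 0.6, TRUE),
               bfCSSDenom(mm, 0.6, TRUE))
  expect_equal(qmpbench:::.cssDenominators(mm, 0.6, FALSE),
               bfCSSDenom(mm, 0.6, FALSE))
  # percentile 1.0 reduces CSS to total-sum scaling (x constant)
  tmFull <- transformCSS(seFromMatrix(mm), percentile = 1)
  rel <- sweep(mm, 2, colSums(mm), "/")
  expect_equal(SummarizedExperiment::assay(tmFull, "values"), rel * 1000)
  # identical samples share the scaling denominator
  dup <- cbind(mm[, 1], mm[, 1]); rownames(dup) <- rownames(mm)
  tmDup <- transformCSS(seFromMatrix(dup), percentile = 0.5)
  v <- SummarizedExperiment::assay(tmDup, "values")
  expect_identical(v[, 1], v[, 2])
})

test_that("UQ factors match the hand example and normalize to geomean 1", {
  # nonzero counts (1,2,3,4): type-7 upper quartile 3.25
  m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2)
  f <- sizeFactorsUQ(m)
  expect_equal(qmpbench:::.q7(c(1, 2, 3, 4), 0.75), 3.25)
  # proportional samples get equal factors after depth scaling
  expect_equal(as.vector(f), c(1, 1))
  mm <- randomCounts()
  fm <- sizeFactorsUQ(mm)
  expect_equal(exp(mean(log(fm))), 1)
})

test_that("RLE factors match the hand example and are equivariant", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), 3, 2)
  f <- sizeFactorsRLE(m)
  expect_equal(as.vector(f), c(1 / sqrt(2), sqrt(2)))
  # all-identical samples: unit factors
  same <- matrix(rep(c(3, 7, 11), 3), 3, 3)
  expect_equal(as.vector(sizeFactorsRLE(same)), rep(1, 3))
  # scaling one sample by c multiplies its factor c-fold relative to the
  # others (the geometric-mean reference itself absorbs part of c)
  m2 <- m; m2[, 2] <- m2[, 2] * 5
  f2 <- sizeFactorsRLE(m2)
  expect_equal(as.vector(f2[2] / f2[1]), as.vector(f[2] / f[1]) * 5)
  # normalization equalizes the two proportional samples
  se <- seFromMatrix(m)
  v <- SummarizedExperiment::assay(normalizeByFactors(se, method = "RLE"),
                                   "values")
  expect_equal(v[, 1], v[, 2])
})

test_that("GMPR factors match the two-sample example and symmetry", {
  m <- matrix(c(3, 6, 9, 6, 12, 18), 3, 2)   # B = 2A
  f <- sizeFactorsGMPR(m)
  expect_equal(as.vector(f), c(0.5, 2))
  expect_equal(as.vector(sizeFactorsGMPR(cbind(m[, 1], m[, 1]))), c(1, 1))
  # taxon permutation leaves factors unchanged
  mm <- randomCounts()
  expect_equal(as.vector(sizeFactorsGMPR(mm[sample(nrow(mm)), ])),
               as.vector(sizeFactorsGMPR(mm)))
})

test_that("TMM is 1 for proportional samples and matches edgeR", {
  m <- randomCounts(40, 4, lambda = 100, zeroProb = 0.1)
  m[, 2] <- m[, 1] * 2   # proportional to sample 1
  f <- sizeFactorsTMM(m)
  ref <- attr(f, "reference")
  if (ref %in% c(1, 2)) {
    other <- setdiff(1:2, ref)
    expect_equal(unname(f[other] / f[ref]), 1, tolerance = 1e-10)
  }
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(as.vector(f), as.vector(fe), tolerance = 1e-6)
})

test_that("size factors match brute-force implementations on random toys", {
  for (s in 1:5) {
    m <- withr::with_seed(100 + s, randomCounts(8, 5, lambda = 40))
    expect_equal(as.vector(sizeFactorsUQ(m)), bfUQ(m), tolerance = 1e-6)
    expect_equal(as.vector(sizeFactorsRLE(m)), bfRLE(m), tolerance = 1e-6)
    expect_equal(as.vector(sizeFactorsGMPR(m)), bfGMPR(m), tolerance = 1e-6)
    expect_equal(as.vector(sizeFactorsTMM(m)), bfTMM(m), tolerance = 1e-6)
  }
})

test_that("transformations are invariant to single-sample rescaling", {
  m <- randomCounts(20, 6, lambda = 50, zeroProb = 0.15)
  m2 <- m; m2[, 3] <- m2[, 3] * 9
  # Rel / AST: strictly unchanged
  for (fn in list(transformRel, transformAST)) {
    vA <- SummarizedExperiment::assay(fn(seFromMatrix(m)), "values")
    vB <- SummarizedExperiment::assay(fn(seFromMatrix(m2)), "values")
    expect_equal(vB, vA, tolerance = 1e-10)
  }
  # CLR: strictly invariant on zero-free data (the Bayesian-multiplicative
  # zero replacement deliberately weighs pseudo-counts by sequencing depth,
  # so exact invariance holds only once no zeros need imputing)
  mz <- m + 1; mz2 <- mz; mz2[, 3] <- mz2[, 3] * 9
  expect_equal(SummarizedExperiment::assay(transformCLR(seFromMatrix(mz2)),
                                           "values"),
               SummarizedExperiment::assay(transformCLR(seFromMatrix(mz)),
                                           "values"), tolerance = 1e-10)
  # UQ: depth absorbed by factor x library size, output unchanged
  vA <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m), method = "UQ"), "values")
  vB <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m2), method = "UQ"), "values")
  expect_equal(vB, vA, tolerance = 1e-10)
  # TMM: invariant up to the depth-dependent precision weights
  vA <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m), method = "TMM"), "values")
  vB <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m2), method = "TMM"), "values")
  expect_equal(vB, vA, tolerance = 2e-3)
  # RLE: unchanged up to one global constant (the reference profile moves)
  vA <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m), method = "RLE"), "values")
  vB <- SummarizedExperiment::assay(
    normalizeByFactors(seFromMatrix(m2), method = "RLE"), "values")
  ratio <- vB[vA > 0] / vA[vA > 0]
  expect_lt(diff(range(ratio)), 1e-8)
  # GMPR: the rescaled sample's factor is exactly equivariant
  fA <- sizeFactorsGMPR(m); fB <- sizeFactorsGMPR(m2)
  expect_equal(as.vector(fB[3] / fA[3]), 9, tolerance = 1e-10)
})

test_that("VST is monotone, log2-asymptotic and close to DESeq2's", {
  # overdispersed NB counts with means spread over two decades
  m <- withr::with_seed(42, {
    mu <- rlnorm(150, 4, 1.2)
    matrix(rnbinom(150 * 10, mu = rep(mu, 10), size = 5), 150, 10,
           dimnames = list(paste0("taxon_", 1:150),
                           paste0("sample_", 1:10)))
  })
  tm <- transformVST(seFromMatrix(m))
  v <- SummarizedExperiment::assay(tm, "values")
  trend <- S4Vectors::metadata(tm)$dispersionTrend
  expect_true(trend["a0"] > 0)
  # strictly increasing in counts within a sample
  o <- order(m[, 1])
  expect_true(all(diff(v[o, 1][m[o, 1] > 0 & !duplicated(m[o, 1])]) > 0))
  # large-count differences approach log2 ratios of scaled counts
  a0 <- trend["a0"]; a1 <- trend["a1"]
  q <- c(1e4, 2e4) / 1
  vst <- log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) /
                (4 * a0))
  expect_equal(vst[2] - vst[1], 1, tolerance = 0.01)
  # a0 -> 0: the transform approaches a scaled sqrt on Poisson-like counts
  qs <- c(100, 400)
  smallA <- log2((1 + 2 * 1e-6 * qs +
                    2 * sqrt(1e-6 * qs * (1 + 1e-6 * qs))) / (4 * 1e-6))
  expect_equal(diff(smallA), diff(2 * sqrt(1e-6 * qs)) / log(2),
               tolerance = 0.02)
  skip_if_not_installed("DESeq2")
  dds <- DESeq2::DESeqDataSetFromMatrix(m, data.frame(row.names =
                                                        colnames(m)), ~1)
  vd <- SummarizedExperiment::assay(DESeq2::varianceStabilizingTransformation(
    dds, fitType = "parametric"))
  # same ordering and strong agreement up to the fitted-trend differences
  expect_gt(cor(as.vector(v), as.vector(vd)), 0.99)
})

test_that("QMP rarefies to even sampling depth and rescales to loads", {
  m <- matrix(rpois(20 * 2, 40) + 1, 20, 2)
  m <- cbind(m, m[, 1])
  colnames(m) <- paste0("sample_", 1:3); rownames(m) <- paste0("taxon_", 1:20)
  lib <- colSums(m)
  le <- new("LoadEstimates", trueLoads = c(1e10, 1e11, 2e10) * lib / 30000,
            estimatedLoads = c(1e10, 1e11, 2e10) * lib / 30000,
            achievedR = 1, targetR = 1)
  tm <- transformQMP(seFromMatrix(m), le, seed = 5)
  v <- SummarizedExperiment::assay(tm, "values")
  expect_equal(unname(colSums(v)), unname(estimatedLoads(le)))
  # arithmetic of the even-sampling-depth rule: sizes (30000, 30000),
  # loads (1e10, 1e11) -> targets (3000, 30000)
  m2 <- matrix(c(20000, 10000, 15000, 15000), 2, 2)
  le2 <- new("LoadEstimates", trueLoads = c(1e10, 1e11),
             estimatedLoads = c(1e10, 1e11), achievedR = 1, targetR = 1)
  tm2 <- transformQMP(seFromMatrix(m2), le2, seed = 6)
  vv <- SummarizedExperiment::assay(tm2, "values")
  expect_equal(unname(colSums(vv)), c(1e10, 1e11))
  # even-depth case: rarefaction is the identity and QMP = Rel x load
  le3 <- new("LoadEstimates", trueLoads = colSums(m2) * 1e6,
             estimatedLoads = colSums(m2) * 1e6, achievedR = 1, targetR = 1)
  tm3 <- transformQMP(seFromMatrix(m2), le3, seed = 7)
  rel <- sweep(m2, 2, colSums(m2), "/")
  expect_equal(unname(SummarizedExperiment::assay(tm3, "values")),
               unname(sweep(rel, 2, colSums(m2) * 1e6, "*")))
})

test_that("QMP's even-depth contract holds on simulated data", {
  ce <- tinyCommunity(seed = 30, nSamples = 30, nTaxa = 25)
  se <- simulateSequencing(ce, seed = 31)
  le <- simulateLoadMeasurement(loads(ce), seed = 32)
  tm <- transformQMP(se, le, seed = 33)
  v <- SummarizedExperiment::assay(tm, "values")
  # reconstruct post-rarefaction read totals from the evenness rule
  rate <- librarySizes(se) / loads(se)
  target <- pmin(librarySizes(se), round(min(rate) * loads(se)))
  depth <- target / loads(se)
  expect_lt(diff(range(depth)) / mean(depth), 0.01)
  expect_equal(unname(colSums(v)), unname(estimatedLoads(le)))
})

test_that("ACS is proportions times estimated load", {
  m <- matrix(c(10, 10, 5, 15), 2, 2)
  le <- new("LoadEstimates", trueLoads = c(1e10, 2e10),
            estimatedLoads = c(1e10, 2e10), achievedR = 1, targetR = 1)
  v <- SummarizedExperiment::assay(transformACS(seFromMatrix(m), le),
                                   "values")
  expect_equal(unname(v[, 1]), c(5e9, 5e9))
  expect_equal(unname(colSums(v)), c(1e10, 2e10))
})

test_that("the dispatcher covers all methods and rejects bad input", {
  ce <- tinyCommunity(seed = 40, nSamples = 20, nTaxa = 15)
  se <- simulateSequencing(ce, seed = 41)
  le <- simulateLoadMeasurement(loads(ce), seed = 42)
  for (meth in transformMethods()) {
    tm <- transformCounts(se, meth, loads = le, seed = 43)
    expect_s4_class(tm, "TransformedExperiment")
    expect_identical(transformMethod(tm), meth)
  }
  expect_error(transformCounts(se, "QMP"), "load")
  expect_error(transformCounts(se, "nope"), "unknown")
  # Seq is the identity baseline
  expect_identical(SummarizedExperiment::assay(transformCounts(se, "Seq"),
                                               "values"),
                   SummarizedExperiment::assay(se, "reads"))
})
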