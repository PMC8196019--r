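test_that("correlation matrices honor the sign design and are PSD", {
  m <- generateCorrelationMatrix(300, posFraction = 0.9, seed = 1)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 300))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_lt(abs(attr(m, "posFraction") - 0.9), 0.05)
  # PSD repair is gentle: entries move by less than 0.1
  raw <- withr::with_seed(1, {
    k <- 300 * 299 / 2
    mags <- runif(k, 0.05, 0.6)
    signs <- ifelse(runif(k) < 0.9, 1, -1)
    r <- matrix(0, 300, 300)
    r[upper.tri(r)] <- mags * signs
    r + t(r) + diag(300)
  })
  # the PSD projection preserves the designed structure: entries stay
  # strongly correlated with the raw draw and signs are mostly kept
  off <- upper.tri(m)
  expect_gt(cor(m[off], raw[off]), 0.9)
  expect_gt(mean(sign(m[off]) == sign(raw[off])), 0.85)
})

test_that("a two-taxon all-positive request and the identity are honored", {
  m2 <- generateCorrelationMatrix(2, posFraction = 1, seed = 3)
  expect_gt(m2[1, 2], 0)
  id <- generateCorrelationMatrix(5, posFraction = 0.9,
                                  magnitudeRange = c(0, 0), seed = 4)
  expect_equal(matrix(id, 5, 5), diag(5))
})

test_that("copula marginals follow the negative binomial inverse CDF", {
  # geometric distribution: P(X = 0) = 0.5, so the median quantile maps to 0
  expect_identical(qnbinom(0.5, size = 1, prob = 0.5), 0)
  # NB goodness of fit of simulated marginals at n = 1000
  nb <- data.frame(size = c(1, 2, 1), prob = c(0.05, 0.08, 0.5))
  X <- sampleCopulaCommunity(diag(3), nb, 1000, seed = 7)
  for (j in 1:3) {
    br <- unique(qnbinom(seq(0.1, 0.9, 0.1), nb$size[j], nb$prob[j]))
    obs <- table(cut(X[, j], c(-1, br, Inf)))
    expTheo <- diff(pnbinom(c(-1, br, Inf), nb$size[j], nb$prob[j])) * 1000
    keep <- expTheo > 1
    chi <- sum((obs[keep] - expTheo[keep])^2 / expTheo[keep])
    expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
  }
})

test_that("latent correlation 0.5 yields the closed-form Spearman value", {
  corr <- matrix(c(1, 0.5, 0.5, 1), 2)
  nb <- data.frame(size = c(2, 2), prob = c(0.02, 0.03))
  X <- sampleCopulaCommunity(corr, nb, 1e5, seed = 11)
  expect_equal(cor(X[, 1], X[, 2], method = "spearman"),
               6 / pi * asin(0.25), tolerance = 0.012)
})

test_that("independent taxa show no spurious rank correlation", {
  nb <- sampleNBParams(20, seed = 2)
  X <- sampleCopulaCommunity(diag(20), nb, 1000, seed = 3)
  rho <- cor(X, method = "spearman")
  off <- abs(rho[upper.tri(rho)])
  # 95% envelope for n = 1000 under independence
  expect_gt(mean(off < 1.96 / sqrt(999)), 0.9)
  expect_error(sampleCopulaCommunity(matrix(c(1, -2, -2, 1), 2),
                                     nb[1:2, ], 10),
               "positive semi-definite")
})

test_that("copula correlations are invariant to monotone marginal changes", {
  corr <- generateCorrelationMatrix(4, 0.9, seed = 5)
  nbA <- data.frame(size = rep(1, 4), prob = rep(0.05, 4))
  nbB <- data.frame(size = rep(1, 4), prob = rep(0.01, 4))  # different scale
  XA <- sampleCopulaCommunity(corr, nbA, 2000, seed = 9)
  XB <- sampleCopulaCommunity(corr, nbB, 2000, seed = 9)
  sA <- cor(XA, method = "spearman")[upper.tri(diag(4))]
  sB <- cor(XB, method = "spearman")[upper.tri(diag(4))]
  expect_equal(sA, sB, tolerance = 0.05)
})

test_that("bloomer identification finds co-monotone taxa and flags absence", {
  m <- matrix(rpois(200 * 5, 20), 200, 5)
  m[, 3] <- rowSums(m)           # co-monotone with the totals by construction
  bl <- identifyBloomer(m, threshold = 0.9)
  expect_identical(as.integer(bl), 3L)
  expect_gt(attr(bl, "rho"), 0.9)
  flat <- matrix(5, 50, 4)
  expect_true(is.na(identifyBloomer(flat)))
  expect_identical(formals(identifyBloomer)$threshold, 0.9)
})

test_that("load-correlated taxa hit their designed latent correlations", {
  ld <- withr::with_seed(1, rlnorm(1000, 25, 0.8))
  # perfect correlation: monotone in loads up to NB ties
  perf <- generateLoadCorrelatedTaxon(ld, 1.0, seed = 2)
  expect_true(all(diff(perf$counts[order(ld)]) >= 0))
  # opportunist: empirical latent Pearson near -0.5
  opp <- generateLoadCorrelatedTaxon(ld, -0.5, seed = 3)
  expect_equal(cor(opp$latent, opp$z), -0.5, tolerance = 0.06)
  # unresponsive: load association non-significant in >= 90% of replicates
  pvals <- vapply(1:30, function(s) {
    u <- generateLoadCorrelatedTaxon(ld, 0.01, seed = s)
    suppressWarnings(cor.test(u$counts, ld, method = "spearman"))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  expect_error(generateLoadCorrelatedTaxon(rep(3, 10), 0.5),
               "zero variance")
})

test_that("special-taxon latent correlations average to design over replicates", {
  ld <- withr::with_seed(8, rlnorm(1000, 25, 0.8))
  for (target in c(0.5, -0.5, 0.01)) {
    got <- vapply(1:50, function(s)
      with(generateLoadCorrelatedTaxon(ld, target, seed = 100 + s),
           cor(latent, z)), numeric(1))
    expect_equal(mean(got), target, tolerance = 0.03)
  }
})

test_that("load scaling is global, range-respecting and proportion-preserving", {
  X <- matrix(rpois(50 * 20, 40), 50, 20) + 1
  sc <- scaleToLoadRange(X)
  expect_equal(sc$loads, rowSums(sc$counts))
  expect_gte(min(sc$loads), 1.9e9)
  expect_lte(max(sc$loads), 1e13)
  # per-sample proportions unchanged
  expect_equal(sc$counts[3, ] / sum(sc$counts[3, ]), X[3, ] / sum(X[3, ]))
  # equal raw totals map to equal loads
  X2 <- rbind(X, X[1, ])
  sc2 <- scaleToLoadRange(X2)
  expect_equal(sc2$loads[1], sc2$loads[51])
  expect_error(scaleToLoadRange(matrix(0, 3, 3)), "positive total")
})

test_that("blooming simulation produces a valid, reproducible community", {
  bl <- simulateBlooming(nSamples = 400, nTaxa = 150, seed = 21,
                         maxAttempts = 80)
  expect_s4_class(bl, "CommunityExperiment")
  expect_identical(scenario(bl), "blooming")
  expect_identical(sum(taxonRoles(bl) == "bloomer"), 1L)
  expect_gt(S4Vectors::metadata(bl)$bloomerRho, 0.9)
  expect_equal(loads(bl), colSums(SummarizedExperiment::assay(bl, "counts")))
  bl2 <- simulateBlooming(nSamples = 400, nTaxa = 150, seed = 21,
                          maxAttempts = 80)
  expect_identical(SummarizedExperiment::assay(bl, "counts"),
                   SummarizedExperiment::assay(bl2, "counts"))
})

test_that("succession replaces exactly the bloomer column", {
  bl <- simulateBlooming(nSamples = 300, nTaxa = 120, seed = 33,
                         maxAttempts = 80)
  su <- deriveSuccession(bl, seed = 34)
  expect_identical(scenario(su), "succession")
  idx <- which(taxonRoles(su) == "succession")
  expect_identical(unname(idx), unname(which(taxonRoles(bl) == "bloomer")))
  keep <- setdiff(seq_len(nrow(bl)), idx)
  expect_identical(SummarizedExperiment::assay(su, "counts")[keep, ],
                   SummarizedExperiment::assay(bl, "counts")[keep, ])
  expect_lt(abs(S4Vectors::metadata(su)$successionLatentR - 0.5), 0.15)
  # no new bloomer is expected after the replacement
  expect_true(is.na(identifyBloomer(su)))
  expect_equal(loads(su), colSums(SummarizedExperiment::assay(su, "counts")))
})

test_that("dysbiosis downsamples half the cohort to 20% of the load", {
  bl <- simulateBlooming(nSamples = 300, nTaxa = 120, seed = 55,
                         maxAttempts = 80)
  dy <- deriveDysbiosis(bl, seed = 56)
  gr <- sampleGroups(dy)
  expect_identical(sort(unique(gr)), c("diseased", "healthy"))
  expect_equal(sum(gr == "diseased"), 150)
  pre <- S4Vectors::metadata(dy)$preDownsampleLoads
  post <- S4Vectors::metadata(dy)$postDownsampleLoads
  ratio <- (post / pre)[gr == "diseased"]
  expect_equal(mean(ratio), 0.2, tolerance = 0.01)
  expect_true(all(abs(ratio - 0.2) < 1e-3))
  # healthy samples untouched by downsampling
  expect_equal(unname((post / pre)[gr == "healthy"]), rep(1, 150))
  expect_true(sum(taxonRoles(dy) == "unresponsive") %in% 10:11)
  expect_identical(sum(taxonRoles(dy) == "opportunist"), 1L)
  wt <- wilcox.test(loads(dy)[gr == "diseased"], loads(dy)[gr == "healthy"])
  expect_lt(wt$p.value, 0.001)
  expect_lt(median(loads(dy)[gr == "diseased"]),
            median(loads(dy)[gr == "healthy"]))
  expect_equal(loads(dy), colSums(SummarizedExperiment::assay(dy, "counts")))
})

test_that("sample subsampling keeps n samples and group balance", {
  bl <- simulateBlooming(nSamples = 300, nTaxa = 120, seed = 77,
                         maxAttempts = 80)
  expect_identical(subsampleSamples(bl, 300), bl)
  sub <- subsampleSamples(bl, 120, seed = 78)
  expect_identical(ncol(sub), 120L)
  expect_error(subsampleSamples(bl, 500), "cannot retain")
  dy <- deriveDysbiosis(bl, seed = 79)
  dsub <- subsampleSamples(dy, 100, seed = 80)
  tab <- table(sampleGroups(dsub))
  expect_equal(unname(tab["diseased"]) / 100, 0.5, tolerance = 0.05)
  expect_identical(length(S4Vectors::metadata(dsub)$preDownsampleLoads), 100L)
})
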