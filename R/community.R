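# Synthetic community generation: Gaussian-copula multivariate negative
# binomials with designed taxon-taxon correlation structure, plus the three
# ecological scenarios (blooming, succession, dysbiosis).

#' Generate a random taxon-taxon correlation matrix
#'
#' Off-diagonal entries are drawn with magnitudes uniform in
#' `magnitudeRange` and a fraction `posFraction` of positive signs, mirroring
#' the mostly-positive taxon covariation observed in fecal microbiomes. The
#' raw matrix is projected to the nearest positive semi-definite correlation
#' matrix by eigenvalue clipping (floor `1e-6`) followed by re-normalization
#' to unit diagonal.
#'
#' @param nTaxa number of taxa (matrix dimension).
#' @param posFraction fraction of off-diagonal entries designed positive;
#'   must exceed 0.5.
#' @param magnitudeRange range of absolute correlation values to draw from.
#' @param seed optional integer seed.
#' @return symmetric PSD correlation matrix with attribute `"posFraction"`
#'   (the observed positive sign fraction before repair).
#' @export
generateCorrelationMatrix <- function(nTaxa, posFraction = 0.9,
                                      magnitudeRange = c(0.05, 0.6),
                                      seed = NULL) {
  stopifnot(nTaxa >= 2)
  if (!(posFraction > 0.5 && posFraction <= 1))
    stop("posFraction must be in (0.5, 1]")
  .withSeed(seed)
  k <- nTaxa * (nTaxa - 1) / 2
  mags <- stats::runif(k, magnitudeRange[1], magnitudeRange[2])
  signs <- ifelse(stats::runif(k) < posFraction, 1, -1)
  m <- matrix(0, nTaxa, nTaxa)
  m[upper.tri(m)] <- mags * signs
  m <- m + t(m)
  diag(m) <- 1
  obsPos <- mean(signs > 0)
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values < 1e-6)) {
    ev <- pmax(e$values, 1e-6)
    m <- e$vectors %*% (ev * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation structure could not be repaired to PSD")
  structure(m, posFraction = obsPos)
}

#' Draw per-taxon negative-binomial parameters
#'
#' Community taxa receive a dispersion (size) parameter drawn uniformly from
#' `sizeValues` and a probability parameter uniform on the open interval
#' `probRange`. With the (size, prob) parameterization of [stats::qnbinom()]
#' the marginal mean is `size * (1 - prob) / prob`, so small `prob` yields
#' the dense, heavy-tailed abundance profiles typical of stool communities.
#'
#' @param nTaxa number of taxa.
#' @param sizeValues candidate size (dispersion) values; discrete uniform.
#' @param probRange open interval for the probability parameter.
#' @param seed optional integer seed.
#' @return data.frame with columns `size` and `prob`.
#' @export
sampleNBParams <- function(nTaxa, sizeValues = c(1, 2),
                           probRange = c(0, 0.1), seed = NULL) {
  .withSeed(seed)
  q <- stats::runif(nTaxa, probRange[1], probRange[2])
  while (any(q <= probRange[1]))   # open interval: prob = 0 is degenerate
    q[q <= probRange[1]] <- stats::runif(sum(q <= probRange[1]),
                                         probRange[1], probRange[2])
  data.frame(size = sample(sizeValues, nTaxa, replace = TRUE), prob = q)
}

#' Sample a community from a Gaussian copula with NB marginals
#'
#' Draws latent multivariate Gaussian samples with the given correlation
#' matrix, maps each marginal through the Gaussian CDF and then through the
#' negative-binomial inverse CDF with that taxon's (size, prob) parameters.
#'
#' @param corr PSD taxon-taxon correlation matrix.
#' @param nb data.frame of per-taxon NB parameters as from [sampleNBParams()].
#' @param nSamples number of samples to draw.
#' @param seed optional integer seed.
#' @return integer matrix of abundances, samples x taxa.
#' @export
sampleCopulaCommunity <- function(corr, nb, nSamples, seed = NULL) {
  p <- nrow(corr)
  stopifnot(nrow(nb) == p, ncol(corr) == p)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  .withSeed(seed)
  Z <- MASS::mvrnorm(nSamples, mu = rep(0, p), Sigma = corr)
  U <- stats::pnorm(Z)
  X <- vapply(seq_len(p),
              function(j) stats::qnbinom(U[, j], size = nb$size[j],
                                         prob = nb$prob[j]),
              numeric(nSamples))
  dimnames(X) <- list(paste0("sample_", seq_len(nSamples)),
                      paste0("taxon_", seq_len(p)))
  X
}

#' Identify the bloomer taxon of a community
#'
#' The bloomer is the taxon whose abundance has the highest Spearman
#' correlation with the community loads, provided that correlation exceeds
#' `threshold` (default 0.9).
#'
#' @param x a `CommunityExperiment`, or a samples x taxa abundance matrix.
#' @param threshold minimum Spearman rho against loads.
#' @return the taxon index, with attribute `"rho"`; `NA` if no taxon
#'   qualifies.
#' @export
identifyBloomer <- function(x, threshold = 0.9) {
  if (is(x, "CommunityExperiment")) {
    m <- t(assay(x, "counts"))
    ld <- loads(x)
  } else {
    m <- as.matrix(x)
    ld <- rowSums(m)
  }
  if (nrow(m) < 3) stop("at least 3 samples are required")
  rho <- drop(.spearman(m, ld)$rho)
  if (all(is.na(rho))) return(structure(NA_integer_, rho = NA_real_))
  j <- which.max(rho)
  if (rho[j] > threshold) structure(as.integer(j), rho = unname(rho[j]))
  else structure(NA_integer_, rho = unname(rho[j]))
}

#' Generate a taxon with a specified latent correlation to the loads
#'
#' Implements the special-taxon construction: loads are z-scored (assumed
#' approximately Gaussian), a standard Gaussian is drawn with the specified
#' correlation to the z-scored loads, and the result is mapped through the
#' negative-binomial inverse CDF (default size 1, prob 0.5).
#'
#' @param loads per-sample loads (or raw totals) to correlate against.
#' @param targetCorr designed latent correlation: 0.5 for a succession
#'   taxon, -0.5 for an opportunist, 0.01 for an unresponsive taxon.
#' @param size,prob NB parameters of the replacement taxon.
#' @param seed optional integer seed.
#' @return list with `counts` (NB abundances), `latent` (the retained latent
#'   Gaussian variable) and `z` (the z-scored loads).
#' @export
generateLoadCorrelatedTaxon <- function(loads, targetCorr, size = 1,
                                        prob = 0.5, seed = NULL) {
  stopifnot(length(loads) >= 2, abs(targetCorr) <= 1)
  if (stats::sd(loads) == 0) stop("loads have zero variance")
  .withSeed(seed)
  z <- as.numeric(scale(loads))
  latent <- targetCorr * z +
    sqrt(1 - targetCorr^2) * stats::rnorm(length(z))
  list(counts = stats::qnbinom(stats::pnorm(latent), size = size, prob = prob),
       latent = latent, z = z)
}

#' Scale a raw community so loads fall in the biological range
#'
#' Multiplies the whole matrix by a single constant chosen so that the
#' per-sample totals (microbial loads, cells/g) are centered, in log space,
#' inside `[loadMin, loadMax]`. A global constant preserves every designed
#' correlation and every within-sample proportion, and lets the load spread
#' (max/min) vary naturally across replicate matrices.
#'
#' @param counts samples x taxa abundance matrix with positive totals.
#' @param loadMin,loadMax bounds of the target load range (cells/g).
#' @return list with `counts` (scaled matrix), `loads` (row sums) and
#'   `scale` (the constant applied).
#' @export
scaleToLoadRange <- function(counts, loadMin = 1.9e9, loadMax = 1e13) {
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("all samples must have positive total abundance")
  if (max(tot) / min(tot) > loadMax / loadMin)
    stop("raw load spread (", format(max(tot) / min(tot), digits = 3),
         ") exceeds the target range ratio; cannot place loads in range")
  ctr <- (log(loadMin) + log(loadMax)) / 2
  sc <- exp(ctr - mean(range(log(tot))))
  list(counts = counts * sc, loads = tot * sc, scale = sc)
}

#' Simulate a blooming-scenario community
#'
#' Runs the copula procedure and accepts the first draw containing a bloomer
#' (a taxon whose Spearman correlation with loads exceeds
#' `bloomThreshold`); the correlation structure and NB parameters are
#' regenerated, with fresh sub-seeds, until a bloomer emerges (at most
#' `maxAttempts` times). The accepted matrix is scaled into the biological
#' load range.
#'
#' @param nSamples,nTaxa community dimensions (defaults 1000 x 300).
#' @param seed integer seed for the whole procedure.
#' @param posFraction,magnitudeRange correlation design, see
#'   [generateCorrelationMatrix()].
#' @param bloomThreshold Spearman threshold defining a bloomer.
#' @param loadRange target range of microbial loads (cells/g).
#' @param maxAttempts maximum number of regeneration attempts.
#' @return a [CommunityExperiment-class] with scenario `"blooming"` and the
#'   bloomer role recorded.
#' @export
simulateBlooming <- function(nSamples = 1000, nTaxa = 300, seed = NULL,
                             posFraction = 0.9, magnitudeRange = c(0.05, 0.6),
                             bloomThreshold = 0.9,
                             loadRange = c(1.9e9, 1e13), maxAttempts = 50) {
  .withSeed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, maxAttempts)
  for (a in seq_len(maxAttempts)) {
    res <- withr::with_seed(subseeds[a], {
      corr <- generateCorrelationMatrix(nTaxa, posFraction, magnitudeRange)
      nb <- sampleNBParams(nTaxa)
      X <- sampleCopulaCommunity(corr, nb, nSamples)
      bl <- identifyBloomer(X, bloomThreshold)
      list(X = X, nb = nb, bloomer = bl)
    })
    if (!is.na(res$bloomer)) {
      sc <- scaleToLoadRange(res$X, loadRange[1], loadRange[2])
      roles <- rep("none", nTaxa)
      roles[res$bloomer] <- "bloomer"
      ce <- CommunityExperiment(t(sc$counts), scenario = "blooming",
                                roles = roles, nbParams = res$nb,
                                loadScale = sc$scale)
      metadata(ce)$attempts <- a
      metadata(ce)$bloomerRho <- attr(res$bloomer, "rho")
      return(ce)
    }
  }
  stop("no bloomer (Spearman > ", bloomThreshold, ") emerged in ",
       maxAttempts, " attempts")
}

# Replace one taxon column (raw NB counts scaled by the matrix constant) and
# recompute loads.
.replaceTaxon <- function(ce, idx, newRawCounts, role) {
  cts <- assay(ce, "counts")
  cts[idx, ] <- newRawCounts * metadata(ce)$loadScale
  roles <- as.character(rowData(ce)$role)
  roles[idx] <- role
  list(counts = cts, roles = roles)
}

#' Derive the ecological-succession scenario from a blooming community
#'
#' The bloomer is replaced by a succession taxon with a mild designed
#' correlation (latent r = 0.5) to the community loads; all other taxa and
#' the across-taxa correlation structure are untouched. Loads are recomputed
#' from the new matrix.
#'
#' @param ce a blooming `CommunityExperiment` with an identified bloomer.
#' @param seed optional integer seed.
#' @param targetCorr designed latent correlation of the succession taxon.
#' @return a [CommunityExperiment-class] with scenario `"succession"`.
#' @export
deriveSuccession <- function(ce, seed = NULL, targetCorr = 0.5) {
  stopifnot(is(ce, "CommunityExperiment"))
  idx <- which(taxonRoles(ce) == "bloomer")
  if (length(idx) != 1) stop("input must contain exactly one bloomer taxon")
  .withSeed(seed)
  lt <- generateLoadCorrelatedTaxon(loads(ce), targetCorr)
  rep <- .replaceTaxon(ce, idx, lt$counts, "succession")
  out <- CommunityExperiment(rep$counts, scenario = "succession",
                             roles = rep$roles,
                             nbParams = metadata(ce)$nbParams,
                             loadScale = metadata(ce)$loadScale)
  metadata(out)$successionLatentR <- stats::cor(lt$latent, lt$z)
  out
}

#' Derive the dysbiosis scenario from a blooming community
#'
#' Half of the samples, selected by uniform stratification along the load
#' distribution (alternate load ranks at a random phase), are randomly
#' downsampled to `downsampleFraction` (20 percent) of their load by
#' multinomial subsampling of cells. The bloomer is replaced by an
#' opportunist taxon (latent r = -0.5 against the post-downsampling loads)
#' and 10-11 randomly chosen non-special taxa are replaced by unresponsive
#' taxa (latent r = 0.01). Downsampled samples are labelled `"diseased"`.
#'
#' @param ce a blooming `CommunityExperiment` with an identified bloomer.
#' @param seed optional integer seed.
#' @param downsampleFraction fraction of the load retained in diseased
#'   samples.
#' @param opportunistCorr,unresponsiveCorr designed latent correlations.
#' @param nUnresponsive number of unresponsive replacements; by default 10
#'   or 11 with equal probability.
#' @return a [CommunityExperiment-class] with scenario `"dysbiosis"`,
#'   special-taxon roles and per-sample group labels.
#' @export
deriveDysbiosis <- function(ce, seed = NULL, downsampleFraction = 0.2,
                            opportunistCorr = -0.5, unresponsiveCorr = 0.01,
                            nUnresponsive = NULL) {
  stopifnot(is(ce, "CommunityExperiment"))
  idx <- which(taxonRoles(ce) == "bloomer")
  if (length(idx) != 1) stop("input must contain exactly one bloomer taxon")
  n <- ncol(ce)
  if (n < 20) stop("at least 20 samples are required")
  .withSeed(seed)
  if (is.null(nUnresponsive)) nUnresponsive <- sample(10:11, 1)
  if (nUnresponsive + 1 > nrow(ce))
    stop("fewer taxa than requested replacements")

  ld <- loads(ce)
  sc <- metadata(ce)$loadScale
  raw <- round(assay(ce, "counts") / sc)      # back to integer cell counts
  ord <- order(ld)
  phase <- sample(2, 1)
  diseased <- ord[seq(phase, n, by = 2)]

  for (i in diseased) {
    tot <- sum(raw[, i])
    target <- round(downsampleFraction * tot)
    raw[, i] <- stats::rmultinom(1, target, raw[, i] / tot)[, 1]
  }
  postLoads <- colSums(raw) * sc

  opp <- generateLoadCorrelatedTaxon(postLoads, opportunistCorr)
  raw[idx, ] <- opp$counts
  roles <- as.character(rowData(ce)$role)
  roles[idx] <- "opportunist"

  candidates <- setdiff(which(roles == "none"), idx)
  unresp <- sample(candidates, nUnresponsive)
  for (j in unresp) {
    raw[j, ] <- generateLoadCorrelatedTaxon(postLoads,
                                            unresponsiveCorr)$counts
    roles[j] <- "unresponsive"
  }

  groups <- rep("healthy", n)
  groups[diseased] <- "diseased"
  out <- CommunityExperiment(raw * sc, scenario = "dysbiosis",
                             roles = roles, groups = groups,
                             nbParams = metadata(ce)$nbParams,
                             loadScale = sc)
  metadata(out)$opportunistLatentR <- stats::cor(opp$latent, opp$z)
  # loads before and right after downsampling (prior to the taxon
  # replacements, which move additional mass when the bloomer dominates)
  metadata(out)$preDownsampleLoads <- stats::setNames(ld, colnames(ce))
  metadata(out)$postDownsampleLoads <- stats::setNames(postLoads,
                                                       colnames(ce))
  out
}

#' Subsample the samples of a community
#'
#' Retains `n` distinct samples without replacement. For the dysbiosis
#' scenario the draw is stratified by health group so the approximate group
#' balance is preserved.
#'
#' @param ce a `CommunityExperiment`.
#' @param n number of samples to retain (default 200).
#' @param seed optional integer seed.
#' @return the subsampled [CommunityExperiment-class].
#' @export
subsampleSamples <- function(ce, n = 200, seed = NULL) {
  stopifnot(is(ce, "CommunityExperiment"))
  N <- ncol(ce)
  if (n > N) stop("cannot retain ", n, " of ", N, " samples")
  if (n == N) return(ce)
  .withSeed(seed)
  gr <- sampleGroups(ce)
  if (!is.null(gr)) {
    keep <- unlist(lapply(split(seq_len(N), gr), function(ix) {
      k <- round(n * length(ix) / N)
      sample(ix, k)
    }), use.names = FALSE)
    # rounding can leave us one off target
    if (length(keep) > n) keep <- sample(keep, n)
    while (length(keep) < n)
      keep <- c(keep, sample(setdiff(seq_len(N), keep), n - length(keep)))
  } else {
    keep <- sample(N, n)
  }
  keep <- sort(keep)
  out <- ce[, keep]
  for (nm in c("preDownsampleLoads", "postDownsampleLoads")) {
    v <- metadata(out)[[nm]]
    if (!is.null(v)) metadata(out)[[nm]] <- v[keep]
  }
  out
}
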