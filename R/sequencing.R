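# Simulated metagenomic sequencing: log-normal library sizes and multinomial
# read sampling (with replacement) from each sample's relative abundances.

#' Draw per-sample library sizes from a log-normal distribution
#'
#' Library sizes are log-normal with `meanlog` 10.3 and `sdlog` 0.3 by
#' default (median around 30,000 reads, the depth typical of clinical
#' microbiome cohorts), rounded to the nearest integer with a floor of 1.
#'
#' @param n number of samples.
#' @param meanlog,sdlog log-scale mean and standard deviation.
#' @param seed optional integer seed.
#' @return integer vector of library sizes.
#' @export
drawLibrarySizes <- function(n, meanlog = 10.3, sdlog = 0.3, seed = NULL) {
  stopifnot(n >= 1, sdlog >= 0)
  .withSeed(seed)
  pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
}

#' Simulate metagenomic sequencing of a community
#'
#' For each sample, reads are drawn multinomially (random sampling with
#' replacement) from the sample's relative taxon abundances, at the given
#' library size. Sequencing sees only composition: the per-sample sampling
#' depth (library size / microbial load) shrinks as loads grow.
#'
#' @param ce a `CommunityExperiment`.
#' @param librarySizes optional vector of per-sample read totals; drawn via
#'   [drawLibrarySizes()] when `NULL`.
#' @param meanlog,sdlog library-size distribution parameters, used when
#'   `librarySizes` is `NULL`.
#' @param seed optional integer seed.
#' @return a [SequenceExperiment-class] carrying the true loads, scenario,
#'   taxon roles and (for dysbiosis) group labels of the parent community.
#' @export
simulateSequencing <- function(ce, librarySizes = NULL, meanlog = 10.3,
                               sdlog = 0.3, seed = NULL) {
  stopifnot(is(ce, "CommunityExperiment"))
  .withSeed(seed)
  n <- ncol(ce)
  if (is.null(librarySizes))
    librarySizes <- drawLibrarySizes(n, meanlog, sdlog)
  stopifnot(length(librarySizes) == n)
  cts <- assay(ce, "counts")
  tot <- colSums(cts)
  if (any(tot <= 0)) stop("cannot sequence an all-zero sample")
  reads <- matrix(vapply(seq_len(n), function(i)
    stats::rmultinom(1, librarySizes[i], cts[, i] / tot[i])[, 1],
    numeric(nrow(cts))), nrow = nrow(cts))
  dimnames(reads) <- dimnames(cts)
  SequenceExperiment(reads, loads = loads(ce), groups = sampleGroups(ce),
                     scenario = scenario(ce), roles = taxonRoles(ce))
}
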