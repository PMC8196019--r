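# End-to-end benchmark orchestration: community -> metadata -> sequencing ->
# load estimates -> transformations -> diversity and association scoring,
# per scenario and replicate, deterministic given a master seed.

#' Benchmark configuration
#'
#' @param scenarios scenarios to run.
#' @param nReplicates replicate communities per scenario (default 10).
#' @param nSamples samples retained per analysis matrix (default 200).
#' @param nPoolSamples samples drawn per community before subsampling
#'   (default 1000).
#' @param nTaxa taxa per community (default 300).
#' @param meanlog,sdlog library-size distribution (defaults 10.3, 0.3).
#' @param rRange load-measurement acceptance range.
#' @param loadRange target microbial load range (cells/g).
#' @param methods transformation tags to benchmark.
#' @param families association families to score.
#' @param alpha BH-adjusted significance threshold.
#' @param masterSeed master seed for the run.
#' @return a list of class `qmpbench_config`.
#' @export
benchmarkConfig <- function(scenarios = c("blooming", "succession",
                                          "dysbiosis"),
                            nReplicates = 10, nSamples = 200,
                            nPoolSamples = 1000, nTaxa = 300,
                            meanlog = 10.3, sdlog = 0.3,
                            rRange = c(0.85, 0.95),
                            loadRange = c(1.9e9, 1e13),
                            methods = transformMethods(),
                            families = c("taxon_load", "taxon_metadata",
                                         "taxon_taxon"),
                            alpha = 0.05, masterSeed = 1L) {
  stopifnot(all(scenarios %in% .SCENARIOS),
            all(methods %in% transformMethods()),
            nSamples <= nPoolSamples)
  structure(list(scenarios = scenarios, nReplicates = nReplicates,
                 nSamples = nSamples, nPoolSamples = nPoolSamples,
                 nTaxa = nTaxa, meanlog = meanlog, sdlog = sdlog,
                 rRange = rRange, loadRange = loadRange, methods = methods,
                 families = families, alpha = alpha,
                 masterSeed = as.integer(masterSeed)),
            class = "qmpbench_config")
}

# Generate the three scenario matrices of one replicate from a single
# blooming community, subsampled to the analysis size.
.simulateReplicate <- function(cfg, seeds, subsample = TRUE) {
  bloom <- simulateBlooming(cfg$nPoolSamples, cfg$nTaxa, seed = seeds[1],
                            loadRange = cfg$loadRange)
  full <- list(blooming = bloom)
  if ("succession" %in% cfg$scenarios)
    full$succession <- deriveSuccession(bloom, seed = seeds[2])
  if ("dysbiosis" %in% cfg$scenarios)
    full$dysbiosis <- deriveDysbiosis(bloom, seed = seeds[3])
  full <- full[intersect(.SCENARIOS, cfg$scenarios)]
  if (!subsample) return(full)
  lapply(seq_along(full), function(i)
    subsampleSamples(full[[i]], cfg$nSamples, seed = seeds[3 + i])) |>
    stats::setNames(names(full))
}

# Reference + per-method association and diversity scoring of one matrix.
.evaluateMatrix <- function(ce, se, le, md, disease, cfg, seed) {
  refsX <- ce
  fams <- cfg$families
  if (!is.null(disease)) fams <- union(fams, "taxon_disease")
  refTargets <- list(taxon_load = loads(ce), taxon_metadata = md,
                     taxon_taxon = NULL, taxon_disease = disease)
  ref <- lapply(stats::setNames(fams, fams), function(fa)
    detectAssociations(refsX, refTargets[[fa]], family = fa,
                       alpha = cfg$alpha))
  divRef <- alphaDiversity(ce)
  roles <- taxonRoles(ce)

  assoc <- list(); special <- list(); divers <- list()
  subseeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                length(cfg$methods)))
  for (k in seq_along(cfg$methods)) {
    meth <- cfg$methods[k]
    tm <- transformCounts(se, meth, loads = le, seed = subseeds[k])
    testX <- tm
    # transformed-side load associations use the experimentally knowable
    # quantity: the estimated loads
    testLoad <- estimatedLoads(le)
    for (fa in fams) {
      test <- detectAssociations(testX, switch(fa,
                                               taxon_load = testLoad,
                                               taxon_metadata = md,
                                               taxon_taxon = NULL,
                                               taxon_disease = disease),
                                 family = fa, alpha = cfg$alpha)
      cmp <- classifyVsReference(ref[[fa]], test)
      assoc[[length(assoc) + 1]] <- cbind(
        data.frame(method = meth, family = fa), cmp)
      if (fa %in% c("taxon_load", "taxon_metadata", "taxon_disease") &&
          any(roles != "none")) {
        sp <- specialTaxaEval(ref[[fa]], test, roles)
        if (nrow(sp))
          special[[length(special) + 1]] <- cbind(
            data.frame(method = meth, family = fa), sp)
      }
    }
    if (methodFlags(meth)$diversitySuitable) {
      divTest <- alphaDiversity(tm)
      for (idx in colnames(divTest)) {
        rc <- richnessCorrelation(divRef[[idx]], divTest[[idx]])
        divers[[length(divers) + 1]] <- cbind(
          data.frame(method = meth, index = idx), rc)
      }
    }
  }
  list(assoc = do.call(rbind, assoc),
       special = if (length(special)) do.call(rbind, special) else NULL,
       diversity = do.call(rbind, divers))
}

#' Run the full transformation benchmark
#'
#' For every scenario and replicate: simulate a community, metadata,
#' sequencing and load estimates, apply the configured transformations, and
#' score diversity recovery and association recovery against the
#' ground-truth community. Deterministic given `cfg$masterSeed`.
#'
#' @param cfg a configuration from [benchmarkConfig()].
#' @param keepMatrices also return the simulated objects (memory-heavy).
#' @return list of class `qmpbench_result` with data.frames `diversity`
#'   (per scenario/replicate/method/index Pearson R and category),
#'   `associations` and `specialTaxa` (confusion summaries), `spread`
#'   (per-matrix load spread), and the `config`.
#' @export
runBenchmark <- function(cfg = benchmarkConfig(), keepMatrices = FALSE) {
  seeds <- seedStream(cfg$masterSeed,
                      cfg$nReplicates * 16)
  sdx <- 0
  nextSeeds <- function(k) {
    out <- seeds[sdx + seq_len(k)]; sdx <<- sdx + k; out
  }
  assoc <- list(); special <- list(); divers <- list(); spread <- list()
  kept <- list()
  for (rep in seq_len(cfg$nReplicates)) {
    repSeeds <- nextSeeds(16)
    mats <- .simulateReplicate(cfg, repSeeds[1:8])
    for (sc in names(mats)) {
      ce <- mats[[sc]]
      scSeedBase <- repSeeds[8 + match(sc, .SCENARIOS)]
      stageSeeds <- withr::with_seed(scSeedBase,
                                     sample.int(.Machine$integer.max - 1L, 5))
      md <- buildMetadataMatrix(ce, seed = stageSeeds[1])
      disease <- if (identical(sc, "dysbiosis"))
        buildDiseaseStatus(ce, seed = stageSeeds[2]) else NULL
      se <- simulateSequencing(ce, meanlog = cfg$meanlog, sdlog = cfg$sdlog,
                               seed = stageSeeds[3])
      le <- simulateLoadMeasurement(loads(ce), rRange = cfg$rRange,
                                    seed = stageSeeds[4])
      ev <- .evaluateMatrix(ce, se, le, md, disease, cfg, stageSeeds[5])
      tagIt <- function(df) if (is.null(df)) NULL else
        cbind(data.frame(scenario = sc, replicate = rep), df)
      assoc[[length(assoc) + 1]] <- tagIt(ev$assoc)
      special[[length(special) + 1]] <- tagIt(ev$special)
      divers[[length(divers) + 1]] <- tagIt(ev$diversity)
      ld <- loads(ce)
      spread[[length(spread) + 1]] <- data.frame(
        scenario = sc, replicate = rep, spread = max(ld) / min(ld),
        achievedLoadR = achievedR(le))
      if (keepMatrices)
        kept[[paste(sc, rep, sep = "_")]] <-
          list(community = ce, sequence = se, loads = le, metadata = md,
               disease = disease)
    }
  }
  structure(list(config = cfg,
                 diversity = do.call(rbind, divers),
                 associations = do.call(rbind, assoc),
                 specialTaxa = do.call(rbind, special),
                 spread = do.call(rbind, spread),
                 matrices = if (keepMatrices) kept else NULL),
            class = "qmpbench_result")
}

#' @export
print.qmpbench_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("qmpbench benchmark: %d scenario(s) x %d replicate(s), %d methods\n",
              length(unique(x$spread$scenario)), cfg$nReplicates,
              length(cfg$methods)))
  cat(sprintf("  %d association summaries, %d diversity correlations\n",
              nrow(x$associations), nrow(x$diversity)))
  invisible(x)
}

#' ACS-vs-QMP precision and sensitivity by microbial load spread
#'
#' Reproduces the disease-association analysis: dysbiosis matrices are
#' ranked by their load spread (max/min) and split into low/medium/high
#' spread groups (4/4/2 for ten matrices, proportional otherwise); for each
#' sequencing depth in the grid, sequence matrices are transformed with ACS
#' and QMP and their recovery of taxon-disease associations is scored
#' against the ground truth.
#'
#' @param communities list of dysbiosis `CommunityExperiment`s.
#' @param meanlogGrid log-scale mean library sizes to sweep (default four
#'   depths between roughly 10,000 and 100,000 reads).
#' @param sdlog library-size log-sd.
#' @param seed integer seed.
#' @param rRange load-measurement acceptance range.
#' @param noise disease-label noise fraction.
#' @param alpha BH threshold.
#' @return list with `results` (per matrix/depth/method confusion),
#'   `groups` (matrix spread grouping) and `comparison` (per spread group:
#'   paired two-sided Wilcoxon signed-rank of QMP vs ACS precision and
#'   sensitivity).
#' @export
spreadAnalysis <- function(communities,
                           meanlogGrid = c(9.2, 10.0, 10.8, 11.5),
                           sdlog = 0.3, seed = 1L, rRange = c(0.85, 0.95),
                           noise = 0.07, alpha = 0.05) {
  stopifnot(length(communities) >= 2,
            all(vapply(communities, function(x)
      identical(scenario(x), "dysbiosis"), logical(1))))
  nm <- length(communities)
  spreads <- vapply(communities, function(ce) {
    ld <- loads(ce); max(ld) / min(ld)
  }, numeric(1))
  ord <- order(spreads)
  sizes <- if (nm == 10) c(4, 4, 2)
           else pmax(1, round(nm * c(0.4, 0.4, 0.2)))
  while (sum(sizes) > nm) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  while (sum(sizes) < nm) sizes[1] <- sizes[1] + 1
  groupOf <- rep(c("low", "medium", "high"), sizes)[order(ord)]
  seeds <- seedStream(seed, nm * (2 + 2 * length(meanlogGrid)))
  sdx <- 0
  res <- list()
  for (i in seq_len(nm)) {
    ce <- communities[[i]]
    disease <- buildDiseaseStatus(ce, noise = noise,
                                  seed = seeds[sdx <- sdx + 1])
    ref <- detectAssociations(ce, disease, family = "taxon_disease",
                              alpha = alpha)
    le <- simulateLoadMeasurement(loads(ce), rRange = rRange,
                                  seed = seeds[sdx <- sdx + 1])
    for (ml in meanlogGrid) {
      se <- simulateSequencing(ce, meanlog = ml, sdlog = sdlog,
                               seed = seeds[sdx <- sdx + 1])
      qmpSeed <- seeds[sdx <- sdx + 1]
      for (meth in c("ACS", "QMP")) {
        tm <- transformCounts(se, meth, loads = le, seed = qmpSeed)
        test <- detectAssociations(tm, disease, family = "taxon_disease",
                                   alpha = alpha)
        cmp <- classifyVsReference(ref, test)
        res[[length(res) + 1]] <- cbind(
          data.frame(matrix = i, spread = spreads[i],
                     spreadGroup = groupOf[i], meanlog = ml,
                     meanDepth = round(exp(ml + sdlog^2 / 2)),
                     method = meth), cmp)
      }
    }
  }
  res <- do.call(rbind, res)
  cmpRows <- list()
  for (gr in unique(groupOf)) {
    sub <- res[res$spreadGroup == gr, ]
    wide <- merge(sub[sub$method == "QMP",
                      c("matrix", "meanlog", "precision", "sensitivity")],
                  sub[sub$method == "ACS",
                      c("matrix", "meanlog", "precision", "sensitivity")],
                  by = c("matrix", "meanlog"), suffixes = c(".qmp", ".acs"))
    for (metric in c("precision", "sensitivity")) {
      a <- wide[[paste0(metric, ".qmp")]]
      b <- wide[[paste0(metric, ".acs")]]
      ok <- !is.na(a) & !is.na(b)
      pv <- if (sum(ok) >= 3 && any(a[ok] != b[ok]))
        stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                           exact = FALSE)$p.value else NA_real_
      cmpRows[[length(cmpRows) + 1]] <- data.frame(
        spreadGroup = gr, metric = metric,
        medianQMP = stats::median(a, na.rm = TRUE),
        medianACS = stats::median(b, na.rm = TRUE),
        meanDelta = mean(a[ok] - b[ok]), p = pv)
    }
  }
  list(results = res, groups = data.frame(matrix = seq_len(nm),
                                          spread = spreads,
                                          spreadGroup = groupOf),
       comparison = do.call(rbind, cmpRows))
}

#' Sweep the benchmark over sequencing depth or cohort size
#'
#' Re-evaluates association recovery for a set of replicate communities
#' while varying either the mean sequencing depth (log-normal `meanlog`) or
#' the cohort size, holding everything else at the configuration defaults.
#'
#' @param cfg a [benchmarkConfig()]; `nReplicates` communities are
#'   simulated once and reused across grid points.
#' @param axis `"sequencing_depth"` (grid of `meanlog` values) or
#'   `"cohort_size"` (grid of sample counts).
#' @param grid numeric grid for the chosen axis.
#' @return data.frame of confusion summaries per grid point, scenario,
#'   replicate, method and family.
#' @export
sweepBenchmark <- function(cfg = benchmarkConfig(nReplicates = 3),
                           axis = c("sequencing_depth", "cohort_size"),
                           grid = NULL) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "sequencing_depth") c(9.9, 10.9, 12.0, 13.12)
            else c(20, 100, 500, 1000)
  if (axis == "cohort_size" && max(grid) > cfg$nPoolSamples)
    stop("cohort sizes beyond the community pool size")
  seeds <- seedStream(cfg$masterSeed, cfg$nReplicates)
  out <- list()
  for (rep in seq_len(cfg$nReplicates)) {
    mats <- .simulateReplicate(cfg, withr::with_seed(
      seeds[rep], sample.int(.Machine$integer.max - 1L, 8)),
      subsample = (axis != "cohort_size"))
    for (gi in seq_along(grid)) {
      g <- grid[gi]
      cfgG <- cfg
      if (axis == "sequencing_depth") cfgG$meanlog <- g
      for (sc in names(mats)) {
        ce <- mats[[sc]]
        stageSeeds <- withr::with_seed(
          (seeds[rep] %% 1000000L) + gi * 101L + match(sc, .SCENARIOS),
          sample.int(.Machine$integer.max - 1L, 6))
        if (axis == "cohort_size")
          ce <- subsampleSamples(ce, min(g, ncol(ce)), seed = stageSeeds[6])
        md <- buildMetadataMatrix(ce, seed = stageSeeds[1])
        disease <- if (identical(sc, "dysbiosis"))
          buildDiseaseStatus(ce, seed = stageSeeds[2]) else NULL
        se <- simulateSequencing(ce, meanlog = cfgG$meanlog,
                                 sdlog = cfgG$sdlog, seed = stageSeeds[3])
        le <- simulateLoadMeasurement(loads(ce), rRange = cfgG$rRange,
                                      seed = stageSeeds[4])
        ev <- .evaluateMatrix(ce, se, le, md, disease, cfgG, stageSeeds[5])
        out[[length(out) + 1]] <- cbind(
          data.frame(axis = axis, gridValue = g, scenario = sc,
                     replicate = rep), ev$assoc)
      }
    }
  }
  do.call(rbind, out)
}
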