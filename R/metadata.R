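# Simulated metadata: 100 abstract covariates per community (50 numeric, 50
# categorical) with a recorded ground-truth map of which feature targets
# which taxon or the microbial loads, at designed |Spearman| in [0.3, 0.6].

.NUMERIC_DISTS <- c("uniform", "gaussian", "negbin")

.drawNullFeature <- function(n, dist) {
  switch(dist,
         uniform  = stats::runif(n),
         gaussian = stats::rnorm(n),
         negbin   = stats::rnbinom(n, size = 2, mu = 10),
         stop("unknown distribution: ", dist))
}

#' Generate a numeric metadata feature
#'
#' Uncorrelated features (`target = NULL`) are drawn from one of three
#' distributions (uniform, Gaussian, negative binomial). Correlated features
#' are built by Gaussian-copula mixing: the target is rank-transformed to
#' normal scores and mixed with independent Gaussian noise at the weight
#' that maps a designed Spearman rho (drawn uniformly in `rhoRange`) to its
#' latent Pearson value; the draw is repeated until the achieved |Spearman|
#' lands inside `rhoRange`.
#'
#' @param n number of samples (required when `target` is `NULL`).
#' @param target optional numeric vector to correlate with.
#' @param dist marginal distribution for uncorrelated features.
#' @param rhoRange designed absolute Spearman range.
#' @param negative if `TRUE` the designed correlation is negative.
#' @param seed optional integer seed.
#' @param maxRetries attempts to land the achieved correlation in range.
#' @return list with `values`, `designedRho`, `achievedRho`.
#' @export
generateNumericFeature <- function(n = NULL, target = NULL,
                                   dist = c("uniform", "gaussian", "negbin"),
                                   rhoRange = c(0.3, 0.6), negative = FALSE,
                                   seed = NULL, maxRetries = 20) {
  .withSeed(seed)
  if (is.null(target)) {
    dist <- match.arg(dist)
    return(list(values = .drawNullFeature(n, dist), designedRho = 0,
                achievedRho = NA_real_))
  }
  if (stats::sd(target) == 0) stop("target has zero variance")
  n <- length(target)
  zt <- stats::qnorm((rank(target, ties.method = "average") - 0.5) / n)
  sgn <- if (negative) -1 else 1
  for (i in seq_len(maxRetries)) {
    rhoS <- stats::runif(1, rhoRange[1], rhoRange[2])
    w <- 2 * sin(pi * rhoS / 6)          # latent Pearson for target Spearman
    if (w > 1 - 1e-12) w <- 1            # exact monotone copy at the limit
    v <- sgn * (w * zt + sqrt(1 - w^2) * stats::rnorm(n))
    ach <- stats::cor(v, target, method = "spearman")
    if (abs(ach) >= rhoRange[1] && abs(ach) <= rhoRange[2])
      return(list(values = v, designedRho = sgn * rhoS, achievedRho = ach))
  }
  stop("could not achieve |Spearman| in [", rhoRange[1], ", ", rhoRange[2],
       "] after ", maxRetries, " attempts")
}

#' Generate a categorical metadata feature
#'
#' A numeric surrogate with a mild designed correlation to the target
#' (|Spearman| in `rhoRange`) is discretized at random quantile boundaries
#' into `nClasses` classes; class labels are then randomly permuted, so the
#' association runs through class membership rather than class order. Only
#' 2, 4, 6 or 8 classes are allowed.
#'
#' @param n number of samples (required when `target` is `NULL`).
#' @param target optional numeric vector the surrogate correlates with.
#' @param nClasses number of classes: 2, 4, 6 or 8.
#' @param rhoRange designed absolute Spearman range for the surrogate.
#' @param seed optional integer seed.
#' @param maxRetries attempts to redraw boundaries that empty a class.
#' @return list with `values` (factor), `designedRho`, `achievedRho` (of the
#'   surrogate), `surrogate`.
#' @export
generateCategoricalFeature <- function(n = NULL, target = NULL,
                                       nClasses = 2, rhoRange = c(0.3, 0.6),
                                       seed = NULL, maxRetries = 20) {
  if (!nClasses %in% c(2, 4, 6, 8))
    stop("nClasses must be one of 2, 4, 6, 8")
  .withSeed(seed)
  if (is.null(target)) {
    surrogate <- stats::rnorm(n)
    designed <- 0; achieved <- NA_real_
  } else {
    n <- length(target)
    if (n < 2 * nClasses) stop("need at least 2 samples per class")
    f <- generateNumericFeature(target = target, rhoRange = rhoRange)
    surrogate <- f$values; designed <- f$designedRho; achieved <- f$achievedRho
  }
  for (i in seq_len(maxRetries)) {
    probs <- sort(stats::runif(nClasses - 1, 0.1, 0.9))
    br <- unique(c(-Inf, .q7(surrogate, probs), Inf))
    cls <- cut(surrogate, br, labels = FALSE)
    if (length(unique(cls)) == nClasses) {
      perm <- sample(nClasses)
      return(list(values = factor(paste0("class_", perm[cls])),
                  designedRho = designed, achievedRho = achieved,
                  surrogate = surrogate))
    }
  }
  stop("could not produce ", nClasses, " non-empty classes")
}

#' Build a full metadata matrix for a community
#'
#' Produces 100 features: 50 numeric and 50 categorical, each half holding
#' 35 random features, 10 features linked to a taxon and 5 linked to the
#' microbial loads. Link targets are drawn without replacement from the
#' non-special taxa; designed |Spearman| values are in `rhoRange`.
#'
#' @param ce a `CommunityExperiment`.
#' @param seed optional integer seed.
#' @param rhoRange designed absolute Spearman range for linked features.
#' @param layout counts per half: random, taxon-linked, load-linked.
#' @return a [MetadataTable-class].
#' @export
buildMetadataMatrix <- function(ce, seed = NULL, rhoRange = c(0.3, 0.6),
                                layout = c(random = 35, taxon = 10, load = 5)) {
  stopifnot(is(ce, "CommunityExperiment"))
  .withSeed(seed)
  n <- ncol(ce)
  cts <- assay(ce, "counts")
  ld <- loads(ce)
  usable <- which(taxonRoles(ce) == "none" &
                    apply(cts, 1, stats::sd) > 0)
  nTaxonLinked <- 2 * layout[["taxon"]]
  if (length(usable) < nTaxonLinked)
    stop("not enough non-special, variable taxa to link metadata to")
  targets <- sample(usable, nTaxonLinked)

  feats <- list(); truth <- list(); k <- 0; tix <- 0
  addFeature <- function(name, values, type, target, designed, achieved,
                         nClasses = NA_integer_) {
    k <<- k + 1
    feats[[name]] <<- values
    truth[[name]] <<- data.frame(feature = name, type = type,
                                 target = target, designedRho = designed,
                                 achievedRho = achieved, nClasses = nClasses,
                                 stringsAsFactors = FALSE)
  }

  for (type in c("numeric", "categorical")) {
    for (i in seq_len(layout[["random"]])) {
      nm <- sprintf("%s_rand_%02d", substr(type, 1, 3), i)
      if (type == "numeric") {
        f <- generateNumericFeature(n = n,
                                    dist = .NUMERIC_DISTS[1 + (i %% 3)])
        addFeature(nm, f$values, type, "none", 0, NA_real_)
      } else {
        nc <- sample(c(2, 4, 6, 8), 1)
        f <- generateCategoricalFeature(n = n, nClasses = nc)
        addFeature(nm, f$values, type, "none", 0, NA_real_, nc)
      }
    }
    for (i in seq_len(layout[["taxon"]])) {
      tix <- tix + 1
      tgt <- targets[tix]
      nm <- sprintf("%s_taxon_%02d", substr(type, 1, 3), i)
      if (type == "numeric") {
        f <- generateNumericFeature(target = cts[tgt, ], rhoRange = rhoRange,
                                    negative = stats::runif(1) < 0.5)
        addFeature(nm, f$values, type, rownames(ce)[tgt], f$designedRho,
                   f$achievedRho)
      } else {
        nc <- sample(c(2, 4, 6, 8), 1)
        f <- generateCategoricalFeature(target = cts[tgt, ], nClasses = nc,
                                        rhoRange = rhoRange)
        addFeature(nm, f$values, type, rownames(ce)[tgt], f$designedRho,
                   f$achievedRho, nc)
      }
    }
    for (i in seq_len(layout[["load"]])) {
      nm <- sprintf("%s_load_%02d", substr(type, 1, 3), i)
      if (type == "numeric") {
        f <- generateNumericFeature(target = ld, rhoRange = rhoRange,
                                    negative = stats::runif(1) < 0.5)
        addFeature(nm, f$values, type, "load", f$designedRho, f$achievedRho)
      } else {
        nc <- sample(c(2, 4, 6, 8), 1)
        f <- generateCategoricalFeature(target = ld, nClasses = nc,
                                        rhoRange = rhoRange)
        addFeature(nm, f$values, type, "load", f$designedRho, f$achievedRho,
                   nc)
      }
    }
  }
  dat <- as.data.frame(feats, row.names = colnames(ce))
  tm <- do.call(rbind, truth)
  rownames(tm) <- NULL
  new("MetadataTable", data = dat, truthMap = tm)
}

#' Build the dysbiosis disease-status variable
#'
#' Labels derive from the community's health groups with a fraction `noise`
#' of labels flipped, emulating imperfect clinical phenotyping. The
#' resulting label must keep a significant negative association with the
#' loads (two-sided Wilcoxon rank-sum, diseased lower) and both classes must
#' exceed a quarter of the cohort.
#'
#' @param ce a dysbiosis `CommunityExperiment`.
#' @param noise fraction of labels flipped; must be below 0.5.
#' @param seed optional integer seed.
#' @return factor of `"healthy"`/`"diseased"` with attributes `"flipped"`
#'   (indices), `"wilcoxP"` (association p-value).
#' @export
buildDiseaseStatus <- function(ce, noise = 0.07, seed = NULL) {
  stopifnot(is(ce, "CommunityExperiment"))
  if (!identical(scenario(ce), "dysbiosis"))
    stop("disease status is defined for the dysbiosis scenario only")
  if (noise >= 0.5)
    stop("noise must be below 0.5 to preserve the association direction")
  .withSeed(seed)
  gr <- sampleGroups(ce)
  n <- length(gr)
  lab <- gr
  nFlip <- round(noise * n)
  flip <- integer(0)
  if (nFlip > 0) {
    flip <- sample(n, nFlip)
    lab[flip] <- ifelse(gr[flip] == "healthy", "diseased", "healthy")
  }
  tabs <- table(lab)
  if (length(tabs) < 2 || any(tabs < 0.25 * n))
    stop("flipping produced a degenerate class balance")
  ld <- loads(ce)
  wt <- stats::wilcox.test(ld[lab == "diseased"], ld[lab == "healthy"],
                           alternative = "two.sided", exact = FALSE)
  if (stats::median(ld[lab == "diseased"]) >= stats::median(ld[lab == "healthy"]) ||
      wt$p.value >= 0.05)
    warning("disease label is not significantly negatively associated with loads")
  structure(factor(lab, levels = c("healthy", "diseased")),
            flipped = sort(flip), wilcoxP = wt$p.value)
}
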