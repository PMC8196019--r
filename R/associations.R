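# Association mapping and recovery scoring: Spearman screens with
# Benjamini-Hochberg correction, confusion classification against the
# ground-truth community, and the method-comparison statistics.

.valuesMatrix <- function(x) {
  if (is(x, "TransformedExperiment")) t(assay(x, "values"))
  else if (is(x, "CommunityExperiment")) t(assay(x, "counts"))
  else if (is(x, "SequenceExperiment")) t(assay(x, "reads"))
  else as.matrix(x)                      # samples x taxa
}

.assocFrame <- function(pair, rho, p, family, alpha) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(pair = pair, family = family, rho = rho, p = p, q = q,
             sign = sign(rho),
             significant = !is.na(q) & q < alpha,
             stringsAsFactors = FALSE)
}

#' Detect associations by correlation screening
#'
#' Runs the benchmark's association tests within one family and applies
#' Benjamini-Hochberg correction across that family:
#' \describe{
#'   \item{taxon_taxon}{Spearman correlation of every unordered taxon pair.}
#'   \item{taxon_load}{Spearman correlation of every taxon against the load
#'     vector in `targets`.}
#'   \item{taxon_metadata}{numeric and 2-class features: Spearman (2-class
#'     features on a 0/1 coding); features with 4 or more classes:
#'     Kruskal-Wallis, with undefined sign.}
#'   \item{taxon_disease}{Spearman of every taxon against the 0/1 disease
#'     label.}
#' }
#' P-values use the t approximation of the Spearman test (the convention of
#' [stats::cor.test()] under ties). Pairs involving a constant vector get
#' `NA` statistics and are never significant.
#'
#' @param x taxa data: a `CommunityExperiment`, `TransformedExperiment`,
#'   `SequenceExperiment` or samples x taxa matrix.
#' @param targets the other side of the pairs: `NULL` for taxon-taxon, a
#'   numeric vector for taxon-load, a [MetadataTable-class] (or data.frame)
#'   for taxon-metadata, a 2-level factor for taxon-disease.
#' @param family the analysis family.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.frame with columns pair, family, rho, p, q, sign,
#'   significant.
#' @export
detectAssociations <- function(x, targets = NULL,
                               family = c("taxon_taxon", "taxon_load",
                                          "taxon_metadata", "taxon_disease"),
                               alpha = 0.05) {
  family <- match.arg(family)
  m <- .valuesMatrix(x)
  taxa <- colnames(m)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(ncol(m)))

  if (family == "taxon_taxon") {
    sp <- .spearman(m)
    ut <- upper.tri(sp$rho)
    ij <- which(ut, arr.ind = TRUE)
    return(.assocFrame(paste(taxa[ij[, 1]], taxa[ij[, 2]], sep = "|"),
                       sp$rho[ut], sp$p[ut], family, alpha))
  }

  if (family %in% c("taxon_load", "taxon_disease")) {
    y <- if (family == "taxon_disease") {
      stopifnot(nlevels(as.factor(targets)) == 2)
      as.numeric(as.factor(targets)) - 1
    } else as.numeric(targets)
    stopifnot(length(y) == nrow(m))
    sp <- .spearman(m, y)
    return(.assocFrame(taxa, drop(sp$rho), drop(sp$p), family, alpha))
  }

  # taxon_metadata
  md <- if (is(targets, "MetadataTable")) metadataFeatures(targets)
        else as.data.frame(targets)
  stopifnot(nrow(md) == nrow(m))
  pair <- rho <- p <- NULL
  isNum <- vapply(md, is.numeric, logical(1))
  numLike <- md[isNum]
  for (nm in names(md)[!isNum]) {     # categorical features
    f <- as.factor(md[[nm]])
    if (nlevels(f) == 2) {
      numLike[[nm]] <- as.numeric(f) - 1
    } else {
      kw <- .kruskalCols(m, f)
      pair <- c(pair, paste(taxa, nm, sep = "|"))
      rho <- c(rho, rep(NA_real_, length(taxa)))
      p <- c(p, kw$p)
    }
  }
  if (length(numLike)) {
    sp <- .spearman(m, as.matrix(as.data.frame(numLike)))
    pair <- c(pair, as.vector(outer(taxa, names(numLike), paste, sep = "|")))
    rho <- c(rho, as.vector(sp$rho))
    p <- c(p, as.vector(sp$p))
  }
  .assocFrame(pair, rho, p, family, alpha)
}

#' Classify detected associations against a reference set
#'
#' True positives are associations significant in both the reference
#' (ground-truth community) and the test matrix with the same sign;
#' associations significant in both but with opposite signs are discordant
#' and penalize both precision (counted as false positives) and sensitivity
#' (counted as false negatives). When either side has an undefined sign
#' (Kruskal-Wallis families), joint significance counts as a true positive.
#'
#' @param ref,test association data.frames from [detectAssociations()] over
#'   the same pair universe.
#' @return one-row data.frame with TP, FP, FN, TN, discordant, precision,
#'   sensitivity and FPR (rates are `NA` when their denominator is 0).
#' @export
classifyVsReference <- function(ref, test) {
  if (nrow(ref) != nrow(test) || !setequal(ref$pair, test$pair))
    stop("reference and test cover different pair universes")
  test <- test[match(ref$pair, test$pair), ]
  bothSig <- ref$significant & test$significant
  signKnown <- !is.na(ref$sign) & !is.na(test$sign) & ref$sign != 0 &
    test$sign != 0
  tp <- sum(bothSig & (!signKnown | ref$sign == test$sign))
  disc <- sum(bothSig & signKnown & ref$sign != test$sign)
  fpOnly <- sum(!ref$significant & test$significant)
  fnOnly <- sum(ref$significant & !test$significant)
  tn <- sum(!ref$significant & !test$significant)
  fp <- fpOnly + disc
  fn <- fnOnly + disc
  data.frame(TP = tp, FP = fpOnly, FN = fnOnly, TN = tn, discordant = disc,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

#' Categorize a richness correlation
#'
#' Pearson correlation between reference and comparison per-sample richness,
#' classified as strong (R > 0.8, p < 0.05), moderate (0.5 < R <= 0.8),
#' mild (0 < R <= 0.5), negative (R < 0, p < 0.05) or non-significant
#' (p >= 0.05).
#'
#' @param reference,comparison numeric vectors (e.g. per-sample observed
#'   richness).
#' @return one-row data.frame with R, p and category.
#' @export
richnessCorrelation <- function(reference, comparison) {
  if (stats::sd(reference) == 0 || stats::sd(comparison) == 0)
    return(data.frame(R = NA_real_, p = NA_real_,
                      category = "non-significant"))
  ct <- stats::cor.test(reference, comparison)
  R <- unname(ct$estimate); p <- ct$p.value
  category <- if (p >= 0.05) "non-significant"
  else if (R > 0.8) "strong"
  else if (R > 0.5) "moderate"
  else if (R > 0) "mild"
  else "negative"
  data.frame(R = R, p = p, category = category, stringsAsFactors = FALSE)
}

#' Confusion summaries restricted to special taxa
#'
#' Subsets an association comparison to the pairs involving each
#' special-taxon role (bloomer, opportunist, unresponsive, succession) and
#' classifies each subset separately.
#'
#' @param ref,test association data.frames over the same universe.
#' @param roles named character vector of taxon roles (from
#'   [taxonRoles()]).
#' @return data.frame with one row per role present.
#' @export
specialTaxaEval <- function(ref, test, roles) {
  special <- roles[roles != "none"]
  out <- lapply(unique(special), function(role) {
    taxaR <- names(special)[special == role]
    pat <- paste0("(^|\\|)(", paste(taxaR, collapse = "|"), ")($|\\|)")
    keep <- grepl(pat, ref$pair)
    if (!any(keep))
      return(cbind(data.frame(role = role, n = 0), classifyVsReference(
        ref[0, ], test[0, ])))
    cbind(data.frame(role = role, n = sum(keep)),
          classifyVsReference(ref[keep, ], test[match(ref$pair[keep],
                                                      test$pair), ]))
  })
  do.call(rbind, out)
}

#' Dunn's post-hoc test of multiple groups
#'
#' Pairwise z statistics on the joint ranks with the tie-corrected variance,
#' two-sided p-values and multiplicity adjustment (BH by default). With two
#' groups it reduces to the normal approximation of the rank-sum test.
#'
#' @param x numeric response values.
#' @param g group labels.
#' @param method multiplicity adjustment passed to [stats::p.adjust()].
#' @return data.frame with one row per group pair: `group1`, `group2`, `Z`
#'   (positive when `group1` ranks higher), `p`, `p.adj`.
#' @export
dunnTest <- function(x, g, method = "BH") {
  g <- as.factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pp) {
    i <- pp[1]; j <- pp[2]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ng[[i]] + 1 / ng[[j]]))
    z <- (mr[[i]] - mr[[j]]) / se
    c(Z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    Z = res["Z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p.adj <- stats::p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}

#' Compare methods on a benchmark metric
#'
#' Kruskal-Wallis omnibus test of the metric across methods, followed by
#' Dunn's post-hoc pairwise comparisons (BH-adjusted, two-sided) when the
#' omnibus test is computable.
#'
#' @param df data.frame of per-replicate metric values.
#' @param value name of the metric column.
#' @param group name of the method column.
#' @return list with `kruskal` (htest) and `dunn` (data.frame, `NULL` when
#'   degenerate).
#' @export
compareMethods <- function(df, value, group = "method") {
  x <- df[[value]]; g <- as.factor(df[[group]])
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || length(x) < 3)
    stop("need at least two methods with three values")
  if (length(unique(x)) == 1)
    return(list(kruskal = NULL, dunn = NULL,
                note = "all values tied; omnibus undefined"))
  kw <- stats::kruskal.test(x, g)
  list(kruskal = kw, dunn = dunnTest(x, g))
}
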