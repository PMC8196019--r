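# Alpha diversity: observed richness, Chao1, Shannon, Simpson (1-D), with
# the per-transformation applicability rules of the benchmark.

.DIVERSITY_INDICES <- c("observed", "chao1", "shannon", "simpson")

#' Which diversity indices a transformation supports
#'
#' CLR and VST produce negative values and Rel and AST produce values in
#' `[0, 1]` only; none of the four supports count-based diversity
#' estimation. All other methods are allowed, after rounding to the nearest
#' integer where the method leaves the count scale.
#'
#' @param method a tag from [transformMethods()].
#' @return named logical vector over the four indices.
#' @export
applicabilityMask <- function(method) {
  fl <- methodFlags(method)
  ok <- fl$diversitySuitable
  stats::setNames(rep(ok, 4), .DIVERSITY_INDICES)
}

.alphaDiversityMatrix <- function(m, indices, chao1Variant = "bias-corrected",
                                  round = TRUE) {
  indices <- match.arg(indices, .DIVERSITY_INDICES, several.ok = TRUE)
  if (round) m <- base::round(m)
  if (any(m < 0)) stop("diversity is undefined for negative abundances")
  res <- as.data.frame(matrix(nrow = ncol(m), ncol = 0),
                       row.names = colnames(m))
  tot <- colSums(m)
  p <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
  if ("observed" %in% indices) res$observed <- colSums(m > 0)
  if ("chao1" %in% indices) {
    sObs <- colSums(m > 0)
    f1 <- colSums(m == 1)
    f2 <- colSums(m == 2)
    res$chao1 <- if (chao1Variant == "bias-corrected")
      sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
    else
      sObs + ifelse(f2 > 0, f1^2 / (2 * f2), f1 * (f1 - 1) / 2)
  }
  if ("shannon" %in% indices)
    res$shannon <- -colSums(ifelse(p > 0, p * log(p), 0))
  if ("simpson" %in% indices) res$simpson <- 1 - colSums(p^2)
  res
}

#' @describeIn alphaDiversity indices of a plain abundance matrix
#'   (taxa x samples); values are rounded to the nearest integer first
#'   unless `round = FALSE`.
#' @param chao1Variant `"bias-corrected"` (default, finite when no
#'   doubletons exist) or `"classic"`.
#' @param round round values to the nearest integer before computing.
#' @export
setMethod("alphaDiversity", "matrix",
  function(x, indices = c("observed", "chao1", "shannon", "simpson"),
           chao1Variant = c("bias-corrected", "classic"), round = TRUE) {
    .alphaDiversityMatrix(x, indices, match.arg(chao1Variant), round)
  })

#' @describeIn alphaDiversity indices of the ground-truth community
#'   (absolute cell counts).
#' @export
setMethod("alphaDiversity", "CommunityExperiment",
  function(x, indices = c("observed", "chao1", "shannon", "simpson"), ...) {
    .alphaDiversityMatrix(assay(x, "counts"), indices, "bias-corrected",
                          round = TRUE)
  })

#' @describeIn alphaDiversity indices of a transformed matrix; refuses
#'   methods whose output does not support diversity estimation and rounds
#'   to the nearest integer where the method requires it.
#' @export
setMethod("alphaDiversity", "TransformedExperiment",
  function(x, indices = c("observed", "chao1", "shannon", "simpson"),
           chao1Variant = c("bias-corrected", "classic")) {
    fl <- metadata(x)$flags
    if (!fl$diversitySuitable)
      stop("diversity indices are not defined for ", fl$method,
           "-transformed data (", fl$diversityNote, ")")
    .alphaDiversityMatrix(assay(x, "values"), indices,
                          match.arg(chao1Variant), round = TRUE)
  })
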