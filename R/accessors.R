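#' @describeIn CommunityExperiment per-sample microbial loads (cells/g).
#' @param x a `CommunityExperiment`.
#' @export
setMethod("loads", "CommunityExperiment", function(x) {
  stats::setNames(x$load, colnames(x))
})

#' @describeIn SequenceExperiment the true loads of the parent community.
#' @param x a `SequenceExperiment`.
#' @export
setMethod("loads", "SequenceExperiment", function(x) {
  if (!"load" %in% names(colData(x))) return(NULL)
  stats::setNames(x$load, colnames(x))
})

#' @describeIn LoadEstimates the true loads.
#' @param x a `LoadEstimates`.
#' @export
setMethod("loads", "LoadEstimates", function(x) x@trueLoads)

setMethod("scenario", "SummarizedExperiment",
          function(x) metadata(x)$scenario)

setMethod("taxonRoles", "SummarizedExperiment", function(x) {
  if (!"role" %in% names(rowData(x))) return(NULL)
  stats::setNames(as.character(rowData(x)$role), rownames(x))
})

setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  if (!"group" %in% names(colData(x))) return(NULL)
  stats::setNames(as.character(x$group), colnames(x))
})

#' @describeIn SequenceExperiment per-sample library sizes.
#' @export
setMethod("librarySizes", "SequenceExperiment", function(x) {
  stats::setNames(x$libSize, colnames(x))
})

#' @describeIn TransformedExperiment the transformation tag.
#' @param x a `TransformedExperiment`.
#' @export
setMethod("transformMethod", "TransformedExperiment",
          function(x) metadata(x)$method)

#' @describeIn LoadEstimates the noisy estimates.
#' @export
setMethod("estimatedLoads", "LoadEstimates", function(x) x@estimatedLoads)

#' @describeIn LoadEstimates achieved log-scale Pearson correlation.
#' @export
setMethod("achievedR", "LoadEstimates", function(x) x@achievedR)

#' Feature table of a MetadataTable
#' @param x a `MetadataTable`.
#' @return data.frame of features (samples in rows).
#' @export
metadataFeatures <- function(x) {
  stopifnot(is(x, "MetadataTable"))
  x@data
}

#' Ground-truth association map of a MetadataTable
#' @param x a `MetadataTable`.
#' @return data.frame with the designed target and correlation per feature.
#' @export
truthMap <- function(x) {
  stopifnot(is(x, "MetadataTable"))
  x@truthMap
}

setMethod("show", "CommunityExperiment", function(object) {
  cat(sprintf("CommunityExperiment: %d taxa x %d samples [%s]\n",
              nrow(object), ncol(object), scenario(object)))
  ld <- loads(object)
  cat(sprintf("  loads: %.3g - %.3g cells/g (spread %.1f)\n",
              min(ld), max(ld), max(ld) / min(ld)))
  sp <- taxonRoles(object)
  sp <- sp[sp != "none"]
  if (length(sp))
    cat("  special taxa:", paste(sprintf("%s(%s)", names(sp), sp),
                                 collapse = ", "), "\n")
  gr <- sampleGroups(object)
  if (!is.null(gr)) cat("  groups:", paste(names(table(gr)), table(gr),
                                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SequenceExperiment", function(object) {
  cat(sprintf("SequenceExperiment: %d taxa x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  library sizes: %d - %d (median %d)\n",
              as.integer(min(object$libSize)), as.integer(max(object$libSize)),
              as.integer(stats::median(object$libSize))))
})

setMethod("show", "TransformedExperiment", function(object) {
  fl <- metadata(object)$flags
  cat(sprintf("TransformedExperiment [%s]: %d taxa x %d samples (unit: %s)\n",
              transformMethod(object), nrow(object), ncol(object), fl$unit))
  cat(sprintf("  diversity-suitable: %s%s\n", fl$diversitySuitable,
              if (isTRUE(fl$requiresRounding)) " (after rounding)" else ""))
})

setMethod("show", "LoadEstimates", function(object) {
  cat(sprintf(
    "LoadEstimates: %d samples, achieved log-scale r = %.3f (target %.3f)\n",
    length(object@trueLoads), object@achievedR, object@targetR))
})

setMethod("show", "MetadataTable", function(object) {
  tm <- object@truthMap
  cat(sprintf("MetadataTable: %d samples x %d features (%d numeric, %d categorical)\n",
              nrow(object@data), ncol(object@data),
              sum(tm$type == "numeric"), sum(tm$type == "categorical")))
  cat(sprintf("  designed links: %d taxon, %d load, %d random\n",
              sum(!tm$target %in% c("none", "load")),
              sum(tm$target == "load"), sum(tm$target == "none")))
})
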