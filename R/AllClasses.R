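#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

.SCENARIOS <- c("blooming", "succession", "dysbiosis")
.ROLES <- c("none", "bloomer", "succession", "opportunist", "unresponsive")

#' Ground-truth community matrix with per-sample microbial loads
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' simulation ground truth: absolute abundances (cells/g) in the `"counts"`
#' assay (taxa in rows, samples in columns), per-sample microbial loads in
#' `colData()$load` (always the column sums of the counts), the ecological
#' scenario in `metadata()$scenario`, special-taxon roles (bloomer,
#' succession, opportunist, unresponsive) in `rowData()$role`, and, for the
#' dysbiosis scenario, health-group labels in `colData()$group`.
#'
#' @aliases CommunityExperiment-class
#' @export
setClass("CommunityExperiment", contains = "SummarizedExperiment")

#' Simulated metagenomic read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding integer
#' read counts (`"reads"` assay, taxa in rows), per-sample library sizes in
#' `colData()$libSize` (always the column sums), and the true microbial load
#' of the parent community in `colData()$load`.
#'
#' @aliases SequenceExperiment-class
#' @export
setClass("SequenceExperiment", contains = "SummarizedExperiment")

#' A sequence matrix after one of the thirteen benchmark transformations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' transformed values (`"values"` assay), the method tag in
#' `metadata()$method` and its capability flags (diversity suitability,
#' rounding requirement, sign, unit) in `metadata()$flags`.
#'
#' @aliases TransformedExperiment-class
#' @export
setClass("TransformedExperiment", contains = "SummarizedExperiment")

#' Simulated experimental measurement of microbial loads
#'
#' Result of the flow-cytometry-like measurement model: true loads, noisy
#' estimates, and the achieved log-scale Pearson correlation between them.
#'
#' @slot trueLoads numeric, simulated ground-truth loads (cells/g).
#' @slot estimatedLoads numeric, noisy estimates (cells/g).
#' @slot achievedR achieved Pearson correlation of the log loads.
#' @slot targetR the target correlation the noise level was solved for.
#' @export
setClass("LoadEstimates", representation(
  trueLoads = "numeric", estimatedLoads = "numeric",
  achievedR = "numeric", targetR = "numeric"))

#' Simulated metadata with a ground-truth association map
#'
#' @slot data data.frame of features (samples in rows); numeric and
#'   categorical columns.
#' @slot truthMap data.frame with one row per feature: `feature`, `type`
#'   (numeric/categorical), `target` (`"none"`, `"load"`, or a taxon name),
#'   `designedRho`, `achievedRho`, `nClasses`.
#' @export
setClass("MetadataTable", representation(
  data = "data.frame", truthMap = "data.frame"))

setValidity("CommunityExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (!"load" %in% names(colData(object)))
      msg <- c(msg, "colData column 'load' is required")
    else {
      ld <- object$load
      if (any(abs(ld - colSums(cts)) > 1e-6 * pmax(ld, 1)))
        msg <- c(msg, "loads must equal the column sums of counts")
    }
  }
  sc <- metadata(object)$scenario
  if (is.null(sc) || !sc %in% .SCENARIOS)
    msg <- c(msg, "metadata()$scenario must be one of blooming/succession/dysbiosis")
  if (!"role" %in% names(rowData(object)))
    msg <- c(msg, "rowData column 'role' is required")
  else if (!all(rowData(object)$role %in% .ROLES))
    msg <- c(msg, "unknown taxon role")
  if (length(msg)) msg else TRUE
})

setValidity("SequenceExperiment", function(object) {
  msg <- character()
  if (!"reads" %in% names(assays(object)))
    msg <- c(msg, "assay 'reads' is required")
  else {
    rd <- assay(object, "reads")
    if (any(rd < 0) || any(rd != round(rd)))
      msg <- c(msg, "reads must be nonnegative integers")
    if (!"libSize" %in% names(colData(object)))
      msg <- c(msg, "colData column 'libSize' is required")
    else if (any(object$libSize != colSums(rd)))
      msg <- c(msg, "library sizes must equal the column sums of reads")
  }
  if (length(msg)) msg else TRUE
})

setValidity("TransformedExperiment", function(object) {
  msg <- character()
  if (!"values" %in% names(assays(object)))
    msg <- c(msg, "assay 'values' is required")
  m <- metadata(object)$method
  if (is.null(m) || !m %in% transformMethods())
    msg <- c(msg, "metadata()$method must be one of the 13 registered methods")
  if (length(msg)) msg else TRUE
})

setValidity("LoadEstimates", function(object) {
  msg <- character()
  if (length(object@trueLoads) != length(object@estimatedLoads))
    msg <- c(msg, "true and estimated loads must have equal length")
  if (any(object@estimatedLoads <= 0)) msg <- c(msg, "estimated loads must be positive")
  if (length(msg)) msg else TRUE
})

# ---- constructors ----------------------------------------------------------

#' Construct a CommunityExperiment
#'
#' @param counts numeric matrix of absolute abundances, taxa x samples.
#' @param scenario one of `"blooming"`, `"succession"`, `"dysbiosis"`.
#' @param roles character vector of per-taxon roles (default all `"none"`).
#' @param groups optional per-sample health labels (`"healthy"`/`"diseased"`).
#' @param nbParams optional data.frame of per-taxon negative-binomial
#'   parameters (`size`, `prob`).
#' @param loadScale the global cells-per-count scaling constant applied to
#'   place loads in the biological range.
#' @return a [CommunityExperiment-class] object.
#' @export
CommunityExperiment <- function(counts, scenario, roles = NULL, groups = NULL,
                                nbParams = NULL, loadScale = NA_real_) {
  .checkCountMatrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (is.null(roles)) roles <- rep("none", nrow(counts))
  cd <- DataFrame(load = colSums(counts), row.names = colnames(counts))
  if (!is.null(groups)) cd$group <- groups
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = cd,
    rowData = DataFrame(role = roles, row.names = rownames(counts)))
  metadata(se) <- list(scenario = scenario, nbParams = nbParams,
                       loadScale = loadScale)
  new("CommunityExperiment", se)
}

#' Construct a SequenceExperiment
#'
#' @param reads integer matrix of read counts, taxa x samples.
#' @param loads optional true microbial loads of the parent community.
#' @param groups optional per-sample health labels.
#' @param scenario optional parent scenario tag.
#' @param roles optional per-taxon roles carried over from the community.
#' @return a [SequenceExperiment-class] object.
#' @export
SequenceExperiment <- function(reads, loads = NULL, groups = NULL,
                               scenario = NULL, roles = NULL) {
  .checkCountMatrix(reads, "reads")
  storage.mode(reads) <- "double"
  if (is.null(rownames(reads)))
    rownames(reads) <- paste0("taxon_", seq_len(nrow(reads)))
  if (is.null(colnames(reads)))
    colnames(reads) <- paste0("sample_", seq_len(ncol(reads)))
  cd <- DataFrame(libSize = colSums(reads), row.names = colnames(reads))
  if (!is.null(loads)) cd$load <- loads
  if (!is.null(groups)) cd$group <- groups
  if (is.null(roles)) roles <- rep("none", nrow(reads))
  se <- SummarizedExperiment(
    assays = list(reads = reads), colData = cd,
    rowData = DataFrame(role = roles, row.names = rownames(reads)))
  metadata(se) <- list(scenario = scenario)
  new("SequenceExperiment", se)
}

.TransformedExperiment <- function(values, template, method,
                                   estimatedLoads = NULL) {
  cd <- colData(template)
  if (!is.null(estimatedLoads)) cd$estimatedLoad <- estimatedLoads
  se <- SummarizedExperiment(assays = list(values = values),
                             colData = cd, rowData = rowData(template))
  metadata(se) <- c(metadata(template)[intersect("scenario",
                                                 names(metadata(template)))],
                    list(method = method, flags = methodFlags(method)))
  new("TransformedExperiment", se)
}
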