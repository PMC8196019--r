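#' Per-sample microbial loads (cells/g)
#' @param x a CommunityExperiment, SequenceExperiment or LoadEstimates.
#' @return numeric vector of loads.
#' @export
setGeneric("loads", function(x) standardGeneric("loads"))

#' Ecological scenario tag
#' @param x a CommunityExperiment or derived object.
#' @return `"blooming"`, `"succession"` or `"dysbiosis"` (or `NULL`).
#' @export
setGeneric("scenario", function(x) standardGeneric("scenario"))

#' Special-taxon roles
#' @param x an object with per-taxon role annotation.
#' @return named character vector of roles.
#' @export
setGeneric("taxonRoles", function(x) standardGeneric("taxonRoles"))

#' Per-sample health-group labels (dysbiosis scenario)
#' @param x a CommunityExperiment or derived object.
#' @return character vector of `"healthy"`/`"diseased"`, or `NULL`.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Per-sample library sizes (total reads)
#' @param x a SequenceExperiment.
#' @return numeric vector of library sizes.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' Transformation method tag of a transformed matrix
#' @param x a TransformedExperiment.
#' @return the method abbreviation (e.g. `"QMP"`).
#' @export
setGeneric("transformMethod", function(x) standardGeneric("transformMethod"))

#' Noisy load estimates
#' @param x a LoadEstimates object.
#' @return numeric vector of estimated loads (cells/g).
#' @export
setGeneric("estimatedLoads", function(x) standardGeneric("estimatedLoads"))

#' Achieved log-scale correlation of a load measurement
#' @param x a LoadEstimates object.
#' @return Pearson correlation between log true and log estimated loads.
#' @export
setGeneric("achievedR", function(x) standardGeneric("achievedR"))

#' Alpha diversity indices
#'
#' @param x a matrix (taxa x samples), CommunityExperiment or
#'   TransformedExperiment.
#' @param indices which of `"observed"`, `"chao1"`, `"shannon"`, `"simpson"`
#'   to compute.
#' @param ... further arguments (`chao1Variant`, `round`).
#' @return data.frame with one row per sample and one column per index.
#' @export
setGeneric("alphaDiversity",
           function(x, indices = c("observed", "chao1", "shannon", "simpson"),
                    ...) standardGeneric("alphaDiversity"))
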