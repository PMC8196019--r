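# Plain-text serialization: TSV dialects for communities, sequence
# matrices, load estimates and metadata, plus optional BIOM export.

.writeMatrixTSV <- function(m, file) {
  # samples x taxa on disk, first column = sample IDs
  df <- data.frame(sample = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTSV <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  if (names(df)[1] != "sample")
    stop("malformed matrix TSV (", file, "): first column must be 'sample'")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$sample
  m
}

#' Write a community matrix and its sidecar annotation
#'
#' The counts go to `file` (samples x taxa TSV, first column sample IDs);
#' loads, scenario, group labels and special-taxon roles go to sidecar TSVs
#' named `<file>.samples.tsv` and `<file>.taxa.tsv`.
#'
#' @param ce a `CommunityExperiment`.
#' @param file path of the counts TSV.
#' @return `file`, invisibly.
#' @export
writeCommunityTSV <- function(ce, file) {
  stopifnot(is(ce, "CommunityExperiment"))
  .writeMatrixTSV(assay(ce, "counts"), file)
  gr <- sampleGroups(ce)
  samp <- data.frame(sample = colnames(ce), load = loads(ce),
                     scenario = scenario(ce),
                     group = if (is.null(gr)) NA_character_ else gr)
  utils::write.table(samp, paste0(file, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tax <- data.frame(taxon = rownames(ce), role = taxonRoles(ce))
  utils::write.table(tax, paste0(file, ".taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a community matrix written by [writeCommunityTSV()]
#' @param file path of the counts TSV.
#' @return a [CommunityExperiment-class].
#' @export
readCommunityTSV <- function(file) {
  m <- .readMatrixTSV(file)
  samp <- utils::read.table(paste0(file, ".samples.tsv"), sep = "\t",
                            header = TRUE)
  tax <- utils::read.table(paste0(file, ".taxa.tsv"), sep = "\t",
                           header = TRUE)
  if (!identical(as.character(samp$sample), colnames(m)))
    stop("sample sidecar does not match the counts matrix for ", file)
  groups <- if (all(is.na(samp$group))) NULL else as.character(samp$group)
  CommunityExperiment(m, scenario = unique(samp$scenario),
                      roles = as.character(tax$role), groups = groups)
}

#' Write / read a sequence matrix as TSV
#'
#' Integer read counts, samples x taxa, first column sample IDs; library
#' sizes are recoverable as row sums.
#'
#' @param se a `SequenceExperiment`.
#' @param file TSV path.
#' @return `file` (write) or a [SequenceExperiment-class] (read).
#' @export
writeSequenceTSV <- function(se, file) {
  stopifnot(is(se, "SequenceExperiment"))
  .writeMatrixTSV(assay(se, "reads"), file)
  invisible(file)
}

#' @rdname writeSequenceTSV
#' @export
readSequenceTSV <- function(file) {
  SequenceExperiment(.readMatrixTSV(file))
}

#' Write / read load estimates as TSV
#' @param le a `LoadEstimates`.
#' @param file TSV path.
#' @param samples optional sample names.
#' @return `file` (write) or a [LoadEstimates-class] (read).
#' @export
writeLoadEstimatesTSV <- function(le, file, samples = NULL) {
  stopifnot(is(le, "LoadEstimates"))
  if (is.null(samples)) samples <- paste0("sample_", seq_along(loads(le)))
  utils::write.table(
    data.frame(sample = samples, true_load = loads(le),
               estimated_load = estimatedLoads(le)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLoadEstimatesTSV
#' @export
readLoadEstimatesTSV <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE)
  new("LoadEstimates", trueLoads = df$true_load,
      estimatedLoads = df$estimated_load,
      achievedR = stats::cor(log(df$true_load), log(df$estimated_load)),
      targetR = NA_real_)
}

#' Write / read a metadata table (features + truth map) as TSV
#' @param md a `MetadataTable`.
#' @param file path of the feature TSV; the truth map goes to
#'   `<file>.truth.tsv`.
#' @return `file` (write) or a [MetadataTable-class] (read).
#' @export
writeMetadataTSV <- function(md, file) {
  stopifnot(is(md, "MetadataTable"))
  dat <- metadataFeatures(md)
  utils::write.table(data.frame(sample = rownames(dat), dat),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truthMap(md), paste0(file, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMetadataTSV
#' @export
readMetadataTSV <- function(file) {
  dat <- utils::read.table(file, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(dat) <- dat$sample
  dat$sample <- NULL
  tm <- utils::read.table(paste0(file, ".truth.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  for (nm in tm$feature[tm$type == "categorical"])
    dat[[nm]] <- factor(dat[[nm]])
  new("MetadataTable", data = dat, truthMap = tm)
}

#' Export counts to a BIOM table
#'
#' Writes a BIOM-format table (via the biomformat package) with microbial
#' loads or library sizes attached as sample metadata.
#'
#' @param x a `CommunityExperiment` or `SequenceExperiment`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportBIOM <- function(x, file) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM export")
  m <- if (is(x, "CommunityExperiment")) assay(x, "counts")
       else assay(x, "reads")
  smeta <- if (is(x, "CommunityExperiment"))
    data.frame(load = loads(x), row.names = colnames(m))
  else data.frame(libSize = librarySizes(x), row.names = colnames(m))
  b <- biomformat::make_biom(data = m, sample_metadata = smeta)
  biomformat::write_biom(b, file)
  invisible(file)
}
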