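#' Relative-abundance matrix of a community
#'
#' @param x a [TRFCommunity-class].
#' @return numeric matrix, bins x samples; columns sum to 1 (0 for empty
#'   samples).
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' Representative bin sizes (bp)
#'
#' @param x a [TRFCommunity-class].
#' @return numeric vector of representative (mean member) sizes.
#' @export
setGeneric("binSizes", function(x) standardGeneric("binSizes"))

#' Bin labels
#'
#' @param x a [TRFCommunity-class].
#' @return character vector of bin labels (size to one decimal).
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' Restriction enzyme a community profile derives from
#'
#' @param x a [TRFCommunity-class].
#' @return enzyme name (character).
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))

#' Binning gap tolerance of a community matrix
#'
#' @param x a [TRFCommunity-class].
#' @return gap tolerance in bp.
#' @export
setGeneric("gapTolerance", function(x) standardGeneric("gapTolerance"))

#' Per-sample diversity indices
#'
#' @param x a relative-abundance vector (summing to 1) or a
#'   [TRFCommunity-class].
#' @param ... passed to methods.
#' @return a data.frame with columns `S` (richness), `shannon` (H', nats),
#'   `evenness` (J' = H'/ln S, 0 when S = 1), `dominance` (D = sum p_i^2),
#'   `simpson_complement` (1 - D) and `simpson_reciprocal` (1/D); one row
#'   per sample for a community, a single row for a vector.
#' @export
setGeneric("diversityIndices",
           function(x, ...) standardGeneric("diversityIndices"))

#' Bray-Curtis dissimilarity
#'
#' @param x a [TRFCommunity-class] or a samples x features abundance matrix
#'   with normalised rows.
#' @param ... passed to methods.
#' @return a [stats::dist] of pairwise Bray-Curtis dissimilarities
#'   d = sum|x - y| / sum(x + y), labelled by sample.
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' Core / shared / unique ribotype classification
#'
#' @param x a [TRFCommunity-class].
#' @param grouping named vector mapping every sample to a group.
#' @param ... passed to methods.
#' @return a `ribotypeClassification` list with elements `core` (bins present
#'   in every group), `shared` (named list: bin -> groups, for bins in two
#'   or more but not all groups) and `unique` (named list: group -> bins
#'   found only in that group). The three parts partition the detected bins.
#' @export
setGeneric("classifyTRFs",
           function(x, grouping, ...) standardGeneric("classifyTRFs"))
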