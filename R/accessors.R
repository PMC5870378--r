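#' @describeIn relAbundance bins x samples relative-abundance matrix.
#' @export
setMethod("relAbundance", "TRFCommunity", function(x) {
  SummarizedExperiment::assay(x, "relabund")
})

#' @describeIn binSizes representative sizes of a community's bins.
#' @export
setMethod("binSizes", "TRFCommunity", function(x) {
  SummarizedExperiment::rowData(x)$binSize
})

#' @describeIn binLabels labels of a community's bins.
#' @export
setMethod("binLabels", "TRFCommunity", function(x) {
  SummarizedExperiment::rowData(x)$binLabel
})

#' @describeIn enzymeName enzyme recorded for a community matrix.
#' @export
setMethod("enzymeName", "TRFCommunity", function(x) {
  S4Vectors::metadata(x)$enzyme
})

#' @describeIn gapTolerance binning tolerance recorded for a community
#'   matrix.
#' @export
setMethod("gapTolerance", "TRFCommunity", function(x) {
  S4Vectors::metadata(x)$gapTolerance
})

setMethod("show", "TRFCommunity", function(object) {
  cat(sprintf("TRFCommunity: %d T-RF bin%s x %d sample%s (enzyme %s)\n",
              nrow(object), if (nrow(object) == 1) "" else "s",
              ncol(object), if (ncol(object) == 1) "" else "s",
              S4Vectors::metadata(object)$enzyme))
  sizes <- SummarizedExperiment::rowData(object)$binSize
  if (length(sizes))
    cat(sprintf("  bin sizes: %.1f-%.1f bp; gap tolerance %.2g bp\n",
                min(sizes), max(sizes),
                S4Vectors::metadata(object)$gapTolerance))
  cat("  samples:", paste(utils::head(colnames(object), 8), collapse = ", "),
      if (ncol(object) > 8) "..." else "", "\n")
})

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s: 5'-%s-3'%s\n", object@name, object@sequence,
              if (object@labeled) " [5' labeled]" else ""))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  site <- object@site
  cut <- paste0(substr(site, 1, object@cutOffset), "^",
                substr(site, object@cutOffset + 1L, nchar(site)))
  cat(sprintf("RestrictionEnzyme %s: %s\n", object@name, cut))
})

setMethod("show", "NMDSResult", function(object) {
  cat(sprintf(
    "NMDS ordination: %d samples in %d dimensions\n  Kruskal stress-1 = %.5f (best of %d starts%s)\n",
    nrow(object@coordinates), ncol(object@coordinates), object@stress,
    object@nStarts, if (object@converged) ", converged" else ""))
})

setMethod("show", "ANOSIMResult", function(object) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d %s)\n",
              object@R, object@pValue, object@method, object@nPermutations,
              if (object@method == "exact") "distinct labelings"
              else "permutations"))
  if (nrow(object@pairwise)) {
    cat("  pairwise:\n")
    print(object@pairwise, row.names = FALSE)
  }
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %d taxa, %d groups (%d samples), effect size %.2g\n",
    object@nTaxa, length(object@groups), sum(object@groups),
    object@effectSize))
  cat(sprintf(
    "  noise: sampleLogSD %.2g, areaCV %.2g, size jitter %.2g bp, floor %.3g\n",
    object@sampleLogSD, object@areaCV, object@sizeJitterSD,
    object@detectionFloor))
  cat(sprintf("  %d replicate run(s), seed %d\n", object@nReplicateRuns,
              object@seed))
})

setMethod("show", "ScenarioTruth", function(object) {
  cat(sprintf(
    "ScenarioTruth: %d taxa, %d samples in %d groups\n",
    length(object@sequences), nrow(object@abundances),
    nlevels(object@groups)))
})

#' Accessors for scenario ground truth
#'
#' @param truth a [ScenarioTruth-class].
#' @return `truthAbundances`: samples x taxa matrix of true relative
#'   abundances; `truthGroups`: factor of sample group memberships;
#'   `truthSequences`: `DNAStringSet` of taxon templates; `truthTRFs`:
#'   data.frame of in-silico predicted T-RFs per taxon and enzyme.
#' @name scenario-accessors
NULL

#' @rdname scenario-accessors
#' @export
truthAbundances <- function(truth) truth@abundances

#' @rdname scenario-accessors
#' @export
truthGroups <- function(truth) truth@groups

#' @rdname scenario-accessors
#' @export
truthSequences <- function(truth) truth@sequences

#' @rdname scenario-accessors
#' @export
truthTRFs <- function(truth) truth@predictedTRFs

#' Accessors for NMDS results
#'
#' @param x an [NMDSResult-class].
#' @return `nmdsCoordinates`: samples x k coordinate matrix; `nmdsStress`:
#'   Kruskal stress-1 of the returned configuration.
#' @name nmds-accessors
NULL

#' @rdname nmds-accessors
#' @export
nmdsCoordinates <- function(x) x@coordinates

#' @rdname nmds-accessors
#' @export
nmdsStress <- function(x) x@stress

#' Accessors for ANOSIM results
#'
#' @param x an [ANOSIMResult-class].
#' @return `anosimR`: the R statistic; `anosimP`: the permutation p-value;
#'   `anosimPairwise`: data.frame of pairwise tests.
#' @name anosim-accessors
NULL

#' @rdname anosim-accessors
#' @export
anosimR <- function(x) x@R

#' @rdname anosim-accessors
#' @export
anosimP <- function(x) x@pValue

#' @rdname anosim-accessors
#' @export
anosimPairwise <- function(x) x@pairwise
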