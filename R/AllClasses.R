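#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.validDNA <- function(x) nzchar(x) && grepl("^[ACGT]+$", x)
.validIUPAC <- function(x) nzchar(x) && grepl("^[ACGTRYSWKMBDHVN]+$", x)

#' Primer class
#'
#' A PCR primer: a short oligonucleotide over the IUPAC alphabet, optionally
#' carrying a 5' fluorescent label (the labelled primer defines which end of
#' the amplicon yields the detected terminal restriction fragment).
#'
#' @slot name primer name.
#' @slot sequence primer sequence, 5' to 3', IUPAC codes allowed.
#' @slot labeled logical; `TRUE` if the primer carries a 5' fluorophore.
#'
#' @seealso [primerRegistry()] for the built-in primers.
#' @export
setClass("Primer",
  representation(name = "character", sequence = "character",
                 labeled = "logical"),
  prototype(labeled = FALSE)
)

setValidity("Primer", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !.validIUPAC(toupper(object@sequence)))
    msg <- c(msg, "primer sequence must be a non-empty IUPAC DNA string")
  if (length(object@labeled) != 1L || is.na(object@labeled))
    msg <- c(msg, "'labeled' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a Primer
#'
#' @param name primer name.
#' @param sequence 5' to 3' sequence; IUPAC degeneracy codes allowed.
#' @param labeled whether the primer carries a 5' fluorescent label.
#' @return A [Primer-class] object.
#' @examples
#' Primer("799f", "AACMGGATTAGATACCCKG", labeled = TRUE)
#' @export
Primer <- function(name, sequence, labeled = FALSE) {
  new("Primer", name = name, sequence = toupper(sequence), labeled = labeled)
}

#' RestrictionEnzyme class
#'
#' A type II restriction enzyme described by its recognition site (IUPAC
#' codes allowed) and the number of bases of the site retained on the 5'
#' (labelled) fragment after cutting the top strand.
#'
#' @slot name enzyme name.
#' @slot site recognition site on the top strand, IUPAC codes allowed.
#' @slot cutOffset integer in `[0, nchar(site)]`: bases of the site kept on
#'   the 5' fragment. DdeI (C^TNAG) has offset 1, HaeIII (GG^CC) 2,
#'   HhaI (GCG^C) 3.
#'
#' @seealso [enzymeRegistry()] for the built-in enzymes.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutOffset = "integer")
)

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@site) != 1L || !.validIUPAC(toupper(object@site)))
    msg <- c(msg, "recognition site must be a non-empty IUPAC DNA string")
  off <- object@cutOffset
  if (length(off) != 1L || is.na(off) || off < 0L || off > nchar(object@site))
    msg <- c(msg, "cutOffset must lie in [0, nchar(site)]")
  if (length(msg)) msg else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' Non-palindromic recognition sites trigger a warning: sites are scanned on
#' the top strand only, which is complete only when the site equals its own
#' reverse complement under IUPAC degeneracy.
#'
#' @param name enzyme name.
#' @param site recognition sequence, IUPAC codes allowed.
#' @param cutOffset bases of the site retained on the 5' fragment.
#' @return A [RestrictionEnzyme-class] object.
#' @examples
#' RestrictionEnzyme("DdeI", "CTNAG", 1)
#' @export
RestrictionEnzyme <- function(name, site, cutOffset) {
  site <- toupper(site)
  obj <- new("RestrictionEnzyme", name = name, site = site,
             cutOffset = as.integer(cutOffset))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (!identical(site, rc))
    warning("recognition site of ", name, " is not degeneracy-palindromic; ",
            "top-strand scanning may miss bottom-strand sites")
  obj
}

#' TRFCommunity: a binned T-RFLP community matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are T-RF bins and whose
#' columns are samples. The single assay, `"relabund"`, holds relative
#' abundances: every sample (column) sums to 1, or to 0 for a sample in
#' which no peak survived filtering. Row metadata records the bin label
#' (representative size rounded to one decimal), the representative size
#' (mean of member sizes) and the member sizes used for re-binning when
#' replicate runs are merged. The enzyme and the binning gap tolerance are
#' stored in `metadata()`.
#'
#' Note the orientation: the community matrix is conventionally described
#' as samples x T-RFs with rows summing to 1; following the
#' SummarizedExperiment convention the stored assay is its transpose
#' (bins x samples), so columns sum to 1.
#'
#' @seealso [binTRFs()], [mergeReplicates()], [relAbundance()]
#' @export
setClass("TRFCommunity", contains = "SummarizedExperiment")

setValidity("TRFCommunity", function(object) {
  msg <- character()
  if (!"relabund" %in% SummarizedExperiment::assayNames(object))
    return("assay 'relabund' is required")
  a <- SummarizedExperiment::assay(object, "relabund")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    msg <- c(msg, "relative abundances must lie in [0, 1]")
  cs <- colSums(a)
  bad <- abs(cs - 1) > 1e-9 & abs(cs) > 1e-12
  if (any(bad))
    msg <- c(msg, sprintf(
      "sample columns must sum to 1 (or 0 if empty); offending: %s",
      paste(colnames(a)[bad], collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("binLabel", "binSize") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'binLabel' and 'binSize'")
  if (length(msg)) msg else TRUE
})

#' Construct a TRFCommunity
#'
#' @param abundance numeric matrix, bins x samples, columns summing to 1
#'   (or 0 for empty samples).
#' @param binSizes numeric vector of representative bin sizes (bp), one per
#'   row of `abundance`.
#' @param enzyme name of the restriction enzyme the profile derives from.
#' @param gapTolerance single-linkage gap tolerance (bp) used in binning.
#' @param memberSizes optional [IRanges::NumericList] of raw member sizes
#'   per bin (used for joint re-binning when merging replicate runs);
#'   defaults to the representative sizes.
#' @param colData optional `DataFrame` of sample metadata.
#' @return A [TRFCommunity-class] object.
#' @examples
#' m <- cbind(s1 = c(0.6, 0.4), s2 = c(0.3, 0.7))
#' TRFCommunity(m, binSizes = c(64, 506), enzyme = "DdeI")
#' @export
TRFCommunity <- function(abundance, binSizes, enzyme = NA_character_,
                         gapTolerance = 0.5, memberSizes = NULL,
                         colData = NULL) {
  abundance <- as.matrix(abundance)
  if (length(binSizes) != nrow(abundance))
    stop("length(binSizes) must equal nrow(abundance)")
  if (is.null(memberSizes))
    memberSizes <- IRanges::NumericList(as.list(binSizes))
  labels <- sprintf("%.1f", binSizes)
  rd <- S4Vectors::DataFrame(binLabel = labels, binSize = binSizes,
                             memberSizes = memberSizes)
  rownames(abundance) <- labels
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = abundance), rowData = rd, colData = colData)
  out <- new("TRFCommunity", se)
  S4Vectors::metadata(out)$enzyme <- enzyme
  S4Vectors::metadata(out)$gapTolerance <- gapTolerance
  out
}

#' NMDSResult class
#'
#' Result of a non-metric multidimensional scaling run: the best (lowest
#' Kruskal stress-1) configuration over the random starts, centred at the
#' origin and rotated to its principal axes.
#'
#' @slot coordinates samples x k matrix of ordination coordinates.
#' @slot stress Kruskal stress-1 of the returned configuration.
#' @slot disparities monotone-regressed disparities, one per sample pair in
#'   `dist` order.
#' @slot nStarts number of random starts performed.
#' @slot bestStart index of the start that produced the returned solution.
#' @slot seed random seed used.
#' @slot converged `TRUE` if the winning start met the stress-change
#'   tolerance before the iteration cap.
#' @slot startStress final stress of every start.
#' @export
setClass("NMDSResult",
  representation(coordinates = "matrix", stress = "numeric",
                 disparities = "numeric", nStarts = "integer",
                 bestStart = "integer", seed = "integer",
                 converged = "logical", startStress = "numeric")
)

#' ANOSIMResult class
#'
#' Result of an analysis-of-similarities permutation test.
#'
#' @slot R the ANOSIM R statistic, in [-1, 1].
#' @slot pValue permutation p-value in (0, 1].
#' @slot nPermutations number of permutations used (for `method =
#'   "sampled"`) or the number of distinct labelings enumerated (for
#'   `method = "exact"`).
#' @slot method `"sampled"` or `"exact"`.
#' @slot pairwise data.frame of pairwise group tests (groupA, groupB, R, p,
#'   method).
#' @export
setClass("ANOSIMResult",
  representation(R = "numeric", pValue = "numeric",
                 nPermutations = "integer", method = "character",
                 pairwise = "data.frame")
)

#' ScenarioConfig class
#'
#' Parameters of a synthetic T-RFLP study. Defaults emulate a six-genotype
#' seed-endophyte survey with three replicate samples per genotype and
#' duplicate electrophoresis runs.
#'
#' @slot nTaxa number of taxa in the mock community.
#' @slot groups named integer vector: samples per group.
#' @slot effectSize magnitude of the group-specific log-abundance shift
#'   (0 = no group structure).
#' @slot sampleLogSD log-scale SD of replicate-to-replicate compositional
#'   variability within a group.
#' @slot areaCV coefficient of variation of multiplicative peak-area noise.
#' @slot sizeJitterSD SD (bp) of Gaussian fragment-size calling jitter.
#' @slot detectionFloor minimum peak area (fluorescence units) retained.
#' @slot nReplicateRuns duplicate electrophoresis runs per sample.
#' @slot totalSignal total fluorescence area per profile before noise.
#' @slot allowCollisions if `TRUE`, two taxa may share a T-RF (multi-
#'   assignment testing); otherwise T-RFs are >= 2 bp apart within enzyme.
#' @slot seed integer random seed.
#' @export
setClass("ScenarioConfig",
  representation(nTaxa = "integer", groups = "integer",
                 effectSize = "numeric", sampleLogSD = "numeric",
                 areaCV = "numeric", sizeJitterSD = "numeric",
                 detectionFloor = "numeric", nReplicateRuns = "integer",
                 totalSignal = "numeric", allowCollisions = "logical",
                 seed = "integer")
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be >= 1")
  if (length(object@groups) < 1L || any(object@groups < 1L))
    msg <- c(msg, "each group needs at least one sample")
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
    msg <- c(msg, "groups must have unique names")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@sizeJitterSD < 0) msg <- c(msg, "sizeJitterSD must be >= 0")
  if (object@areaCV < 0) msg <- c(msg, "areaCV must be >= 0")
  if (object@nReplicateRuns < 1L) msg <- c(msg, "nReplicateRuns must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioConfig
#'
#' @param nTaxa number of taxa.
#' @param groups named integer vector of samples per group.
#' @param effectSize between-group log-abundance shift magnitude.
#' @param sampleLogSD within-group log-scale sample variability.
#' @param areaCV CV of multiplicative peak-area noise.
#' @param sizeJitterSD SD (bp) of fragment-size jitter.
#' @param detectionFloor minimum retained peak area.
#' @param nReplicateRuns duplicate runs per sample.
#' @param totalSignal total profile fluorescence area.
#' @param allowCollisions allow two taxa to share a T-RF.
#' @param seed integer random seed.
#' @return A [ScenarioConfig-class] object.
#' @examples
#' scenarioConfig(nTaxa = 10, groups = c(A = 3, B = 3), seed = 1)
#' @export
scenarioConfig <- function(nTaxa = 24L,
                           groups = c(IR29 = 3L, FL478 = 3L, IC27 = 3L,
                                      IC31 = 3L, IC32 = 3L, IC37 = 3L),
                           effectSize = 2, sampleLogSD = 0.25,
                           areaCV = 0.2, sizeJitterSD = 0.15,
                           detectionFloor = 50, nReplicateRuns = 2L,
                           totalSignal = 1e4, allowCollisions = FALSE,
                           seed = 1L) {
  g <- as.integer(groups)
  names(g) <- names(groups)
  new("ScenarioConfig", nTaxa = as.integer(nTaxa), groups = g,
      effectSize = effectSize, sampleLogSD = sampleLogSD, areaCV = areaCV,
      sizeJitterSD = sizeJitterSD, detectionFloor = detectionFloor,
      nReplicateRuns = as.integer(nReplicateRuns),
      totalSignal = totalSignal, allowCollisions = allowCollisions,
      seed = as.integer(seed))
}

#' ScenarioTruth class
#'
#' Ground truth of a generated synthetic scenario.
#'
#' @slot sequences `DNAStringSet` of taxon template sequences (each
#'   containing one forward-primer site and one reverse-complemented
#'   reverse-primer site).
#' @slot predictedTRFs data.frame (taxon, enzyme, trf_length, cut_found) of
#'   in-silico predictions for the amplicons.
#' @slot abundances samples x taxa matrix of true relative abundances
#'   (rows sum to 1).
#' @slot groups factor of group membership, one level per group, one entry
#'   per sample (names = sample ids).
#' @slot config the generating [ScenarioConfig-class].
#' @export
setClass("ScenarioTruth",
  representation(sequences = "DNAStringSet", predictedTRFs = "data.frame",
                 abundances = "matrix", groups = "factor",
                 config = "ScenarioConfig")
)
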