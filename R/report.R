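## Presentation-layer exports: abundance-ordered heatmap matrices,
## provenance records, and a one-call pipeline writing the standard
## output bundle.

#' Export a heatmap-ready ordered matrix
#'
#' Orders the bins of a community matrix for heatmap rendering: by
#' decreasing total (summed over samples) abundance, ties broken by
#' ascending bin size — or alphabetically by label. A companion `total`
#' column carries each bin's summed abundance.
#'
#' @param x a [TRFCommunity-class].
#' @param ordering `"total_abundance"` (default) or `"label"`.
#' @param file optional TSV output path.
#' @return data.frame with columns `bin`, `total` and one column per
#'   sample, rows ordered as described.
#' @export
exportHeatmapMatrix <- function(x, ordering = c("total_abundance", "label"),
                                file = NULL) {
  ordering <- match.arg(ordering)
  a <- relAbundance(x)
  if (!nrow(a)) stop("empty community matrix")
  totals <- rowSums(a)
  ord <- switch(ordering,
    total_abundance = order(-totals, binSizes(x)),
    label = order(binLabels(x)))
  out <- data.frame(bin = binLabels(x)[ord], total = totals[ord],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(a[ord, , drop = FALSE],
                                  check.names = FALSE))
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Write a machine-readable provenance record
#'
#' Records everything needed to reproduce a run bit-for-bit: the
#' configuration actually used, the seed, and package/R versions.
#'
#' @param file output path (JSON).
#' @param config named list of run parameters.
#' @param seed integer seed of the run.
#' @return the path, invisibly.
#' @export
writeProvenance <- function(file, config = list(), seed = NA_integer_) {
  payload <- list(
    config = config,
    seed = seed,
    versions = list(
      TRFLPtools = as.character(utils::packageVersion("TRFLPtools")),
      R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Run the full T-RFLP analysis pipeline
#'
#' Filters a (possibly multi-run, single-enzyme) peak table to the sizing
#' range, bins and merges it into a community matrix, and computes
#' diversity indices, the ribotype classification, Bray-Curtis
#' dissimilarities, the NMDS ordination, the ANOSIM test and the UPGMA
#' dendrogram. When `outDir` is given, writes the standard bundle:
#' `matrix.tsv`, `diversity.tsv`, `nmds.tsv`, `anosim.json`,
#' `dendrogram.nwk`, `heatmap.tsv` and `provenance.json`.
#'
#' @param peaks peak data.frame for one enzyme (see [readPeakTable()]).
#' @param grouping named vector mapping samples to groups.
#' @param outDir optional output directory (created if missing).
#' @param gapTolerance binning tolerance (bp).
#' @param minBp,maxBp,organellarMax size filter (see [filterSizeRange()]).
#' @param k,nStarts NMDS dimensions and random starts.
#' @param nPermutations ANOSIM permutations.
#' @param seed integer seed for NMDS starts and ANOSIM permutations.
#' @return (invisibly) a list with elements `community`, `diversity`,
#'   `classification`, `dissimilarity`, `nmds`, `anosim` and `upgma`.
#' @export
runTRFLP <- function(peaks, grouping, outDir = NULL, gapTolerance = 0.5,
                     minBp = 50, maxBp = 500, organellarMax = 800,
                     k = 2L, nStarts = 100L, nPermutations = 999L,
                     seed = 1L) {
  peaks <- .checkPeakTable(peaks)
  peaks <- filterSizeRange(peaks, minBp, maxBp, organellarMax)
  comm <- buildCommunityMatrix(peaks, gapTolerance)
  div <- diversityIndices(comm)
  cls <- classifyTRFs(comm, grouping)
  d <- brayCurtis(comm)
  nmds <- nmdsEmbed(d, k = k, nStarts = nStarts, seed = seed)
  ans <- anosimTest(d, grouping, nPermutations = nPermutations, seed = seed)
  hc <- upgmaCluster(d)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCommunityMatrix(comm, file.path(outDir, "matrix.tsv"))
    divOut <- cbind(sample = rownames(div), div)
    utils::write.table(divOut, file.path(outDir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    coords <- nmdsCoordinates(nmds)
    nmdsOut <- data.frame(sample = rownames(coords), coords,
                          group = as.character(grouping[rownames(coords)]),
                          check.names = FALSE)
    utils::write.table(nmdsOut, file.path(outDir, "nmds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(stress = nmdsStress(nmds), global_R = anosimR(ans),
           p_value = anosimP(ans), method = ans@method,
           pairwise = anosimPairwise(ans)),
      file.path(outDir, "anosim.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    exportNewick(hc, file.path(outDir, "dendrogram.nwk"))
    exportHeatmapMatrix(comm, file = file.path(outDir, "heatmap.tsv"))
    writeProvenance(
      file.path(outDir, "provenance.json"),
      config = list(gapTolerance = gapTolerance, minBp = minBp,
                    maxBp = maxBp, organellarMax = organellarMax, k = k,
                    nStarts = nStarts, nPermutations = nPermutations,
                    grouping = as.list(
                      stats::setNames(as.character(grouping),
                                      names(grouping)))),
      seed = seed)
  }
  invisible(list(community = comm, diversity = div, classification = cls,
                 dissimilarity = d, nmds = nmds, anosim = ans, upgma = hc))
}
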