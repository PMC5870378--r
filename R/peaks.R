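## Electropherogram peak processing: reading sized-peak tables, filtering
## to the reliable sizing range, cross-sample single-linkage binning of
## T-RF sizes, area normalisation and merging of duplicate runs.

.PEAK_COLS <- c("sample", "enzyme", "size", "height", "area")

.checkPeakTable <- function(peaks) {
  missing <- setdiff(.PEAK_COLS, names(peaks))
  if (length(missing))
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"run" %in% names(peaks)) peaks$run <- "run1"
  peaks
}

#' Read an electropherogram peak table
#'
#' Reads a delimited text export of sized fragment-analysis peaks (one row
#' per peak), with header columns `sample`, `enzyme`, `size`, `height`,
#' `area` and optionally `run` (replicate electrophoresis run; defaults to
#' `"run1"`). Comma or tab delimiters are autodetected. Row order is
#' preserved.
#'
#' @param path path to the delimited file.
#' @param sep field delimiter; `NULL` (default) autodetects comma vs tab
#'   from the header line.
#' @return data.frame of peaks with the columns above.
#' @export
readPeakTable <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  raw <- .checkPeakTable(raw)
  for (col in c("size", "height", "area")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at line %d of %s: '%s'",
                   col, bad[1] + 1L, path, raw[[col]][bad[1]]))
    if (anyNA(v))
      stop(sprintf("missing '%s' value at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path))
    raw[[col]] <- v
  }
  if (any(raw$size <= 0)) stop("peak sizes must be positive")
  if (any(raw$area <= 0)) stop("peak areas must be positive")
  raw[, c("sample", "enzyme", "run", "size", "height", "area")]
}

#' Write a peak table to TSV
#'
#' @param peaks data.frame of peaks.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePeakTable <- function(peaks, file) {
  utils::write.table(peaks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Filter peaks to the reliable sizing range
#'
#' Retains peaks whose size lies within the internal size standard's
#' reliable range, and removes large organellar (mitochondrial) amplicon
#' fragments above a length threshold. Defaults: 50-500 bp (a 500-size
#' standard) with an 800 bp organellar ceiling, between the ~730 bp
#' bacterial and ~850 bp mitochondrial amplicons. Bounds are inclusive.
#'
#' @param peaks data.frame of peaks (columns as in [readPeakTable()]).
#' @param minBp,maxBp inclusive size-standard range (bp).
#' @param organellarMax organellar-fragment removal threshold (bp); peaks
#'   above `min(maxBp, organellarMax)` are dropped.
#' @return the filtered peak data.frame (possibly zero rows).
#' @export
filterSizeRange <- function(peaks, minBp = 50, maxBp = 500,
                            organellarMax = 800) {
  stopifnot(minBp < maxBp)
  hi <- min(maxBp, organellarMax)
  peaks[peaks$size >= minBp & peaks$size <= hi, , drop = FALSE]
}

#' Normalise peak areas to relative abundance
#'
#' @param areas numeric vector of peak areas from one profile.
#' @return vector of relative abundances p_i = area_i / sum(areas),
#'   summing to 1.
#' @examples
#' normalizeProfile(c(10, 30, 60))
#' @export
normalizeProfile <- function(areas) {
  if (!length(areas) || any(areas < 0))
    stop("areas must be a non-empty vector of non-negative values")
  tot <- sum(areas)
  if (tot <= 0) stop("cannot normalise a profile with zero total area")
  areas / tot
}

## Single-linkage chaining of sorted sizes: a new bin starts wherever the
## gap to the previous size exceeds the tolerance. Returns bin index per
## input element (in input order).
.chainBins <- function(sizes, gapTolerance) {
  ord <- order(sizes)
  s <- sizes[ord]
  newBin <- c(TRUE, diff(s) > gapTolerance)
  binOfSorted <- cumsum(newBin)
  bins <- integer(length(sizes))
  bins[ord] <- binOfSorted
  bins
}

#' Bin T-RF sizes across samples into a community matrix
#'
#' Pools the peak sizes of all samples (one run per sample), sorts them and
#' chains them into bins by single linkage: a new bin starts wherever the
#' gap to the previous pooled size exceeds `gapTolerance`. Within a sample,
#' areas of peaks falling in the same bin are summed before normalisation.
#' The bin's representative size is the mean of its member sizes; its label
#' is that mean rounded to one decimal.
#'
#' @param peaks data.frame of (already filtered) peaks of a single enzyme
#'   and a single run per sample.
#' @param gapTolerance single-linkage gap tolerance in bp (default 0.5,
#'   absorbing sub-bp sizing drift between runs).
#' @param sampleOrder optional character vector fixing the sample (column)
#'   order; defaults to order of first appearance.
#' @return a [TRFCommunity-class]; samples in which no peak survived have
#'   all-zero columns.
#' @export
binTRFs <- function(peaks, gapTolerance = 0.5, sampleOrder = NULL) {
  stopifnot(gapTolerance >= 0)
  peaks <- .checkPeakTable(peaks)
  enz <- unique(peaks$enzyme)
  if (length(enz) > 1L)
    stop("binTRFs requires a single enzyme; got: ",
         paste(enz, collapse = ", "))
  runsPerSample <- tapply(peaks$run, peaks$sample,
                          function(r) length(unique(r)))
  if (any(runsPerSample > 1L))
    stop("multiple runs per sample; bin each run separately and use ",
         "mergeReplicates()")
  if (is.null(sampleOrder)) sampleOrder <- unique(peaks$sample)
  if (!nrow(peaks)) {
    abund <- matrix(0, nrow = 0, ncol = length(sampleOrder),
                    dimnames = list(NULL, sampleOrder))
    return(TRFCommunity(abund, binSizes = numeric(),
                        enzyme = NA_character_,
                        gapTolerance = gapTolerance))
  }

  bins <- .chainBins(peaks$size, gapTolerance)
  nBins <- max(bins)
  repSize <- vapply(seq_len(nBins),
                    function(b) mean(peaks$size[bins == b]), numeric(1))
  members <- IRanges::NumericList(
    lapply(seq_len(nBins), function(b) peaks$size[bins == b]))

  abund <- matrix(0, nrow = nBins, ncol = length(sampleOrder),
                  dimnames = list(NULL, sampleOrder))
  for (s in sampleOrder) {
    sel <- peaks$sample == s
    if (!any(sel)) next
    sums <- tapply(peaks$area[sel], bins[sel], sum)
    abund[as.integer(names(sums)), s] <- sums
    abund[, s] <- abund[, s] / sum(abund[, s])
  }
  TRFCommunity(abund, binSizes = repSize,
               enzyme = if (length(enz)) enz else NA_character_,
               gapTolerance = gapTolerance, memberSizes = members)
}

#' Merge duplicate-run community matrices
#'
#' Re-bins the member sizes of all runs jointly (single linkage at the gap
#' tolerance, so the merged bin set is the union of run bins) and averages
#' the relative abundances of each sample across runs, counting a bin
#' absent from a run as 0. Columns are renormalised to 1, which matters
#' only when a sample is empty in some runs.
#'
#' @param matrices list of [TRFCommunity-class] objects for the same
#'   samples and enzyme, one per replicate run.
#' @param how `"mean"` (default) averages run abundances; `"presence"`
#'   keeps the union of presences with equal weight on each detected
#'   run-bin abundance (both renormalised).
#' @return a merged [TRFCommunity-class].
#' @export
mergeReplicates <- function(matrices, how = c("mean", "presence")) {
  how <- match.arg(how)
  stopifnot(length(matrices) >= 1L)
  if (length(matrices) == 1L) return(matrices[[1L]])
  samples <- colnames(matrices[[1L]])
  enz <- enzymeName(matrices[[1L]])
  tol <- gapTolerance(matrices[[1L]])
  for (m in matrices[-1L]) {
    if (!setequal(colnames(m), samples))
      stop("replicate matrices cover different sample sets")
    if (!identical(enzymeName(m), enz))
      stop("replicate matrices derive from different enzymes")
  }

  ## pool every member size, tagged by (run, bin)
  sizes <- numeric(); runIdx <- integer(); binIdx <- integer()
  for (i in seq_along(matrices)) {
    ms <- SummarizedExperiment::rowData(matrices[[i]])$memberSizes
    for (b in seq_along(ms)) {
      v <- ms[[b]]
      sizes <- c(sizes, v)
      runIdx <- c(runIdx, rep(i, length(v)))
      binIdx <- c(binIdx, rep(b, length(v)))
    }
  }
  merged <- .chainBins(sizes, tol)
  nBins <- max(merged)
  repSize <- vapply(seq_len(nBins),
                    function(b) mean(sizes[merged == b]), numeric(1))
  members <- IRanges::NumericList(
    lapply(seq_len(nBins), function(b) sizes[merged == b]))

  ## every original bin falls entirely inside one merged bin (single
  ## linkage only coarsens); map (run, bin) -> merged bin
  mapTo <- lapply(seq_along(matrices), function(i) {
    nb <- nrow(matrices[[i]])
    vapply(seq_len(nb),
           function(b) unique(merged[runIdx == i & binIdx == b])[1],
           numeric(1))
  })

  abund <- matrix(0, nrow = nBins, ncol = length(samples),
                  dimnames = list(NULL, samples))
  detected <- matrix(0, nrow = nBins, ncol = length(samples))
  for (i in seq_along(matrices)) {
    a <- relAbundance(matrices[[i]])[, samples, drop = FALSE]
    proj <- matrix(0, nrow = nBins, ncol = length(samples))
    for (b in seq_len(nrow(a)))
      proj[mapTo[[i]][b], ] <- proj[mapTo[[i]][b], ] + a[b, ]
    abund <- abund + proj
    detected <- detected + (proj > 0)
  }
  if (how == "mean") {
    abund <- abund / length(matrices)
  } else {
    ## presence mode: average only over the runs that detected the bin, so
    ## a bin seen in one of two runs keeps its full single-run weight
    abund <- abund / pmax(detected, 1)
  }
  cs <- colSums(abund)
  nz <- cs > 0
  abund[, nz] <- sweep(abund[, nz, drop = FALSE], 2, cs[nz], "/")

  TRFCommunity(abund, binSizes = repSize, enzyme = enz,
               gapTolerance = tol, memberSizes = members)
}

#' Build a merged community matrix from a multi-run peak table
#'
#' Convenience wrapper: filters the table (optionally), splits it by run,
#' bins each run with [binTRFs()] and merges the runs with
#' [mergeReplicates()].
#'
#' @param peaks peak data.frame for a single enzyme (any number of runs).
#' @param gapTolerance single-linkage binning tolerance (bp).
#' @param minAbundance optional relative-abundance floor applied after
#'   merging (bins below it are zeroed and columns renormalised); `NULL`
#'   (default) applies no floor.
#' @return a [TRFCommunity-class].
#' @export
buildCommunityMatrix <- function(peaks, gapTolerance = 0.5,
                                 minAbundance = NULL) {
  peaks <- .checkPeakTable(peaks)
  samples <- unique(peaks$sample)
  runs <- unique(peaks$run)
  mats <- lapply(runs, function(r) {
    binTRFs(peaks[peaks$run == r, , drop = FALSE], gapTolerance,
            sampleOrder = samples)
  })
  out <- mergeReplicates(mats)
  if (!is.null(minAbundance)) {
    a <- relAbundance(out)
    a[a < minAbundance] <- 0
    keep <- rowSums(a) > 0
    a <- a[keep, , drop = FALSE]
    cs <- colSums(a)
    nz <- cs > 0
    a[, nz] <- sweep(a[, nz, drop = FALSE], 2, cs[nz], "/")
    rd <- SummarizedExperiment::rowData(out)[keep, ]
    out <- TRFCommunity(a, binSizes = rd$binSize, enzyme = enzymeName(out),
                        gapTolerance = gapTolerance,
                        memberSizes = rd$memberSizes)
  }
  out
}

#' Write a community matrix to TSV
#'
#' First column `bin` (the bin label), remaining columns one per sample;
#' a `#` comment header records the enzyme and gap tolerance so the file
#' round-trips through [readCommunityMatrix()]. Abundances are printed
#' with 17 significant digits, which round-trips doubles exactly.
#'
#' @param x a [TRFCommunity-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCommunityMatrix <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# enzyme=%s gap_tolerance=%.17g", enzymeName(x),
                     gapTolerance(x)), con)
  a <- relAbundance(x)
  writeLines(paste(c("bin", colnames(a)), collapse = "\t"), con)
  for (i in seq_len(nrow(a)))
    writeLines(paste(c(binLabels(x)[i], sprintf("%.17g", a[i, ])),
                     collapse = "\t"), con)
  invisible(file)
}

#' Read a community matrix written by [writeCommunityMatrix()]
#'
#' @param file path to the TSV.
#' @return a [TRFCommunity-class] (member sizes reduce to the bin labels).
#' @export
readCommunityMatrix <- function(file) {
  lines <- readLines(file)
  enz <- NA_character_; tol <- 0.5
  if (startsWith(lines[1], "#")) {
    enz <- sub(".*enzyme=([^ ]+).*", "\\1", lines[1])
    tol <- as.numeric(sub(".*gap_tolerance=([^ ]+).*", "\\1", lines[1]))
    lines <- lines[-1]
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           check.names = FALSE)
  sizes <- as.numeric(tab$bin)
  a <- as.matrix(tab[, -1, drop = FALSE])
  TRFCommunity(a, binSizes = sizes, enzyme = enz, gapTolerance = tol)
}
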