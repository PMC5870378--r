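## Synthetic T-RFLP scenarios with known ground truth: taxon templates with
## planted primer and restriction sites, group-structured abundance
## profiles, and noisy replicate peak tables.

.BASES <- c("A", "C", "G", "T")

.randomDNA <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

## one concrete expansion of a degenerate IUPAC string
.concreteInstance <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- .IUPAC_SETS[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.rcString <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## mutate unintended enzyme-site occurrences in a sequence, leaving the
## intervals in 'protect' (1-based start/end matrix) untouched
.scrubSites <- function(seq, enzymes, protect) {
  inProtected <- function(pos) {
    any(pos >= protect[, 1] & pos <= protect[, 2])
  }
  for (round in seq_len(200)) {
    dirty <- FALSE
    subj <- Biostrings::DNAString(seq)
    for (ez in enzymes) {
      starts <- .matchStarts(ez@site, subj)
      siteLen <- nchar(ez@site)
      for (s in starts) {
        if (any(protect[, 1] == s & protect[, 2] == s + siteLen - 1L))
          next  # a planted site
        cand <- Filter(Negate(inProtected), seq(s, s + siteLen - 1L))
        if (!length(cand))
          stop("cannot scrub a spurious site inside protected regions")
        pos <- cand[[1]]
        patCh <- substr(ez@site, pos - s + 1L, pos - s + 1L)
        bad <- union(.IUPAC_SETS[[patCh]], substr(seq, pos, pos))
        repl <- sample(setdiff(.BASES, bad), 1L)
        substr(seq, pos, pos) <- repl
        dirty <- TRUE
        break
      }
      if (dirty) break
    }
    if (!dirty) return(seq)
  }
  stop("site scrubbing did not converge")
}

## build nTaxa templates with planted, verified T-RFs
.makeTaxa <- function(config, enzymes = enzymeRegistry(),
                      forward = primerRegistry()$`799f`,
                      reverse = primerRegistry()$`1492R`) {
  nTaxa <- config@nTaxa
  ezNames <- names(enzymes)
  grid <- seq(60L, 600L, by = 2L)  # >= 2 bp apart by construction
  if (nTaxa > length(grid))
    stop("cannot give ", nTaxa, " taxa T-RFs separated by 2 bp")

  trf <- matrix(0L, nTaxa, length(enzymes),
                dimnames = list(NULL, ezNames))
  for (e in ezNames) {
    vals <- sample(grid, nTaxa)
    if (config@allowCollisions && nTaxa >= 2L) {
      ## let two taxa share a fragment to exercise multi-assignment
      vals[2L] <- vals[1L]
    }
    trf[, e] <- vals
  }
  ## within a taxon the planted site intervals must not overlap
  offsets <- vapply(enzymes, function(ez) ez@cutOffset, integer(1))
  siteLens <- vapply(enzymes, function(ez) nchar(ez@site), integer(1))
  for (t in seq_len(nTaxa)) {
    for (tries in seq_len(500)) {
      starts <- trf[t, ] - offsets  # 0-based site starts on the amplicon
      ok <- TRUE
      comb <- utils::combn(length(starts), 2)
      for (j in seq_len(ncol(comb))) {
        a <- comb[1, j]; b <- comb[2, j]
        if (starts[a] < starts[b] + siteLens[b] + 2 &&
            starts[b] < starts[a] + siteLens[a] + 2) { ok <- FALSE; break }
      }
      if (ok) break
      e <- ezNames[sample(length(ezNames), 1L)]
      free <- setdiff(grid, trf[, e])
      trf[t, e] <- sample(free, 1L)
    }
  }

  fLen <- nchar(forward@sequence)
  rLen <- nchar(reverse@sequence)
  taxa <- paste0("taxon", sprintf("%02d", seq_len(nTaxa)))
  seqs <- character(nTaxa)
  for (t in seq_len(nTaxa)) {
    insertLen <- sample(650:750, 1L)
    ampLen <- fLen + insertLen + rLen
    fwd <- .concreteInstance(forward@sequence)
    amp <- paste0(fwd, .randomDNA(insertLen), .rcString(reverse@sequence))
    protect <- rbind(c(1L, fLen), c(ampLen - rLen + 1L, ampLen))
    for (e in ezNames) {
      site <- .concreteInstance(enzymes[[e]]@site)
      s0 <- trf[t, e] - offsets[[e]]          # 0-based
      substr(amp, s0 + 1L, s0 + siteLens[[e]]) <- site
      protect <- rbind(protect, c(s0 + 1L, s0 + siteLens[[e]]))
    }
    amp <- .scrubSites(amp, enzymes, protect)
    seqs[t] <- paste0(.randomDNA(30L), amp, .randomDNA(10L))
  }
  templates <- Biostrings::DNAStringSet(seqs)
  names(templates) <- taxa

  pred <- predictionTable(templates, enzymes, forward, reverse)
  expected <- data.frame(
    source_id = rep(taxa, each = length(ezNames)),
    enzyme = rep(ezNames, nTaxa),
    trf_length = as.integer(t(trf)), stringsAsFactors = FALSE)
  key <- paste(pred$source_id, pred$enzyme)
  got <- pred$trf_length[match(paste(expected$source_id, expected$enzyme),
                               key)]
  if (!identical(as.integer(got), expected$trf_length))
    stop("internal error: planted T-RFs not recovered by in-silico digest")

  list(templates = templates, predictedTRFs = pred, trfMatrix = trf)
}

#' Generate the fixed taxon set of a synthetic scenario
#'
#' Builds the taxon templates once (random 16S-like sequences flanking a
#' 650-750 bp insert between a concrete 799f instance and the reverse
#' complement of 1492R, with one planted recognition site per enzyme at a
#' distinct offset) so that repeated abundance simulations can reuse them.
#'
#' @param config a [ScenarioConfig-class]; only `nTaxa`, `allowCollisions`
#'   and `seed` are consulted.
#' @return list with `templates` (`DNAStringSet`), `predictedTRFs`
#'   (data.frame) and `trfMatrix` (taxa x enzymes planted T-RF sizes).
#' @export
scenarioTaxa <- function(config) {
  .withSeed(config@seed, .makeTaxa(config))
}

#' Generate a synthetic scenario with known ground truth
#'
#' Draws a log-normal base abundance profile over the taxa, applies a
#' group-specific log-abundance shift of magnitude `effectSize` to a random
#' half of the taxa per group (sign random; with `effectSize = 0` all
#' groups share the base profile), adds per-sample log-normal variability
#' (`sampleLogSD`) and renormalises. Deterministic under the config seed.
#'
#' @param config a [ScenarioConfig-class].
#' @param taxa optional pre-built taxon set from [scenarioTaxa()] (with a
#'   config of the same `nTaxa`); built from scratch otherwise.
#' @return a [ScenarioTruth-class].
#' @export
generateScenario <- function(config, taxa = NULL) {
  validObject(config)
  .withSeed(config@seed, .generateScenarioImpl(config, taxa))
}

.generateScenarioImpl <- function(config, taxa = NULL) {
  if (is.null(taxa)) taxa <- .makeTaxa(config)
  if (length(taxa$templates) != config@nTaxa)
    stop("supplied taxa do not match config@nTaxa")

  nTaxa <- config@nTaxa
  baseLog <- stats::rnorm(nTaxa, 0, 1)
  groups <- config@groups
  shift <- matrix(0, nrow = length(groups), ncol = nTaxa,
                  dimnames = list(names(groups), NULL))
  for (g in seq_along(groups)) {
    affected <- stats::rbinom(nTaxa, 1L, 0.5) == 1L
    sgn <- sample(c(-1, 1), nTaxa, replace = TRUE)
    shift[g, ] <- config@effectSize * sgn * affected
  }

  sampleIds <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]]))))
  groupOf <- factor(rep(names(groups), groups), levels = names(groups))
  names(groupOf) <- sampleIds

  abund <- matrix(0, nrow = length(sampleIds), ncol = nTaxa,
                  dimnames = list(sampleIds, names(taxa$templates)))
  for (i in seq_along(sampleIds)) {
    lg <- baseLog + shift[as.character(groupOf[i]), ] +
      stats::rnorm(nTaxa, 0, config@sampleLogSD)
    w <- exp(lg)
    abund[i, ] <- w / sum(w)
  }

  new("ScenarioTruth", sequences = taxa$templates,
      predictedTRFs = taxa$predictedTRFs, abundances = abund,
      groups = groupOf, config = config)
}

#' Simulate electropherogram peak tables from a scenario
#'
#' For every enzyme, sample and replicate run: peak area =
#' `totalSignal * true abundance * LogNormal(mean 1, cv = areaCV)`, peak
#' size = predicted T-RF + `Normal(0, sizeJitterSD)`, and peaks with area
#' below `detectionFloor` are dropped. Deterministic under `seed`.
#'
#' @param truth a [ScenarioTruth-class].
#' @param seed integer seed for the measurement noise; defaults to the
#'   scenario seed + 1 so generation and measurement use distinct streams.
#' @return a peak data.frame in the [readPeakTable()] dialect (columns
#'   sample, enzyme, run, size, height, area).
#' @export
simulatePeakTables <- function(truth, seed = truth@config@seed + 1L) {
  .withSeed(seed, .simulatePeakTablesImpl(truth))
}

.simulatePeakTablesImpl <- function(truth) {
  config <- truth@config
  sdlog <- sqrt(log(1 + config@areaCV^2))
  meanlog <- -sdlog^2 / 2   # multiplicative noise with mean exactly 1
  pred <- truth@predictedTRFs
  enzymes <- unique(pred$enzyme)
  samples <- rownames(truth@abundances)
  taxa <- colnames(truth@abundances)

  rows <- vector("list", length(enzymes) * length(samples) *
                   config@nReplicateRuns)
  k <- 0L
  for (ez in enzymes) {
    trfOf <- pred$trf_length[pred$enzyme == ez][
      match(taxa, pred$source_id[pred$enzyme == ez])]
    for (s in samples) {
      p <- truth@abundances[s, ]
      for (r in seq_len(config@nReplicateRuns)) {
        noise <- if (sdlog > 0)
          stats::rlnorm(length(p), meanlog, sdlog) else rep(1, length(p))
        area <- config@totalSignal * p * noise
        size <- trfOf + if (config@sizeJitterSD > 0)
          stats::rnorm(length(p), 0, config@sizeJitterSD) else 0
        keep <- area >= config@detectionFloor & area > 0
        if (!any(keep)) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample = s, enzyme = ez, run = paste0("run", r),
          size = size[keep], height = area[keep] / 2, area = area[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Write scenario templates to FASTA
#'
#' @param truth a [ScenarioTruth-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeScenarioFASTA <- function(truth, file) {
  Biostrings::writeXStringSet(truth@sequences, file)
  invisible(file)
}

#' Write a scenario ground-truth sidecar (JSON)
#'
#' Records the config, group memberships, true abundance vectors and
#' predicted T-RFs so simulated data remain fully reproducible.
#'
#' @param truth a [ScenarioTruth-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, file) {
  cfg <- truth@config
  payload <- list(
    config = list(
      nTaxa = cfg@nTaxa, groups = as.list(cfg@groups),
      effectSize = cfg@effectSize, sampleLogSD = cfg@sampleLogSD,
      areaCV = cfg@areaCV, sizeJitterSD = cfg@sizeJitterSD,
      detectionFloor = cfg@detectionFloor,
      nReplicateRuns = cfg@nReplicateRuns,
      totalSignal = cfg@totalSignal,
      allowCollisions = cfg@allowCollisions, seed = cfg@seed),
    groups = stats::setNames(as.character(truth@groups),
                             names(truth@groups)),
    abundances = apply(truth@abundances, 1, as.list),
    predicted_trfs = truth@predictedTRFs)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
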