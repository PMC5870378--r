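## In-silico PCR and restriction digestion: predicting labelled terminal
## restriction fragment (T-RF) sizes and full ARDRA fingerprints from
## template sequences, and linking observed T-RF bins back to taxa.

.asDNAString <- function(x, what = "sequence") {
  if (is(x, "DNAString")) return(x)
  x <- toupper(as.character(x))
  if (length(x) != 1L || !nzchar(x))
    stop(what, " must be a single non-empty DNA string")
  Biostrings::DNAString(x)
}

.checkTemplate <- function(x) {
  s <- toupper(as.character(x))
  if (!.validDNA(s))
    stop("template must be non-empty and contain only A/C/G/T ",
         "(ambiguity codes are rejected in templates)")
  s
}

## 1-based start positions of degeneracy-aware exact matches of an IUPAC
## pattern on the top strand of an A/C/G/T subject.
.matchStarts <- function(pattern, subject) {
  if (nchar(pattern) > length(subject)) return(integer())
  m <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
  Biostrings::start(m)
}

#' In-silico PCR with degenerate primers
#'
#' Locates amplicons on a template: a top-strand match of the forward
#' primer paired with the nearest downstream match of the
#' reverse-complemented reverse primer. Matching is exact under IUPAC
#' degeneracy (a degenerate code matches any base in its set; no mismatches
#' are tolerated). Every forward match is paired with its nearest
#' non-overlapping downstream reverse site, so overlapping amplicons from
#' repeated forward sites are all reported.
#'
#' @param template a single DNA string (or `DNAString`) over A/C/G/T, a
#'   named character vector, or a `DNAStringSet`; ambiguity codes in
#'   templates are rejected.
#' @param forward,reverse [Primer-class] objects (or IUPAC strings).
#' @return data.frame with one row per amplicon: `source_id`, `start`
#'   (0-based inclusive position of the forward primer's 5' base), `end`
#'   (0-based exclusive, one past the reverse primer's 5' base), `length`
#'   (bp) and `sequence` (top strand). Zero rows when nothing amplifies.
#' @examples
#' p <- primerRegistry()
#' tpl <- paste0("AACAGGATTAGATACCCGG", "TTTT", "AAGTCGTAACAAGGTAACC")
#' inSilicoPCR(tpl, p$`799f`, p$`1492R`)
#' @export
inSilicoPCR <- function(template, forward, reverse) {
  if (is(forward, "Primer")) forward <- forward@sequence
  if (is(reverse, "Primer")) reverse <- reverse@sequence
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!.validIUPAC(forward) || !.validIUPAC(reverse))
    stop("primers must be non-empty IUPAC DNA strings")

  if (is(template, "DNAStringSet") ||
      (is.character(template) && length(template) > 1L)) {
    ids <- names(template)
    if (is.null(ids)) ids <- paste0("seq", seq_along(template))
    res <- lapply(seq_along(template), function(i) {
      out <- inSilicoPCR(as.character(template[[i]]), forward, reverse)
      if (nrow(out)) out$source_id <- ids[i]
      out
    })
    return(do.call(rbind, res))
  }

  id <- names(template)
  if (is.null(id)) id <- "template"
  seq <- .checkTemplate(template)
  subj <- Biostrings::DNAString(seq)
  rcRev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)))

  fStarts <- .matchStarts(forward, subj)
  rStarts <- .matchStarts(rcRev, subj)
  nF <- nchar(forward); nR <- nchar(reverse)

  rows <- lapply(fStarts, function(f) {
    cand <- rStarts[rStarts >= f + nF]
    if (!length(cand)) return(NULL)
    r <- min(cand)
    end1 <- r + nR - 1L                      # 1-based inclusive end
    data.frame(source_id = id, start = f - 1L, end = end1,
               length = end1 - (f - 1L),
               sequence = substr(seq, f, end1),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(source_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

## 0-based cut positions of an enzyme on a top strand, non-overlapping
## occurrences taken left to right; cuts at position 0 or L are not cuts.
.cutPositions <- function(seq, enzyme) {
  subj <- .asDNAString(seq, "amplicon")
  starts <- .matchStarts(enzyme@site, subj)
  if (!length(starts)) return(integer())
  siteLen <- nchar(enzyme@site)
  keep <- integer()
  last <- -siteLen
  for (s in starts) {
    if (s >= last + siteLen) { keep <- c(keep, s); last <- s }
  }
  cuts <- keep - 1L + enzyme@cutOffset
  cuts[cuts > 0L & cuts < length(subj)]
}

#' Predict the labelled terminal restriction fragment of an amplicon
#'
#' Scans the labelled strand 5' to 3' for the first occurrence of the
#' enzyme's recognition site (degeneracy-aware). The T-RF length is the
#' 0-based index of that occurrence plus the enzyme's cut offset, i.e. the
#' labelled 5' base counts as position 1 of the fragment. When the site
#' never occurs the whole amplicon is the labelled fragment.
#'
#' @param amplicon amplicon sequence (character or `DNAString`), top
#'   strand, forward primer first.
#' @param enzyme a [RestrictionEnzyme-class].
#' @param labeledEnd `"forward"` if the forward primer carries the
#'   fluorophore (the amplicon is scanned as given) or `"reverse"` (the
#'   amplicon is reverse-complemented before scanning).
#' @return list with `trf_length` (integer bp) and `cut_found` (logical;
#'   `FALSE` means `trf_length` equals the amplicon length).
#' @examples
#' predictTRF("GGCCATTTT", enzymeRegistry()$HaeIII)  # site at origin: 2 bp
#' @export
predictTRF <- function(amplicon, enzyme,
                       labeledEnd = c("forward", "reverse")) {
  labeledEnd <- match.arg(labeledEnd)
  subj <- .asDNAString(amplicon, "amplicon")
  if (labeledEnd == "reverse") subj <- Biostrings::reverseComplement(subj)
  cuts <- .cutPositions(subj, enzyme)
  if (!length(cuts))
    list(trf_length = length(subj), cut_found = FALSE)
  else
    list(trf_length = as.integer(cuts[1]), cut_found = TRUE)
}

#' Full restriction fingerprint (ARDRA pattern) of an amplicon
#'
#' Cuts the amplicon at every non-overlapping occurrence of the enzyme's
#' site, taken left to right on the top strand; each cut falls
#' `cutOffset` bases into the site. The fragments partition the amplicon.
#'
#' @inheritParams predictTRF
#' @return integer vector of fragment lengths, sorted decreasing; sums to
#'   the amplicon length.
#' @examples
#' ardraPattern("GGCCATTTT", enzymeRegistry()$HaeIII)  # 7, 2
#' @export
ardraPattern <- function(amplicon, enzyme) {
  subj <- .asDNAString(amplicon, "amplicon")
  cuts <- .cutPositions(subj, enzyme)
  frags <- diff(c(0L, cuts, length(subj)))
  sort(as.integer(frags), decreasing = TRUE)
}

#' Compare two ARDRA patterns within a size tolerance
#'
#' Clones are conventionally grouped by restriction pattern; two patterns
#' are equivalent when they have the same number of fragments and every
#' size-ordered fragment pair differs by at most `tolerance` bp.
#'
#' @param a,b integer fragment-length vectors (any order).
#' @param tolerance maximum per-fragment size difference (bp).
#' @return logical.
#' @export
ardraEquivalent <- function(a, b, tolerance = 1) {
  if (length(a) != length(b)) return(FALSE)
  all(abs(sort(a) - sort(b)) <= tolerance)
}

#' Assign taxon identities to an observed T-RF bin
#'
#' Links an observed (binned) T-RF size to the taxa whose in-silico
#' predicted T-RF falls within a tolerance, preserving multi-assignment
#' when several taxa share a fragment size.
#'
#' @param binSize observed bin size (bp).
#' @param predictions data.frame with columns `taxon` and `trf_length`
#'   (e.g. from [predictionTable()]).
#' @param tolerance maximum |predicted - observed| in bp (default 1.0).
#' @return character vector of taxa sorted by |difference| then
#'   alphabetically; empty when the bin is unidentified.
#' @examples
#' preds <- data.frame(taxon = c("Curtobacterium", "Delftia"),
#'                     trf_length = c(506, 64))
#' assignIdentity(506.0, preds)
#' @export
assignIdentity <- function(binSize, predictions, tolerance = 1.0) {
  stopifnot(tolerance >= 0)
  d <- abs(predictions$trf_length - binSize)
  hit <- which(d <= tolerance)
  if (!length(hit)) return(character())
  hit <- hit[order(d[hit], predictions$taxon[hit])]
  unique(as.character(predictions$taxon[hit]))
}

#' Read template sequences from FASTA
#'
#' Multi-record, wrapped-line, case-insensitive FASTA reader for template
#' 16S sequences. Records containing ambiguity codes are rejected, since
#' in-silico digestion of a degenerate template is ill-defined.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readTemplates <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  bad <- !vapply(seqs, .validDNA, logical(1))
  if (any(bad))
    stop("templates contain non-A/C/G/T characters: ",
         paste(names(x)[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Predicted T-RF table for a set of templates
#'
#' Runs [inSilicoPCR()] on every template and [predictTRF()] on the first
#' amplicon of each template for every enzyme, producing the table used to
#' identify observed T-RF bins.
#'
#' @param templates `DNAStringSet` or named character vector of templates.
#' @param enzymes named list of [RestrictionEnzyme-class] (default the
#'   built-in registry).
#' @param forward,reverse primers (defaults: labelled 799f and 1492R).
#' @param taxa optional character vector of taxon labels parallel to
#'   `templates`; defaults to the template names.
#' @param labeledEnd which primer carries the label (see [predictTRF()]).
#' @return data.frame with columns `source_id`, `taxon`, `enzyme`,
#'   `trf_length`, `cut_found`; templates that yield no amplicon are
#'   omitted.
#' @export
predictionTable <- function(templates, enzymes = enzymeRegistry(),
                            forward = primerRegistry()$`799f`,
                            reverse = primerRegistry()$`1492R`,
                            taxa = NULL, labeledEnd = "forward") {
  if (is.character(templates))
    templates <- Biostrings::DNAStringSet(toupper(templates))
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("seq", seq_along(templates))
  if (is.null(taxa)) taxa <- ids
  rows <- list()
  for (i in seq_along(templates)) {
    amp <- inSilicoPCR(as.character(templates[[i]]), forward, reverse)
    if (!nrow(amp)) next
    for (ez in enzymes) {
      pred <- predictTRF(amp$sequence[1], ez, labeledEnd)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = ids[i], taxon = taxa[i], enzyme = ez@name,
        trf_length = pred$trf_length, cut_found = pred$cut_found,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(source_id = character(), taxon = character(),
                      enzyme = character(), trf_length = integer(),
                      cut_found = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a predicted T-RF table to TSV
#'
#' @param predictions data.frame from [predictionTable()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePredictionTable <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
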