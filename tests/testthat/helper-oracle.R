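# Independent brute-force oracles and small fixture builders. The oracle
# expands every IUPAC degeneracy combination to literal strings and scans
# with fixed-string matching, so it shares no code with the package's
# matching path.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

rcOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

expandDegenerate <- function(pattern) {
  sets <- IUPAC[strsplit(pattern, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste,
        collapse = "")
}

# all 1-based match starts of a degenerate pattern, by exhaustive expansion
# and fixed-string scanning (overlaps included)
bruteStarts <- function(pattern, subject) {
  hits <- integer()
  for (lit in expandDegenerate(pattern)) {
    m <- gregexpr(lit, subject, fixed = TRUE)[[1]]
    if (m[1] != -1) hits <- c(hits, as.integer(m))
  }
  sort(unique(hits))
}

# brute-force in-silico PCR: forward starts paired to the nearest
# downstream reverse-complemented-reverse starts
brutePCR <- function(template, fwd, rev) {
  fS <- bruteStarts(fwd, template)
  rS <- bruteStarts(rcOracle(rev), template)
  nF <- nchar(fwd); nR <- nchar(rev)
  out <- NULL
  for (f in fS) {
    cand <- rS[rS >= f + nF]
    if (!length(cand)) next
    r <- min(cand)
    out <- rbind(out, data.frame(start = f - 1L, end = r + nR - 1L,
                                 length = r + nR - 1L - (f - 1L)))
  }
  if (is.null(out))
    data.frame(start = integer(), end = integer(), length = integer())
  else out[order(out$start), , drop = FALSE]
}

# brute-force terminal fragment: first degenerate site hit, position-by-
# position scan, plus cut offset
bruteTRF <- function(amplicon, site, offset) {
  L <- nchar(amplicon)
  sets <- IUPAC[strsplit(site, "")[[1]]]
  for (s in seq_len(L - nchar(site) + 1L)) {
    chars <- strsplit(substr(amplicon, s, s + nchar(site) - 1L), "")[[1]]
    if (all(mapply(function(ch, set) ch %in% set, chars, sets))) {
      cut <- s - 1L + offset
      if (cut > 0L && cut < L) return(list(trf = cut, found = TRUE))
    }
  }
  list(trf = L, found = FALSE)
}

# as bruteDigest but keeping left-to-right fragment order
bruteDigestOrdered <- function(amplicon, site, offset) {
  L <- nchar(amplicon)
  sets <- IUPAC[strsplit(site, "")[[1]]]
  k <- nchar(site)
  cuts <- integer()
  s <- 1L
  while (s <= L - k + 1L) {
    chars <- strsplit(substr(amplicon, s, s + k - 1L), "")[[1]]
    if (all(mapply(function(ch, set) ch %in% set, chars, sets))) {
      cut <- s - 1L + offset
      if (cut > 0L && cut < L) cuts <- c(cuts, cut)
      s <- s + k
    } else s <- s + 1L
  }
  diff(c(0L, cuts, L))
}

# brute-force full digest (non-overlapping occurrences, left to right)
bruteDigest <- function(amplicon, site, offset) {
  L <- nchar(amplicon)
  sets <- IUPAC[strsplit(site, "")[[1]]]
  k <- nchar(site)
  cuts <- integer()
  s <- 1L
  while (s <= L - k + 1L) {
    chars <- strsplit(substr(amplicon, s, s + k - 1L), "")[[1]]
    if (all(mapply(function(ch, set) ch %in% set, chars, sets))) {
      cut <- s - 1L + offset
      if (cut > 0L && cut < L) cuts <- c(cuts, cut)
      s <- s + k
    } else s <- s + 1L
  }
  sort(diff(c(0L, cuts, L)), decreasing = TRUE)
}

randomDNAString <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                            replace = TRUE), collapse = "")

# a tiny community matrix built directly from an abundance matrix
makeCommunity <- function(abund, sizes, enzyme = "DdeI") {
  TRFCommunity(abund, binSizes = sizes, enzyme = enzyme)
}

# peak-table rows in the standard dialect
peakRows <- function(sample, size, area, enzyme = "DdeI", run = "run1") {
  data.frame(sample = sample, enzyme = enzyme, run = run, size = size,
             height = area / 2, area = area, stringsAsFactors = FALSE)
}
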