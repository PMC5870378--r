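#' Built-in primer registry
#'
#' The degenerate eubacterial forward primer 27F-Degen, the
#' chloroplast-avoiding (and 5'-6FAM-labelled) nested forward primer 799f,
#' and the universal reverse primer 1492R. 799f/1492R is the pair whose
#' labelled amplicons are digested and sized in a standard 16S T-RFLP
#' workflow; the labelled primer defines the detected terminal fragment.
#'
#' @return named list of [Primer-class] objects.
#' @examples
#' primerRegistry()$`799f`
#' @export
primerRegistry <- function() {
  list(
    `27F-Degen` = Primer("27F-Degen", "AGRRTTYGATYMTGGYTYAG"),
    `799f`      = Primer("799f", "AACMGGATTAGATACCCKG", labeled = TRUE),
    `1492R`     = Primer("1492R", "GGTTACCTTGTTACGACTT")
  )
}

#' Built-in restriction enzyme registry
#'
#' DdeI (C^TNAG), HaeIII (GG^CC) and HhaI (GCG^C). All three sites are
#' degeneracy-palindromic, so scanning the top strand finds every duplex
#' site. The cut offset counts bases of the site retained on the labelled
#' 5' fragment.
#'
#' @return named list of [RestrictionEnzyme-class] objects.
#' @examples
#' enzymeRegistry()$DdeI
#' @export
enzymeRegistry <- function() {
  list(
    DdeI   = RestrictionEnzyme("DdeI", "CTNAG", 1L),
    HaeIII = RestrictionEnzyme("HaeIII", "GGCC", 2L),
    HhaI   = RestrictionEnzyme("HhaI", "GCGC", 3L)
  )
}

#' Read user primers and enzymes from a plain-text config
#'
#' Extends the built-in registries from a whitespace-delimited text file
#' with one record per line:
#' \preformatted{
#' primer  <name>  <IUPAC sequence>  [labeled]
#' enzyme  <name>  <IUPAC site>      <cut offset>
#' }
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return list with elements `primers` and `enzymes`, each a named list.
#' @export
readRegistryConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  primers <- list()
  enzymes <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- tolower(f[1])
    if (kind == "primer") {
      if (length(f) < 3)
        stop("malformed primer line: ", ln)
      primers[[f[2]]] <- Primer(f[2], f[3],
                                labeled = length(f) >= 4 &&
                                  tolower(f[4]) == "labeled")
    } else if (kind == "enzyme") {
      if (length(f) < 4)
        stop("malformed enzyme line: ", ln)
      enzymes[[f[2]]] <- RestrictionEnzyme(f[2], f[3], as.integer(f[4]))
    } else {
      stop("unknown record type '", f[1], "' in ", path)
    }
  }
  list(primers = primers, enzymes = enzymes)
}
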