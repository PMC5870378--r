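#' Published unique-ribotype counts for six rice genotypes
#'
#' Summary counts of genotype-specific (unique) and total T-RFs detected in
#' the seed endophyte T-RFLP profiles of six *Oryza sativa* ssp. *indica*
#' cultivars of differing salinity tolerance, for three restriction enzymes
#' (DdeI, HaeIII, HhaI). These printed counts fully determine the percent
#' of genotype-specific ribotypes via [percentUnique()] (e.g. the
#' salt-sensitive genotype carries 6 of 15 unique DdeI T-RFs, i.e. 40.0%).
#'
#' @return data.frame with columns `genotype`, `tolerance` (sensitive /
#'   moderate / high), `enzyme`, `unique_trf`, `total_trf`.
#' @export
riceUniqueTRFCounts <- function() {
  path <- system.file("extdata", "rice_unique_trf_counts.tsv",
                      package = "TRFLPtools", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
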