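## Community diversity indices and core/shared/unique ribotype
## classification.

.diversityRow <- function(p) {
  if (any(p < 0)) stop("relative abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("relative abundances must sum to 1 (got ", format(sum(p)),
         "); normalise first")
  pos <- p[p > 0]
  S <- length(pos)
  H <- -sum(pos * log(pos))
  J <- if (S > 1) H / log(S) else 0
  D <- sum(pos^2)
  data.frame(S = S, shannon = H, evenness = J, dominance = D,
             simpson_complement = 1 - D, simpson_reciprocal = 1 / D)
}

#' @describeIn diversityIndices indices of a single relative-abundance
#'   vector (must sum to 1; no silent renormalisation).
#' @export
setMethod("diversityIndices", "numeric", function(x, ...) {
  .diversityRow(x)
})

#' @describeIn diversityIndices one row of indices per sample of a
#'   community matrix. Empty (all-zero) samples yield `S = 0` and `NA`
#'   indices.
#' @export
setMethod("diversityIndices", "TRFCommunity", function(x, ...) {
  a <- relAbundance(x)
  rows <- lapply(colnames(a), function(s) {
    p <- a[, s]
    if (sum(p) == 0)
      data.frame(S = 0L, shannon = NA_real_, evenness = NA_real_,
                 dominance = NA_real_, simpson_complement = NA_real_,
                 simpson_reciprocal = NA_real_)
    else .diversityRow(p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- colnames(a)
  out
})

#' @describeIn classifyTRFs classify the bins of a community matrix. A bin
#'   is present in a group when its abundance exceeds 0 in at least one
#'   sample of the group.
#' @export
setMethod("classifyTRFs", "TRFCommunity", function(x, grouping, ...) {
  a <- relAbundance(x)
  if (is.null(names(grouping)))
    stop("'grouping' must be a named vector mapping samples to groups")
  unmapped <- setdiff(colnames(a), names(grouping))
  if (length(unmapped))
    stop("unmapped sample(s): ", paste(unmapped, collapse = ", "))
  groups <- unique(as.character(grouping[colnames(a)]))
  presence <- sapply(groups, function(g) {
    cols <- colnames(a)[as.character(grouping[colnames(a)]) == g]
    rowSums(a[, cols, drop = FALSE] > 0) > 0
  })
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = nrow(a),
                       dimnames = list(NULL, groups))
  labels <- binLabels(x)
  detected <- rowSums(presence) > 0
  core <- labels[rowSums(presence) == length(groups)]
  unique_ <- stats::setNames(lapply(groups, function(g) {
    labels[presence[, g] & rowSums(presence) == 1]
  }), groups)
  sharedIdx <- which(detected & rowSums(presence) > 1 &
                       rowSums(presence) < length(groups))
  shared <- stats::setNames(lapply(sharedIdx, function(i) {
    groups[presence[i, ]]
  }), labels[sharedIdx])
  structure(list(core = core, shared = shared, unique = unique_,
                 groups = groups),
            class = "ribotypeClassification")
})

#' @export
print.ribotypeClassification <- function(x, ...) {
  cat(sprintf("Ribotype classification over %d groups\n", length(x$groups)))
  cat(sprintf("  core (all groups): %s\n",
              if (length(x$core)) paste(x$core, collapse = ", ") else "none"))
  cat(sprintf("  shared (2+ groups): %d bin(s)\n", length(x$shared)))
  for (g in x$groups)
    cat(sprintf("  unique to %s: %s\n", g,
                if (length(x$unique[[g]]))
                  paste(x$unique[[g]], collapse = ", ") else "none"))
  invisible(x)
}

#' Percentage of genotype-specific (unique) ribotypes
#'
#' @param uniqueCount number of T-RFs found only in the genotype.
#' @param totalCount total T-RFs detected in the genotype.
#' @return `100 * uniqueCount / totalCount`, rounded to one decimal.
#' @examples
#' percentUnique(6, 15)  # 40.0
#' @export
percentUnique <- function(uniqueCount, totalCount) {
  if (any(totalCount <= 0))
    stop("totalCount must be positive")
  if (any(uniqueCount < 0) || any(uniqueCount > totalCount))
    stop("uniqueCount must lie in [0, totalCount]")
  round(100 * uniqueCount / totalCount, 1)
}

#' Group summary table of diversity indices
#'
#' Summarises per-sample diversity indices as mean and standard error per
#' group, in the long layout of a printed diversity table (rows = index x
#' group).
#'
#' @param div data.frame from [diversityIndices()] (rownames = samples).
#' @param grouping named vector mapping samples to groups.
#' @param file optional TSV output path.
#' @return data.frame with columns `index`, `group`, `mean`, `se`, `n` and
#'   a formatted `mean_se` string.
#' @export
diversityTable <- function(div, grouping, file = NULL) {
  groups <- as.character(grouping[rownames(div)])
  if (anyNA(groups)) stop("every sample needs a group")
  rows <- list()
  for (idx in colnames(div)) {
    for (g in unique(groups)) {
      v <- div[groups == g, idx]
      v <- v[!is.na(v)]
      m <- mean(v)
      se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, group = g, mean = m, se = se, n = length(v),
        mean_se = sprintf("%.2f ± %.2f", m, se),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}
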