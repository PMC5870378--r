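## Bray-Curtis dissimilarity, non-metric multidimensional scaling by
## multi-start isotonic-regression minimisation of Kruskal stress-1,
## ANOSIM permutation tests, and UPGMA clustering.

## run expr with a deterministic RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' @describeIn brayCurtis Bray-Curtis dissimilarities between the samples
#'   of a community matrix.
#' @export
setMethod("brayCurtis", "TRFCommunity", function(x, ...) {
  brayCurtis(t(relAbundance(x)))
})

#' @describeIn brayCurtis Bray-Curtis dissimilarities between the rows of
#'   a samples x features matrix.
#' @export
setMethod("brayCurtis", "matrix", function(x, ...) {
  n <- nrow(x)
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("sample", seq_len(n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      denom <- sum(x[i, ] + x[j, ])
      if (denom == 0)
        stop("Bray-Curtis undefined for the all-zero sample pair ",
             labs[i], " / ", labs[j])
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  dimnames(d) <- list(labs, labs)
  stats::as.dist(d)
})

#' Percent similarity from a dissimilarity
#'
#' T-RFLP similarity is conventionally reported on a percent scale,
#' `100 * (1 - d)`.
#'
#' @param d dissimilarities (a `dist` or numeric).
#' @return similarities on the 0-100 scale, same shape as `d`.
#' @export
percentSimilarity <- function(d) 100 * (1 - d)

#' Least-squares monotone (isotonic) regression
#'
#' Pool-adjacent-violators fit of a non-decreasing sequence to `y` in its
#' given order, minimising the (optionally weighted) sum of squares.
#'
#' @param y numeric target values, already ordered by the rank of the
#'   quantity the fit must be monotone in.
#' @param w optional positive weights.
#' @return the fitted non-decreasing vector, same length as `y`.
#' @examples
#' monotoneRegression(c(1, 3, 2))  # 1, 2.5, 2.5
#' @export
monotoneRegression <- function(y, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  if (n <= 1L) return(y)
  ## blocks held as parallel stacks of (value, weight, size)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

## Kruskal stress-1 machinery. delta: observed dissimilarities (vector in
## dist order); d: configuration distances. Ties in delta are handled by
## the primary approach: within a tied block the fit may follow the
## configuration, implemented by ordering tied entries by current d.
.disparities <- function(delta, d) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- monotoneRegression(d[ord])
  dhat
}

.stress1 <- function(d, dhat) {
  denom <- sum(d^2)
  if (denom == 0) return(0)
  sqrt(sum((d - dhat)^2) / denom)
}

#' Kruskal stress-1 of a configuration
#'
#' Evaluates `sqrt(sum((d - dhat)^2) / sum(d^2))` where `d` are the
#' inter-point distances of `coordinates` and `dhat` the disparities
#' obtained by monotone regression of `d` on the ranks of `dissimilarity`.
#'
#' @param dissimilarity a `dist` of observed dissimilarities.
#' @param coordinates samples x k configuration matrix (same order as the
#'   `dist` labels).
#' @return the stress-1 value.
#' @export
kruskalStress <- function(dissimilarity, coordinates) {
  delta <- as.vector(dissimilarity)
  d <- as.vector(stats::dist(coordinates))
  .stress1(d, .disparities(delta, d))
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the observed dissimilarities as
#' closely as possible. Each random start iterates: compute configuration
#' distances, fit disparities by pool-adjacent-violators monotone
#' regression against the dissimilarity ranks, then move points by a
#' Guttman transform towards the disparities, until the stress-1 change
#' drops below `tol` or `maxIter` is reached. The first start is seeded
#' from classical (metric) scaling — pure stress-1 admits degenerate
#' collapsed step-function solutions, and a metric start anchors the search
#' at the true configuration whenever one exists — and the remaining starts
#' are random. The lowest-stress start wins;
#' the returned configuration is centred at the origin and rotated to its
#' principal axes (stress is invariant under rigid motion).
#'
#' @param dissimilarity a `dist` (e.g. from [brayCurtis()]).
#' @param k number of dimensions (default 2).
#' @param nStarts number of random starts (default 100).
#' @param maxIter iteration cap per start (default 300).
#' @param tol convergence tolerance on the stress change (default 1e-7).
#' @param seed integer seed; starts are drawn sequentially from it, so the
#'   first `m` starts of two runs with the same seed coincide.
#' @return an [NMDSResult-class].
#' @export
nmdsEmbed <- function(dissimilarity, k = 2L, nStarts = 100L,
                      maxIter = 300L, tol = 1e-7, seed = 1L) {
  delta <- as.vector(dissimilarity)
  n <- attr(dissimilarity, "Size")
  labs <- attr(dissimilarity, "Labels")
  if (is.null(labs)) labs <- paste0("sample", seq_len(n))
  if (n < 3L) stop("NMDS needs at least 3 samples")
  if (k >= n) stop("k must be smaller than the number of samples")
  stopifnot(nStarts >= 1L)

  ## classical (metric) scaling start: guards against the degenerate
  ## collapsed solutions that pure stress-1 admits, and is exact for
  ## perfectly embeddable data
  Xcmd <- tryCatch({
    cm <- stats::cmdscale(dissimilarity, k = k)
    if (ncol(cm) < k)
      cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
    cm
  }, error = function(e) NULL)

  best <- NULL
  startStress <- numeric(nStarts)
  .withSeed(seed, for (s in seq_len(nStarts)) {
    X <- if (s == 1L && !is.null(Xcmd)) Xcmd
         else matrix(stats::runif(n * k, -0.5, 0.5), n, k)
    d <- as.vector(stats::dist(X))
    dhat <- .disparities(delta, d)
    stress <- .stress1(d, dhat)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      ## Guttman transform towards the disparities
      Dhat <- matrix(0, n, n); Dhat[lower.tri(Dhat)] <- dhat
      Dhat <- Dhat + t(Dhat)
      Dcur <- matrix(0, n, n); Dcur[lower.tri(Dcur)] <- d
      Dcur <- Dcur + t(Dcur)
      ratio <- ifelse(Dcur > 0, Dhat / Dcur, 0)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      X <- B %*% X / n
      d <- as.vector(stats::dist(X))
      dhat <- .disparities(delta, d)
      newStress <- .stress1(d, dhat)
      if (abs(stress - newStress) < tol) {
        stress <- newStress
        converged <- TRUE
        break
      }
      stress <- newStress
    }
    startStress[s] <- stress
    if (is.null(best) || stress < best$stress)
      best <- list(X = X, stress = stress, start = s, converged = converged)
  })

  ## centre and rotate to principal axes; recompute stress pieces on the
  ## final configuration so the stored values are self-consistent
  X <- scale(best$X, center = TRUE, scale = FALSE)
  if (n > 1L) {
    rot <- svd(X)$v
    X <- X %*% rot
  }
  rownames(X) <- labs
  colnames(X) <- paste0("NMDS", seq_len(k))
  d <- as.vector(stats::dist(X))
  dhat <- .disparities(delta, d)
  new("NMDSResult", coordinates = unclass(X), stress = .stress1(d, dhat),
      disparities = dhat, nStarts = as.integer(nStarts),
      bestStart = as.integer(best$start), seed = as.integer(seed),
      converged = best$converged, startStress = startStress)
}

## ANOSIM R for one labelling: ranks r of the dissimilarities are fixed,
## 'within' says which pairs are within-group.
.anosimR <- function(r, within, n) {
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

## all distinct assignments of group labels (sizes fixed) to n positions
.enumerateAssignments <- function(sizes) {
  n <- sum(sizes)
  recur <- function(remaining, positions) {
    if (length(remaining) == 1L)
      return(list(stats::setNames(list(positions), NULL)))
    out <- list()
    picks <- utils::combn(positions, remaining[1], simplify = FALSE)
    for (p in picks) {
      rest <- recur(remaining[-1], setdiff(positions, p))
      for (r in rest) out[[length(out) + 1L]] <- c(list(p), r)
    }
    out
  }
  recur(sizes, seq_len(n))
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All off-diagonal dissimilarities are
#' ranked (average ranks for ties) and
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)`.
#' Significance comes from permuting the group labels; the p-value is
#' `(1 + #\{R* >= R\}) / (1 + nPermutations)`. When the number of distinct
#' labelings `n! / prod(n_g!)` does not exceed `nPermutations` the null
#' distribution is enumerated exactly instead (`method = "exact"`, p =
#' fraction of labelings with `R* >= R`, the observed labelling included).
#'
#' @param dissimilarity a `dist`.
#' @param grouping vector of group labels, one per sample (named vectors
#'   are matched to the `dist` labels).
#' @param nPermutations permutations for the sampled null (default 999).
#' @param seed integer seed for the sampled permutations.
#' @param pairwise if `TRUE` (default) also test every group pair.
#' @param method `"auto"` (exact when feasible, otherwise sampled),
#'   `"exact"` or `"sampled"`.
#' @return an [ANOSIMResult-class].
#' @export
anosimTest <- function(dissimilarity, grouping, nPermutations = 999L,
                       seed = 1L, pairwise = TRUE,
                       method = c("auto", "exact", "sampled")) {
  method <- match.arg(method)
  n <- attr(dissimilarity, "Size")
  labs <- attr(dissimilarity, "Labels")
  if (!is.null(names(grouping))) {
    if (is.null(labs))
      stop("named grouping requires a labelled dissimilarity")
    grouping <- grouping[labs]
  }
  grouping <- as.character(grouping)
  if (length(grouping) != n)
    stop("grouping must map every sample")
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("ANOSIM needs at least two groups")
  if (any(sizes < 2L))
    stop("every group needs at least two samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  r <- rank(as.vector(dissimilarity))
  pairIdx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  withinOf <- function(g) g[pairIdx[, 1]] == g[pairIdx[, 2]]
  Robs <- .anosimR(r, withinOf(grouping), n)

  nDistinct <- round(exp(lgamma(n + 1) - sum(lgamma(sizes + 1))))
  useExact <- switch(method,
    auto = is.finite(nDistinct) && nDistinct <= nPermutations,
    exact = TRUE,
    sampled = FALSE)
  if (useExact && (!is.finite(nDistinct) || nDistinct > 1e6))
    stop("exact enumeration infeasible: ", nDistinct, " labelings")
  if (useExact) {
    groupsOrdered <- names(sizes)
    assigns <- .enumerateAssignments(as.integer(sizes))
    Rnull <- vapply(assigns, function(a) {
      g <- character(n)
      for (i in seq_along(a)) g[a[[i]]] <- groupsOrdered[i]
      .anosimR(r, withinOf(g), n)
    }, numeric(1))
    p <- mean(Rnull >= Robs - 1e-12)
    method <- "exact"
    nUsed <- length(assigns)
  } else {
    count <- .withSeed(seed, {
      cnt <- 0L
      for (b in seq_len(nPermutations)) {
        g <- sample(grouping)
        if (.anosimR(r, withinOf(g), n) >= Robs - 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + count) / (1 + nPermutations)
    method <- "sampled"
    nUsed <- as.integer(nPermutations)
  }

  pw <- data.frame(groupA = character(), groupB = character(),
                   R = numeric(), p = numeric(), method = character(),
                   stringsAsFactors = FALSE)
  if (pairwise && length(sizes) > 2L) {
    dm <- as.matrix(dissimilarity)
    combos <- utils::combn(names(sizes), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(seq_along(combos), function(ci) {
      gs <- combos[[ci]]
      sel <- grouping %in% gs
      sub <- stats::as.dist(dm[sel, sel, drop = FALSE])
      res <- anosimTest(sub, grouping[sel], nPermutations,
                        seed = as.integer(seed) + ci, pairwise = FALSE)
      data.frame(groupA = gs[1], groupB = gs[2], R = res@R, p = res@pValue,
                 method = res@method, stringsAsFactors = FALSE)
    }))
  }

  new("ANOSIMResult", R = Robs, pValue = p,
      nPermutations = as.integer(nUsed), method = method, pairwise = pw)
}

#' UPGMA (group-average) hierarchical clustering
#'
#' @param dissimilarity a `dist`.
#' @return an `hclust` object with non-decreasing merge heights.
#' @export
upgmaCluster <- function(dissimilarity) {
  if (attr(dissimilarity, "Size") < 2L)
    stop("clustering needs at least 2 samples")
  stats::hclust(dissimilarity, method = "average")
}

#' Percent-similarity merge levels of a dendrogram
#'
#' @param hc an `hclust` from [upgmaCluster()] on Bray-Curtis
#'   dissimilarities.
#' @return `100 * (1 - height)` for each merge.
#' @export
similarityLevels <- function(hc) 100 * (1 - hc$height)

#' Export a dendrogram as Newick
#'
#' Branch lengths follow the ultrametric convention (each tip sits at
#' height 0, internal nodes at merge height / 2).
#'
#' @param hc an `hclust`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportNewick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}
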