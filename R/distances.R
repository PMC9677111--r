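# Similarity and distance construction from marker and trait data, plus
# fusion of heterogeneous distance matrices for the joint analysis.

#' Jaccard similarity between accessions from binary bands
#'
#' `s(x, y) = a / (a + b + c)` with a the shared band presences and b, c the
#' presences unique to either accession, computed over pairwise-complete
#' bands (both accessions scored). A pair with no presence at all among its
#' complete bands has undefined similarity and raises an error naming the
#' pair.
#'
#' @param x a [MarkerMatrix-class].
#' @return A [SimilarityMatrix-class].
#' @export
jaccardSimilarity <- function(x) {
  sc <- markerScores(x)
  n <- nrow(sc)
  s <- diag(1, n)
  dimnames(s) <- list(rownames(sc), rownames(sc))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      xi <- sc[i, ]; xj <- sc[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      a <- sum(xi[ok] == 1 & xj[ok] == 1)
      bc <- sum(xi[ok] != xj[ok])
      if (a + bc == 0)
        stop("undefined similarity: accessions '", rownames(sc)[i],
             "' and '", rownames(sc)[j],
             "' share no scored band presence")
      s[i, j] <- s[j, i] <- a / (a + bc)
    }
  }
  SimilarityMatrix(s)
}

#' Convert a similarity matrix to a distance matrix
#'
#' @param sim a [SimilarityMatrix-class].
#' @return A [DistanceMatrix-class] with `d = 1 - s`.
#' @export
similarityToDistance <- function(sim) {
  v <- 1 - dmValues(sim)
  diag(v) <- 0
  DistanceMatrix(v)
}

#' Band-mismatch distance for binary marker data
#'
#' The squared distance between two accessions is the number of
#' pairwise-complete bands at which they differ (the standard metric for
#' one-level molecular variance analysis of binary data); the stored
#' distance is its square root.
#'
#' @param x a [MarkerMatrix-class].
#' @return A [DistanceMatrix-class]; the squared values feed [amova()].
#' @export
bandMismatchDistance <- function(x) {
  sc <- markerScores(x)
  n <- nrow(sc)
  d2 <- matrix(0, n, n, dimnames = list(rownames(sc), rownames(sc)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(sc[i, ]) & !is.na(sc[j, ])
      d2[i, j] <- d2[j, i] <- sum(sc[i, ok] != sc[j, ok])
    }
  }
  DistanceMatrix(sqrt(d2))
}

#' Standardized Euclidean distance between trait profiles
#'
#' Each trait column is centred and scaled to unit variance (population
#' convention, denominator n) before Euclidean distances are taken, so the
#' result is invariant to affine rescaling of any trait.
#'
#' @param traitMeans accession x trait numeric matrix (e.g.
#'   [genotypeMeans()]).
#' @return A [DistanceMatrix-class].
#' @export
traitDistance <- function(traitMeans) {
  m <- as.matrix(traitMeans)
  sds <- apply(m, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(sds == 0))
    stop("zero-variance trait: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m, center = TRUE, scale = FALSE)
  z <- sweep(z, 2L, sds, "/")
  DistanceMatrix(as.matrix(stats::dist(z)))
}

#' Fuse several distance matrices into one
#'
#' Each matrix is range-normalised by its maximum off-diagonal entry (so
#' every input lies in `[0, 1]`) and the normalised matrices are averaged
#' with the given weights (renormalised to sum to one). Inputs must share
#' the same label set; labels are aligned by name.
#'
#' @param matrices list of [DistanceMatrix-class] objects.
#' @param weights non-negative weights, one per matrix, not all zero.
#' @return A [DistanceMatrix-class] with entries in `[0, 1]`.
#' @export
fuseDistances <- function(matrices, weights = rep(1, length(matrices))) {
  stopifnot(length(matrices) >= 1L, length(weights) == length(matrices))
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  lab <- sort(dmLabels(matrices[[1L]]))
  norm <- lapply(seq_along(matrices), function(i) {
    v <- dmValues(matrices[[i]])
    if (!setequal(rownames(v), lab))
      stop("alignment error: matrix ", i, " has different labels")
    v <- v[lab, lab]
    mx <- max(v)
    if (mx == 0) stop("normalization error: matrix ", i, " is all zero")
    v / mx
  })
  w <- weights / sum(weights)
  out <- Reduce(`+`, Map(function(m, wi) m * wi, norm, w))
  DistanceMatrix(out)
}
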