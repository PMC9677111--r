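# Hierarchical clustering (UPGMA / complete / Ward) with deterministic
# tie-breaking, cophenetic analysis and dendrogram comparison; k-means with
# silhouette-guided choice of k; PCA.
#
# The agglomeration is written out explicitly (Lance-Williams updates)
# rather than delegated, because the package pins two conventions the stock
# routines leave unspecified: ties are always broken by the
# lexicographically smallest pair of cluster representative labels, and the
# UPGMA merge height is half the between-cluster average distance, so that
# the cophenetic distance (twice the LCA height) reproduces the original
# distances exactly on ultrametric input.

.agglomerate <- function(d, linkage = c("upgma", "complete", "ward")) {
  linkage <- match.arg(linkage)
  v <- dmValues(d)
  lab <- rownames(v)
  n <- length(lab)
  if (n < 2L) stop("need at least 2 leaves")
  cur <- if (linkage == "ward") v^2 else v   # working dissimilarity
  size <- rep(1L, n)
  id <- -seq_len(n)                          # hclust encoding per active row
  rep_ <- lab                                # representative (min) label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; bestD <- Inf; bestKey <- NULL
    for (ii in seq_len(length(act) - 1L)) {
      for (jj in (ii + 1L):length(act)) {
        i <- act[ii]; j <- act[jj]
        dij <- cur[i, j]
        key <- sort(c(rep_[i], rep_[j]))
        if (dij < bestD - 1e-12 ||
            (abs(dij - bestD) <= 1e-12 && !is.null(bestKey) &&
             (key[1L] < bestKey[1L] ||
              (key[1L] == bestKey[1L] && key[2L] < bestKey[2L])))) {
          best <- c(i, j); bestD <- dij; bestKey <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    mergeDist <- if (linkage == "ward") sqrt(bestD) else bestD
    heights[step] <- if (linkage == "upgma") mergeDist / 2 else mergeDist
    # children ordered by representative label, so serialization is stable
    merge[step, ] <- if (rep_[i] <= rep_[j]) c(id[i], id[j]) else
      c(id[j], id[i])
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      cur[i, k] <- cur[k, i] <- switch(linkage,
        upgma = (ni * cur[i, k] + nj * cur[j, k]) / (ni + nj),
        complete = max(cur[i, k], cur[j, k]),
        ward = ((ni + size[k]) * cur[i, k] + (nj + size[k]) * cur[j, k] -
                size[k] * bestD) / (ni + nj + size[k]))
    }
    size[i] <- ni + nj
    id[i] <- step
    rep_[i] <- min(rep_[i], rep_[j])
    active[j] <- FALSE
  }
  Dendrogram(lab, merge, heights)
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage sequential agglomeration. The merge height is half the
#' between-cluster average distance, so the tree is ultrametric with
#' cophenetic distance (= twice the lowest-common-ancestor height) equal to
#' the between-cluster average distance. Ties are broken toward the
#' lexicographically smallest pair of cluster labels, making the result
#' deterministic.
#'
#' @param d a [DistanceMatrix-class], `n >= 2`.
#' @return A [Dendrogram-class].
#' @export
upgma <- function(d) .agglomerate(d, "upgma")

#' Hierarchical clustering with a chosen linkage
#'
#' Lance-Williams agglomeration with `"upgma"` (average), `"complete"` or
#' `"ward"` (Ward's minimum variance on squared distances) linkage. For
#' `"upgma"` the output is identical to [upgma()]; for the other linkages
#' the merge height is the between-cluster merge distance itself.
#'
#' @param d a [DistanceMatrix-class].
#' @param linkage `"upgma"`, `"complete"` or `"ward"`.
#' @return A [Dendrogram-class].
#' @export
hierarchicalCluster <- function(d, linkage = c("upgma", "complete",
                                               "ward")) {
  .agglomerate(d, match.arg(linkage))
}

#' Convert a Dendrogram to a base hclust object
#'
#' @param dend a [Dendrogram-class].
#' @return An object of class `hclust` (plotting order computed by leaf
#'   traversal).
#' @export
asHclust <- function(dend) {
  m <- mergeMatrix(dend)
  ord <- integer(0)
  rec <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { rec(m[node, 1L]); rec(m[node, 2L]) }
  }
  rec(nrow(m))
  structure(list(merge = m, height = mergeHeights(dend), order = ord,
                 labels = leafLabels(dend), method = "MarkerDiversity",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Cophenetic distance matrix of a Dendrogram
#'
#' `c(i, j)` is twice the height of the lowest common ancestor of leaves i
#' and j — for the package's UPGMA height convention this reproduces the
#' between-cluster average distances on the original scale.
#'
#' @param dend a [Dendrogram-class].
#' @return A [DistanceMatrix-class].
#' @export
copheneticDistance <- function(dend) {
  cc <- 2 * as.matrix(stats::cophenetic(asHclust(dend)))
  lb <- leafLabels(dend)
  DistanceMatrix(cc[lb, lb])
}

#' Cut a Dendrogram into k clusters
#'
#' Cuts between the (n-k)th and (n-k+1)th merge heights; with tied heights
#' the cut resolves toward the lower height, which can make some k
#' unattainable — the nearest attainable partition is then returned with a
#' warning.
#'
#' @param dend a [Dendrogram-class].
#' @param k desired number of clusters, `1 <= k <= n`.
#' @return Named integer vector of contiguous cluster indices `1..k`.
#' @export
cutDendrogram <- function(dend, k) {
  n <- length(leafLabels(dend))
  stopifnot(k >= 1L, k <= n)
  part <- stats::cutree(asHclust(dend), k = k)
  got <- length(unique(part))
  if (got != k)
    warning("tied merge heights: requested k = ", k,
            ", nearest attainable k = ", got)
  part
}

#' Compare two dendrograms on the same leaves
#'
#' Reports the Pearson correlation between the two cophenetic matrices
#' (off-diagonal entries) and, for each k in `kRange`, the adjusted Rand
#' index between the k-cluster cuts together with the number of accessions
#' whose pairwise co-membership differs between the two trees.
#'
#' @param d1,d2 [Dendrogram-class] objects with identical leaf sets.
#' @param kRange integer vector of cut levels.
#' @return list with `copheneticCorrelation` and `cutAgreement`
#'   (data.frame: k, ari, mismatched_accessions).
#' @export
compareDendrograms <- function(d1, d2, kRange = 2:10) {
  if (!setequal(leafLabels(d1), leafLabels(d2)))
    stop("alignment error: dendrograms have different leaf sets")
  lb <- sort(leafLabels(d1))
  c1 <- dmValues(copheneticDistance(d1))[lb, lb]
  c2 <- dmValues(copheneticDistance(d2))[lb, lb]
  ut <- upper.tri(c1)
  rho <- stats::cor(c1[ut], c2[ut])
  kRange <- kRange[kRange >= 1 & kRange <= length(lb)]
  rows <- lapply(kRange, function(k) {
    p1 <- cutDendrogram(d1, k)[lb]
    p2 <- cutDendrogram(d2, k)[lb]
    co1 <- outer(p1, p1, `==`)
    co2 <- outer(p2, p2, `==`)
    mism <- co1 != co2
    diag(mism) <- FALSE
    data.frame(k = k, ari = mclust::adjustedRandIndex(p1, p2),
               mismatched_accessions = sum(rowSums(mism) > 0))
  })
  list(copheneticCorrelation = rho, cutAgreement = do.call(rbind, rows))
}

#' k-means with silhouette-guided selection of k
#'
#' Runs Lloyd's algorithm with `nRestarts` random initialisations for every
#' k in `kRange` (a single seeded RNG stream, so the result is reproducible
#' bit-for-bit given `seed`, `kRange` and `nRestarts`) and keeps the k with
#' the largest mean silhouette width. A maximum mean silhouette below 0.25
#' is flagged as unsupported cluster structure.
#'
#' @param data accession x feature numeric matrix (standardise first if the
#'   features have different scales).
#' @param kRange candidate cluster counts, within `[2, n - 1]`.
#' @param nRestarts random restarts per k (default 25).
#' @param seed integer seed.
#' @return list with `partition` (named integer vector), `k`, `silhouette`
#'   (data.frame: k, mean_silhouette), `supported` (logical).
#' @export
kmeansSelect <- function(data, kRange = 2:10, nRestarts = 25L, seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 observations")
  if (all(apply(data, 2L, function(v) max(v) - min(v)) == 0))
    stop("degenerate input: all points identical, k is undefined")
  kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
  dd <- stats::dist(data)
  set.seed(seed)
  fits <- list(); sil <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    km <- suppressWarnings(
      stats::kmeans(data, centers = kRange[i], nstart = nRestarts,
                    algorithm = "Lloyd", iter.max = 100L))
    sw <- cluster::silhouette(km$cluster, dd)
    sil[i] <- mean(sw[, "sil_width"])
    fits[[i]] <- km$cluster
  }
  bestI <- which.max(sil)
  part <- stats::setNames(fits[[bestI]], rownames(data))
  list(partition = part, k = kRange[bestI],
       silhouette = data.frame(k = kRange, mean_silhouette = sil),
       supported = sil[bestI] >= 0.25)
}

#' Principal component analysis of a trait matrix
#'
#' Eigendecomposition of the correlation matrix (default) or covariance
#' matrix via [stats::prcomp()]. Component signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param data accession x trait numeric matrix, >= 2 traits.
#' @param scale. scale traits to unit variance (default `TRUE`).
#' @return list with `scores`, `loadings`, `eigenvalues`, `percentVar`
#'   (sums to 100 over all components).
#' @export
pcaTraits <- function(data, scale. = TRUE) {
  data <- as.matrix(data)
  if (scale.) {
    sds <- apply(data, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance trait: ",
           paste(colnames(data)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(data, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  ev <- pc$sdev^2
  list(scores = scores, loadings = loadings, eigenvalues = ev,
       percentVar = 100 * ev / sum(ev))
}
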