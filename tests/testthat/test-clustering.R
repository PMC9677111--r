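.abc <- function() {
  DistanceMatrix(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
                        dimnames = list(c("A", "B", "C"),
                                        c("A", "B", "C"))))
}

test_that("upgma reproduces the hand-worked merges and height convention", {
  tre <- upgma(.abc())
  expect_equal(mergeHeights(tre), c(1, 3))
  expect_equal(mergeMatrix(tre)[1, ], c(-1L, -2L))

  two <- DistanceMatrix(matrix(c(0, 5, 5, 0), 2,
                               dimnames = list(c("A", "B"),
                                               c("A", "B"))))
  expect_equal(mergeHeights(upgma(two)), 2.5)
})

test_that("upgma cophenetic matrix equals independent oracles on random input", {
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    D <- randomDistanceMatrix(n, seed = 1000 + seed)
    got <- dmValues(copheneticDistance(upgma(D)))
    expect_equal(got, naiveUpgmaCophenetic(dmValues(D)),
                 tolerance = 1e-10)
    hc <- stats::hclust(as.dist(dmValues(D)), method = "average")
    ref <- as.matrix(stats::cophenetic(hc))[rownames(got), colnames(got)]
    expect_equal(got, ref, tolerance = 1e-10)
    # ultrametric inequality
    cc <- got
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      expect_gte(max(cc[i, k], cc[j, k]) + 1e-12, cc[i, j])
  }
})

test_that("alternative linkages follow their merge rules", {
  tre <- hierarchicalCluster(.abc(), "complete")
  expect_equal(mergeHeights(tre), c(2, 6))

  # all pairwise distances equal: equal merge heights under any linkage
  eq <- DistanceMatrix(matrix(1, 4, 4,
                              dimnames = list(paste0("L", 1:4),
                                              paste0("L", 1:4))) -
                       diag(4))
  for (lk in c("upgma", "complete", "ward"))
    expect_equal(length(unique(round(
      mergeHeights(hierarchicalCluster(eq, lk)), 9))), 1)

  D <- randomDistanceMatrix(9, seed = 77)
  expect_equal(mergeHeights(hierarchicalCluster(D, "upgma")),
               mergeHeights(upgma(D)))
  # ward agrees with hclust ward.D2 heights on continuous data (no ties)
  hw <- stats::hclust(as.dist(dmValues(D)), method = "ward.D2")
  expect_equal(sort(mergeHeights(hierarchicalCluster(D, "ward"))),
               sort(hw$height), tolerance = 1e-10)
  expect_error(hierarchicalCluster(D, "single"), "arg")
})

test_that("tie-breaking is deterministic toward the smallest label pair", {
  lab <- c("B", "A", "C")
  v <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, dimnames = list(lab, lab))
  tre <- upgma(DistanceMatrix(v))
  # first merge must take the lexicographically smallest pair {A, B}
  first <- sort(leafLabels(tre)[-mergeMatrix(tre)[1, ]])
  expect_equal(first, c("A", "B"))
})

test_that("cophenetic distances double the LCA height", {
  two <- Dendrogram(c("A", "B"), matrix(c(-1L, -2L), 1), 1)
  expect_equal(dmValues(copheneticDistance(two))["A", "B"], 2)
  cc <- dmValues(copheneticDistance(upgma(.abc())))
  expect_equal(cc["A", "B"], 2)
  expect_equal(cc["A", "C"], 6)
  expect_equal(cc["B", "C"], 6)
})

test_that("tree cutting yields contiguous partitions at every k", {
  tre <- upgma(.abc())
  expect_equal(unname(cutDendrogram(tre, 1)), rep(1L, 3))
  expect_equal(length(unique(cutDendrogram(tre, 3))), 3)
  p2 <- cutDendrogram(tre, 2)
  expect_equal(p2[["A"]], p2[["B"]])
  expect_false(p2[["A"]] == p2[["C"]])

  D <- randomDistanceMatrix(10, seed = 5)
  tre <- upgma(D)
  hPrev <- 0
  for (k in 10:1) {
    part <- cutDendrogram(tre, k)
    expect_equal(sort(unique(unname(part))), seq_len(k))
  }
})

test_that("dendrogram comparison reports cophenetic correlation and cut agreement", {
  D <- randomDistanceMatrix(10, seed = 3)
  t1 <- upgma(D)
  cmp <- compareDendrograms(t1, t1, kRange = 2:5)
  expect_equal(cmp$copheneticCorrelation, 1)
  expect_true(all(cmp$cutAgreement$ari == 1))
  expect_true(all(cmp$cutAgreement$mismatched_accessions == 0))

  t2 <- upgma(randomDistanceMatrix(10, seed = 4))
  cmp2 <- compareDendrograms(t1, t2, kRange = 2:6)
  lb <- sort(leafLabels(t1))
  for (i in seq_len(nrow(cmp2$cutAgreement))) {
    k <- cmp2$cutAgreement$k[i]
    expect_equal(cmp2$cutAgreement$ari[i],
                 bruteARI(cutDendrogram(t1, k)[lb],
                          cutDendrogram(t2, k)[lb]),
                 tolerance = 1e-12)
  }
  t3 <- upgma(randomDistanceMatrix(9, seed = 4))
  expect_error(compareDendrograms(t1, t3), "alignment")
})

test_that("silhouette-guided k-means recovers planted blob counts", {
  set.seed(2)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, 0, 0.1), n), 2,
                                    center, `+`)
  x2 <- rbind(blob(c(0, 0), 20), blob(c(10, 0), 20))
  rownames(x2) <- sprintf("A%02d", 1:40)
  r2 <- kmeansSelect(x2, 2:6, seed = 11)
  expect_equal(r2$k, 2)
  expect_equal(bruteARI(r2$partition, rep(1:2, each = 20)), 1)
  expect_true(r2$supported)

  x3 <- rbind(blob(c(0, 0), 15), blob(c(10, 0), 15), blob(c(5, 9), 15))
  rownames(x3) <- sprintf("A%02d", 1:45)
  expect_equal(kmeansSelect(x3, 2:6, seed = 11)$k, 3)

  # bit-for-bit reproducibility under a fixed seed
  r2b <- kmeansSelect(x2, 2:6, seed = 11)
  expect_identical(r2$partition, r2b$partition)
  expect_identical(r2$silhouette, r2b$silhouette)

  same <- matrix(1, 5, 2, dimnames = list(paste0("A", 1:5), NULL))
  expect_error(kmeansSelect(same, 2:3), "identical")
  expect_error(kmeansSelect(x2[1:2, ], 2:2), "at least 3")
})

test_that("pca reports percent variance summing to 100 with fixed signs", {
  set.seed(8)
  a <- rnorm(30)
  perf <- cbind(t1 = a, t2 = 2 * a + 3)
  rownames(perf) <- sprintf("A%02d", 1:30)
  p <- pcaTraits(perf)
  expect_equal(p$percentVar[1], 100, tolerance = 1e-9)

  x <- matrix(rnorm(300 * 2), 300, 2,
              dimnames = list(NULL, c("t1", "t2")))
  p2 <- pcaTraits(x)
  expect_equal(sum(p2$percentVar), 100, tolerance = 1e-9)
  expect_equal(p2$percentVar[1], 50, tolerance = 12)   # isotropic
  expect_equal(sum(p2$eigenvalues), 2, tolerance = 1e-9)  # trace identity
  for (j in seq_len(ncol(p2$loadings)))
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)

  # permutation invariance in accession order (up to the same reordering)
  x3 <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("A%02d", 1:20),
                                                 paste0("t", 1:3)))
  p3 <- pcaTraits(x3)
  ord <- sample(20)
  p4 <- pcaTraits(x3[ord, ])
  expect_equal(p4$percentVar, p3$percentVar, tolerance = 1e-9)
  expect_equal(p4$scores[rownames(x3), ], p3$scores, tolerance = 1e-9)

  x3[, 2] <- 5
  expect_error(pcaTraits(x3), "t2")
})
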