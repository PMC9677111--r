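.zeroWithin <- function() {
  lab <- c("A1", "A2", "B1", "B2")
  v <- matrix(1, 4, 4, dimnames = list(lab, lab))
  v[1:2, 1:2] <- 0
  v[3:4, 3:4] <- 0
  list(d = DistanceMatrix(v),
       pop = setNames(c("p1", "p1", "p2", "p2"), lab))
}

test_that("amova attributes all variance among populations in the limiting case", {
  z <- .zeroWithin()
  am <- amova(z$d, z$pop, nPermutations = 99, seed = 1)
  expect_equal(unname(am$percent["among"]), 100)
  expect_equal(am$phi_st, 1)
  expect_equal(am$table$df, c(1, 2))
  expect_equal(sum(am$percent), 100)
})

test_that("amova equals the brute-force pairwise-sum oracle on small instances", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(8:12, 1)
    sizes <- c(2, 2, n - 4)
    pop <- rep(paste0("p", 1:3), sizes)
    lab <- sprintf("A%02d", 1:n)
    v <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    dimnames(v) <- list(lab, lab)
    am <- amova(DistanceMatrix(v), setNames(pop, lab),
                nPermutations = 9, seed = seed)
    br <- bruteAmova(v^2, pop)
    expect_equal(am$table$ss, c(br$ssAmong, br$ssWithin),
                 tolerance = 1e-10)
    expect_equal(am$phi_st, br$phi, tolerance = 1e-10)
    # Phi_ST is invariant to rescaling all distances
    am2 <- amova(DistanceMatrix(3 * v), setNames(pop, lab),
                 nPermutations = 9, seed = seed)
    expect_equal(am2$phi_st, am$phi_st, tolerance = 1e-10)
  }
})

test_that("amova rejects degenerate designs", {
  z <- .zeroWithin()
  bad <- z$pop; bad["A2"] <- "p3"
  expect_error(amova(z$d, bad, 9, 1), "design error")
  lab <- names(z$pop)
  zero <- DistanceMatrix(matrix(0, 4, 4, dimnames = list(lab, lab)))
  expect_error(amova(zero, z$pop, 9, 1), "zero")
  expect_error(amova(z$d, z$pop[1:3], 9, 1), "mapped")
})

test_that("pcoa recovers planted geometry and reports axis shares", {
  set.seed(6)
  pts <- matrix(rnorm(10), 5, 2)
  rownames(pts) <- paste0("A", 1:5)
  v <- as.matrix(dist(pts))
  res <- pcoa(DistanceMatrix(v))
  expect_equal(ncol(res$coordinates), 2)
  expect_lt(procrustesRMS(pts, res$coordinates), 1e-8)
  expect_equal(sum(res$percentVar), 100, tolerance = 1e-9)
  expect_equal(res$cumulativePercent[2], 100, tolerance = 1e-9)
  if (requireNamespace("vegan", quietly = TRUE)) {
    ref <- ape::pcoa(as.dist(v))
    expect_equal(res$eigenvalues[1:2], ref$values$Eigenvalues[1:2],
                 tolerance = 1e-8)
  }

  # collinear points: exactly one positive eigenvalue
  line <- cbind(c(0, 1, 2, 3.5), 0)
  rownames(line) <- paste0("A", 1:4)
  vl <- as.matrix(dist(line))
  resl <- pcoa(DistanceMatrix(vl))
  expect_equal(ncol(resl$coordinates), 1)

  z <- DistanceMatrix(matrix(0, 3, 3, dimnames = list(paste0("A", 1:3),
                                                      paste0("A", 1:3))))
  rz <- pcoa(z)
  expect_true(all(abs(rz$eigenvalues) < 1e-12))
  expect_equal(ncol(rz$coordinates), 0)
})

test_that("mantel test: identity, affine invariance, oracle agreement, null", {
  D1 <- randomDistanceMatrix(24, seed = 31)
  m <- mantelTest(D1, D1, nPermutations = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p_value, 1 / 100, tolerance = 1e-12)

  v <- dmValues(D1)
  aff <- 2.5 * v + 0.3
  diag(aff) <- 0
  expect_equal(mantelTest(D1, DistanceMatrix(aff), 9, 1)$r, 1,
               tolerance = 1e-12)

  Da <- randomDistanceMatrix(24, seed = 61)
  D2 <- randomDistanceMatrix(24, seed = 62)
  mt <- mantelTest(Da, D2, nPermutations = 999, seed = 5)
  if (requireNamespace("vegan", quietly = TRUE)) {
    ref <- vegan::mantel(as.dist(dmValues(Da)), as.dist(dmValues(D2)),
                         permutations = 9)
    expect_equal(mt$r, unname(ref$statistic), tolerance = 1e-10)
  }
  expect_lt(mt$r^2, 0.1)
  expect_gt(mt$p_value, 0.05)

  # reproducible given the seed
  expect_identical(mt$p_value, mantelTest(Da, D2, 999, 5)$p_value)

  lab <- dmLabels(D1)
  flat <- DistanceMatrix(matrix(1, 24, 24, dimnames = list(lab, lab)) -
                         diag(24))
  expect_error(mantelTest(D1, flat, 9, 1), "zero off-diagonal variance")
})

test_that("evanno delta-K matches hand arithmetic and is scale-stable", {
  tab <- do.call(rbind, lapply(1:4, function(k)
    data.frame(K = k, run = 1:3,
               lnpd = c(-100, -80, -75, -74)[k] + c(-2, 0, 2))))
  dk <- evannoDeltaK(tab)
  expect_equal(dk$lprime[2:4], c(20, 5, 1))
  expect_equal(dk$abs_lsecond[3], 4)
  expect_equal(dk$delta_k[3], 2.0)   # sd(L(3)) = 2
  expect_true(is.na(dk$delta_k[1]) && is.na(dk$delta_k[4]))

  # exactly linear mean trajectory: all interior delta-K are 0
  lin <- do.call(rbind, lapply(1:5, function(k)
    data.frame(K = k, run = 1:3, lnpd = -10 * k + c(-1, 0, 1))))
  expect_equal(evannoDeltaK(lin)$delta_k[2:4], rep(0, 3))

  # adding a constant or rescaling leaves delta-K unchanged
  shift <- transform(tab, lnpd = lnpd + 500)
  expect_equal(evannoDeltaK(shift)$delta_k, dk$delta_k)
  scl <- transform(tab, lnpd = lnpd * 3)
  expect_equal(evannoDeltaK(scl)$delta_k, dk$delta_k)

  expect_error(evannoDeltaK(tab[tab$K < 3, ]), "consecutive")
  one <- do.call(rbind, lapply(1:3, function(k)
    data.frame(K = k, run = 1, lnpd = -k)))
  expect_error(evannoDeltaK(one), "runs")
})

test_that("amova permutation p-value flags planted structure and spares noise", {
  sim <- simulateDominantMarkers(rep(8, 4), nLoci = 60, fst = 0.25,
                                 seed = 13)
  am <- amova(bandMismatchDistance(sim$markers), sim$popmap,
              nPermutations = 199, seed = 13)
  expect_lt(am$p_value, 0.05)
  expect_gt(am$phi_st, 0.1)

  # random labels on the same matrix: no signal expected
  set.seed(14)
  noise <- setNames(sample(sim$popmap), names(sim$popmap))
  am0 <- amova(bandMismatchDistance(sim$markers), noise,
               nPermutations = 199, seed = 14)
  expect_gt(am0$p_value, 0.01)
})
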