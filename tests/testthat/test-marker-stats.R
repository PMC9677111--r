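test_that("band frequency is the presence proportion among scored accessions", {
  m <- matrix(0, 24, 2, dimnames = list(sprintf("A%02d", 1:24),
                                        c("P1.a", "P1.b")))
  m[1:12, 1] <- 1
  m[1:9, 2] <- 1
  x <- MarkerMatrix(m)
  expect_equal(bandFrequency(x, "P1.a"), 0.5)
  expect_equal(bandFrequency(x, "P1.b"), 9 / 24)

  m[, 2] <- 1
  expect_equal(bandFrequency(MarkerMatrix(m), "P1.b"), 1.0)
  m[, 2] <- NA
  expect_error(bandFrequency(MarkerMatrix(m), "P1.b"), "all-missing")
})

test_that("PIC modes match hand arithmetic and respect their bounds", {
  m <- matrix(0, 24, 2, dimnames = list(sprintf("A%02d", 1:24),
                                        c("P1.a", "P1.b")))
  m[1:9, 1] <- 1; m[10:24, 2] <- 1      # counts 9 and 15
  x <- MarkerMatrix(m)
  expect_equal(primerPIC(x, "P1"), 1 - (0.375^2 + 0.625^2))  # 0.46875

  m[, 1] <- 1; m[, 2] <- 0               # single expressed band
  expect_equal(primerPIC(MarkerMatrix(m), "P1"), 0)
  m[1:12, 2] <- 1; m[13:24, 1] <- 0      # equal counts
  expect_equal(primerPIC(MarkerMatrix(m), "P1"), 0.5)

  # per-band mode: mean of 1 - p^2 - (1-p)^2, bounded by 0.5
  m[] <- 0; m[1:6, 1] <- 1; m[1:12, 2] <- 1
  p <- c(0.25, 0.5)
  expect_equal(primerPIC(MarkerMatrix(m), "P1", mode = "per_band_mean"),
               mean(1 - p^2 - (1 - p)^2))
  for (seed in 1:20) {
    set.seed(seed)
    mm <- matrix(rbinom(48, 1, runif(1, 0.2, 0.8)), 24,
                 dimnames = list(sprintf("A%02d", 1:24),
                                 c("P1.a", "P1.b")))
    if (sum(mm) == 0) next
    x <- MarkerMatrix(mm)
    expect_lte(primerPIC(x, "P1"), 1 - 1 / 2)
    expect_lte(primerPIC(x, "P1", mode = "per_band_mean"), 0.5)
  }

  m[] <- 0
  expect_error(primerPIC(MarkerMatrix(m), "P1"), "zero presence")
})

test_that("resolving power: absolute mode is bounded, signed mode is 2p", {
  m <- matrix(0, 24, 1, dimnames = list(sprintf("A%02d", 1:24), "P1.a"))
  m[1:12, 1] <- 1
  expect_equal(resolvingPower(MarkerMatrix(m), "P1"), 1)
  m[, 1] <- 1
  expect_equal(resolvingPower(MarkerMatrix(m), "P1"), 0)
  expect_equal(resolvingPower(MarkerMatrix(m), "P1", mode = "signed"), 2)

  # two bands at p = 23/24 and 0.5: signed mode exceeds the absolute bound
  m2 <- matrix(0, 24, 2, dimnames = list(sprintf("A%02d", 1:24),
                                         c("P1.a", "P1.b")))
  m2[1:23, 1] <- 1; m2[1:12, 2] <- 1
  x <- MarkerMatrix(m2)
  expect_equal(resolvingPower(x, "P1", mode = "signed"),
               2 * 23 / 24 + 1, tolerance = 1e-12)
  expect_lte(resolvingPower(x, "P1", mode = "absolute"), 2)
})

test_that("EMR, MI and EMI compose as products of their parts", {
  x <- tinyMarkers()
  e <- effectiveMultiplexRatio(x, "P1")
  expect_equal(e$emr, 2)                  # 2 polymorphic of 2
  expect_equal(e$pp, 100)

  m <- matrix(0, 4, 2, dimnames = list(paste0("A", 1:4),
                                       c("P1.a", "P1.b")))
  m[, 1] <- 1; m[1:2, 2] <- 1             # band a monomorphic
  expect_equal(effectiveMultiplexRatio(MarkerMatrix(m), "P1")$emr, 0.5)
  m[, 2] <- 1
  expect_equal(effectiveMultiplexRatio(MarkerMatrix(m), "P1")$emr, 0)

  expect_equal(markerIndex(0.45, 2), 0.9)
  expect_equal(markerIndex(0, 2), 0)
  expect_equal(markerIndex(0.4, 0.5), 0.2)

  expect_equal(effectiveMarkerIndex(0.899, qm = 1)$emi, 0.674,
               tolerance = 5e-4)
  expect_equal(effectiveMarkerIndex(0, qm = 1)$emi, 0)
  expect_equal(effectiveMarkerIndex(1.0, qm = 0.5)$emi, 0.375)
  expect_equal(effectiveMarkerIndex(1.0, qm = 0.5)$qnd, 0.375)
  expect_error(effectiveMarkerIndex(1, qm = 0.1), "config error")
})

test_that("marker summary table keeps product identities and averages", {
  set.seed(9)
  sim <- simulateDominantMarkers(rep(4, 6), nLoci = 13, fst = 0.2,
                                 seed = 9)
  tab <- summarizeMarkers(sim$markers)
  per <- tab[tab$primer != "Average", ]
  avg <- tab[tab$primer == "Average", ]
  expect_equal(per$MI, per$EMR * per$PIC, tolerance = 1e-12)
  expect_equal(per$EMI, per$MI * 0.75 * 1 * 1, tolerance = 1e-12)
  expect_equal(per$PP, 100 * per$NPB / per$TNB)
  expect_equal(avg$PIC, mean(per$PIC))
  expect_equal(avg$EMI, mean(per$EMI))

  # permuting accession order changes nothing
  sc <- markerScores(sim$markers)
  perm <- MarkerMatrix(sc[sample(nrow(sc)), ])
  tab2 <- summarizeMarkers(perm)
  expect_equal(tab2$PIC, tab$PIC)
  expect_equal(tab2$RP, tab$RP)

  # a single monomorphic primer: everything zero
  m <- matrix(1, 4, 2, dimnames = list(paste0("A", 1:4),
                                       c("P1.a", "P1.b")))
  t0 <- summarizeMarkers(MarkerMatrix(m))
  expect_equal(t0$PP[1], 0)
  expect_equal(t0$MI[1], 0)
  expect_equal(t0$EMI[1], 0)

  # duplicated primer: averages equal the per-primer values
  m2 <- cbind(markerScores(tinyMarkers())[, 1:2],
              markerScores(tinyMarkers())[, 1:2])
  colnames(m2) <- c("P1.a", "P1.b", "P2.a", "P2.b")
  td <- summarizeMarkers(MarkerMatrix(m2))
  expect_equal(td$PIC[3], td$PIC[1])
  expect_equal(td$RP[3], td$RP[1])
})

test_that("bands with missing scores are dropped from primer statistics under the default policy", {
  m <- markerScores(tinyMarkers())
  m[1, "P2.b"] <- NA
  x <- MarkerMatrix(m)
  # P2 statistics now rest on band P2.a alone
  expect_equal(resolvingPower(x, "P2"),
               1 - 2 * abs(0.5 - mean(m[, "P2.a"])))
  expect_error(primerPIC(x, "P2", missingPolicy = "error"), "missing")
})
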