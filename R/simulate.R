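# Seeded generators producing inputs with known structure: dominant marker
# matrices under a Balding-Nichols island model with a chosen Fst, RCBD
# trait data with known variance components, chemotype tables with planted
# cluster structure, and a full study-shaped input bundle (24 accessions in
# 6 unequal ecotype populations, 13 two-band primers, 9 traits in 3 blocks,
# 4 diterpene compounds).

#' Simulate dominant marker data under an island model
#'
#' Per locus, an ancestral presence frequency `p0 ~ Uniform(0.1, 0.9)` is
#' drawn; each population's frequency follows the Balding-Nichols model
#' `p_pop ~ Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)` with `F = fst`; each
#' accession's band is Bernoulli(p_pop). Every locus is a primer with two
#' bands: in `"codominant"` banding (default) the second band is the
#' complement of the first, mimicking a biallelic locus scored as two
#' mutually exclusive gel bands; in `"independent"` banding the second band
#' gets its own frequency draw.
#'
#' @param popSizes integer vector of population sizes (one population each).
#' @param nLoci number of loci (primers).
#' @param fst differentiation parameter in `(0, 1)`.
#' @param banding `"codominant"` or `"independent"`.
#' @param seed integer seed.
#' @return list with `markers` ([MarkerMatrix-class]), `popmap` (named
#'   character), `truth` (list: `p0`, `pPop` — the drawn frequencies).
#' @export
simulateDominantMarkers <- function(popSizes, nLoci, fst,
                                    banding = c("codominant",
                                                "independent"),
                                    seed = 1L) {
  banding <- match.arg(banding)
  stopifnot(fst > 0, fst < 1, all(popSizes >= 1), nLoci >= 1)
  set.seed(seed)
  nPop <- length(popSizes)
  N <- sum(popSizes)
  popLab <- paste0("POP", seq_len(nPop))
  acc <- sprintf("AC%02d", seq_len(N))
  popOf <- rep(popLab, popSizes)
  nBandLoci <- if (banding == "independent") 2L * nLoci else nLoci
  p0 <- stats::runif(nBandLoci, 0.1, 0.9)
  shape <- (1 - fst) / fst
  pPop <- matrix(stats::rbeta(nPop * nBandLoci,
                              rep(p0 * shape, each = nPop),
                              rep((1 - p0) * shape, each = nPop)),
                 nrow = nPop)
  sc <- matrix(0, N, 2L * nLoci)
  primerIds <- sprintf("P%03d", seq_len(nLoci))
  colnames(sc) <- as.vector(rbind(paste0(primerIds, ".a"),
                                  paste0(primerIds, ".b")))
  rownames(sc) <- acc
  popIdx <- match(popOf, popLab)
  for (l in seq_len(nLoci)) {
    b1 <- stats::rbinom(N, 1L, pPop[popIdx, l])
    if (banding == "codominant") {
      b2 <- 1L - b1
    } else {
      b2 <- stats::rbinom(N, 1L, pPop[popIdx, nLoci + l])
    }
    sc[, 2L * l - 1L] <- b1
    sc[, 2L * l] <- b2
  }
  list(markers = MarkerMatrix(sc),
       popmap = stats::setNames(popOf, acc),
       truth = list(p0 = p0, pPop = pPop, fst = fst))
}

#' Simulate RCBD trait observations
#'
#' `Y_ij = mu + g_i + b_j + e_ij` with genotype effects
#' `g ~ N(0, sigma2_g)`, block effects `b ~ N(0, sigma2_b)` and plot errors
#' `e ~ N(0, sigma2_e)`, per trait.
#'
#' @param traitSpecs data.frame with columns `trait`, `mean`, `sigma2_g`,
#'   `sigma2_e` and optionally `sigma2_b` (default 0).
#' @param nGenotypes,nBlocks layout dimensions.
#' @param seed integer seed.
#' @return list with `traits` ([TraitTable-class]) and `truth` (the settings
#'   plus the drawn genotype effects per trait).
#' @export
simulateRcbdTraits <- function(traitSpecs, nGenotypes = 24L, nBlocks = 3L,
                               seed = 1L) {
  set.seed(seed)
  if (is.null(traitSpecs$sigma2_b)) traitSpecs$sigma2_b <- 0
  gen <- sprintf("G%03d", seq_len(nGenotypes))
  blk <- paste0("B", seq_len(nBlocks))
  gEff <- list()
  recs <- lapply(seq_len(nrow(traitSpecs)), function(i) {
    sp <- traitSpecs[i, ]
    g <- stats::rnorm(nGenotypes, 0, sqrt(sp$sigma2_g))
    b <- stats::rnorm(nBlocks, 0, sqrt(sp$sigma2_b))
    e <- stats::rnorm(nGenotypes * nBlocks, 0, sqrt(sp$sigma2_e))
    gEff[[sp$trait]] <<- g
    data.frame(genotype = rep(gen, times = nBlocks),
               block = rep(blk, each = nGenotypes),
               trait = sp$trait,
               value = sp$mean + rep(g, times = nBlocks) +
                 rep(b, each = nGenotypes) + e,
               stringsAsFactors = FALSE)
  })
  list(traits = TraitTable(do.call(rbind, recs)),
       truth = list(settings = traitSpecs, genotypeEffects = gEff))
}

#' Simulate chemotype (compound concentration) profiles
#'
#' Draws accessions around cluster mean vectors with independent Gaussian
#' noise; the planted cluster labels are returned as truth.
#'
#' @param clusterMeans cluster x compound numeric matrix of mean
#'   concentrations (rows are clusters; column names are compound names).
#' @param clusterSizes accessions per cluster.
#' @param noiseSd noise standard deviation (scalar or per compound).
#' @param seed integer seed.
#' @param labels optional accession labels.
#' @return list with `chem` (accession x compound matrix) and `truth`
#'   (named integer vector of planted cluster indices).
#' @export
simulateChemotypes <- function(clusterMeans, clusterSizes, noiseSd = 0.1,
                               seed = 1L, labels = NULL) {
  clusterMeans <- as.matrix(clusterMeans)
  k <- nrow(clusterMeans)
  stopifnot(length(clusterSizes) == k)
  if (k >= 2L && all(noiseSd == 0) &&
      all(apply(clusterMeans, 2L, function(v) length(unique(v))) == 1L))
    warning("degenerate settings: identical cluster means with zero noise")
  set.seed(seed)
  N <- sum(clusterSizes)
  if (is.null(labels)) labels <- sprintf("AC%02d", seq_len(N))
  noiseSd <- rep_len(noiseSd, ncol(clusterMeans))
  cl <- rep(seq_len(k), clusterSizes)
  chem <- clusterMeans[cl, , drop = FALSE] +
    matrix(stats::rnorm(N * ncol(clusterMeans), 0,
                        rep(noiseSd, each = N)), N)
  dimnames(chem) <- list(labels, colnames(clusterMeans))
  list(chem = chem, truth = stats::setNames(cl, labels))
}

# Per-trait generator settings for the study-shaped fixture: nine
# agro-morphological descriptors with means in realistic field units and
# variance components spanning low to high heritability, three blocks.
.fixtureTraitSpecs <- function() {
  data.frame(
    trait = c("DFF", "DM", "PH", "NNP", "NSBP", "LL", "LW", "IL", "DHY"),
    mean = c(95, 150, 65, 28, 22, 7.5, 2.4, 11, 38),
    sigma2_g = c(36, 4, 40, 6, 9, 0.05, 0.09, 1.2, 30),
    sigma2_e = c(5, 5, 18, 5, 5, 0.5, 0.05, 1.0, 22),
    sigma2_b = c(1, 1, 3, 0.5, 0.5, 0.05, 0.01, 0.2, 3),
    stringsAsFactors = FALSE)
}

#' Generate the study-shaped synthetic input bundle
#'
#' One seeded bundle with the shape of the kalmegh panel: 24 accessions
#' (AP1..AP24) in 6 ecotype populations of unequal size (8, 5, 4, 3, 2, 2),
#' 13 two-band primers (26 bands, codominant banding), 9 agro-morphological
#' traits in 3 RCBD blocks, 4 diterpene compounds (AG, NAG, DDAG, AN, % dry
#' weight) with two planted chemotype clusters, and an admixture
#' log-likelihood table (K = 1..10, 3 runs) with a planted peak at K = 2.
#' All files are plain delimited text in the formats the readers consume.
#'
#' @param dir output directory (created if needed); `NULL` returns the
#'   objects without writing files.
#' @param seed integer seed; the bundle is byte-identical for a given seed.
#' @return list with the generated objects (`markers`, `popmap`, `traits`,
#'   `chem`, `lnpd`, `truth`) and, when written, `paths`.
#' @export
makeStudyFixture <- function(dir = NULL, seed = 1L) {
  popSizes <- c(8L, 5L, 4L, 3L, 2L, 2L)
  sim <- simulateDominantMarkers(popSizes, nLoci = 13L, fst = 0.07,
                                 banding = "codominant", seed = seed)
  acc <- paste0("AP", seq_len(24L))
  sc <- markerScores(sim$markers)
  rownames(sc) <- acc
  markers <- MarkerMatrix(sc)
  ecotypes <- c("GP", "WG", "EG", "SPH", "WDR", "IR")
  popmap <- stats::setNames(rep(ecotypes, popSizes), acc)

  tr <- simulateRcbdTraits(.fixtureTraitSpecs(), nGenotypes = 24L,
                           nBlocks = 3L, seed = seed + 1L)
  td <- traitData(tr$traits)
  td$genotype <- acc[match(td$genotype, sprintf("G%03d", 1:24))]
  traits <- TraitTable(td)

  chemMeans <- rbind(c(AG = 2.6, NAG = 0.45, DDAG = 0.85, AN = 0.16),
                     c(AG = 1.3, NAG = 0.70, DDAG = 0.45, AN = 0.08))
  ch <- simulateChemotypes(chemMeans, clusterSizes = c(10L, 14L),
                           noiseSd = c(0.18, 0.07, 0.08, 0.02),
                           seed = seed + 2L, labels = acc)
  ch$chem[ch$chem < 0] <- 0

  set.seed(seed + 3L)
  ks <- 1:10
  muL <- c(-1250, -1080, -1072, -1068, -1066, -1065, -1064.5, -1064.2,
           -1064, -1063.9)
  lnpd <- do.call(rbind, lapply(seq_along(ks), function(i)
    data.frame(K = ks[i], run = 1:3,
               lnpd = muL[i] + stats::rnorm(3, 0, 3))))

  out <- list(markers = markers, popmap = popmap, traits = traits,
              chem = ch$chem, lnpd = lnpd,
              truth = list(markers = sim$truth, traits = tr$truth,
                           chem = ch$truth))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      markers = file.path(dir, "markers.csv"),
      popmap = file.path(dir, "popmap.csv"),
      traits = file.path(dir, "traits.csv"),
      chem = file.path(dir, "chem.csv"),
      lnpd = file.path(dir, "lnpd.csv"))
    utils::write.csv(data.frame(accession = acc, markerScores(markers),
                                check.names = FALSE),
                     paths$markers, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(accession = acc, population = popmap),
                     paths$popmap, row.names = FALSE, quote = FALSE)
    utils::write.csv(traitData(traits), paths$traits, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(accession = acc, ch$chem,
                                check.names = FALSE),
                     paths$chem, row.names = FALSE, quote = FALSE)
    utils::write.csv(lnpd, paths$lnpd, row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}
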