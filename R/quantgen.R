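# RCBD analysis of variance and the derived variability parameters
# (variance components, GCV/PCV, broad-sense heritability, genetic advance).
# The two-way model is Y_ij = mu + g_i + b_j + e_ij; genotypic variance is
# estimated as (MS_genotype - MS_error) / r with r blocks, heritability on a
# plot basis as sigma2_g / (sigma2_g + sigma2_e).

.traitCells <- function(tt, trait) {
  d <- traitData(tt)
  d <- d[d$trait == trait, ]
  if (!nrow(d)) stop("unknown trait '", trait, "'")
  d
}

#' RCBD analysis of variance for one trait
#'
#' Fits the additive genotype + block model with [stats::aov()] and returns
#' the genotype / block / error partition. The layout must be balanced
#' (every genotype in every block exactly once).
#'
#' @param tt a [TraitTable-class].
#' @param trait trait name.
#' @return list with `table` (data.frame: source, df, ss, ms), `fStat`
#'   (genotype F, `NA` when the error mean square is 0), `grandMean`,
#'   `nGenotypes`, `nBlocks`.
#' @export
rcbdAnova <- function(tt, trait) {
  d <- .traitCells(tt, trait)
  g <- factor(d$genotype)
  b <- factor(d$block)
  if (nlevels(g) < 2L || nlevels(b) < 2L)
    stop("design error: trait '", trait,
         "' needs >= 2 genotypes and >= 2 blocks")
  counts <- table(g, b)
  if (any(counts != 1L))
    stop("design error: trait '", trait, "' is unbalanced ",
         "(every genotype must appear once per block)")
  fit <- stats::aov(value ~ genotype + block,
                    data = data.frame(value = d$value, genotype = g,
                                      block = b))
  sm <- summary(fit)[[1L]]
  rn <- trimws(rownames(sm))
  tab <- data.frame(
    source = c("genotype", "block", "error"),
    df = sm[match(c("genotype", "block", "Residuals"), rn), "Df"],
    ss = sm[match(c("genotype", "block", "Residuals"), rn), "Sum Sq"],
    stringsAsFactors = FALSE)
  tab$ms <- tab$ss / tab$df
  # an error mean square at rounding-noise level makes F meaningless
  fStat <- if (tab$ms[3L] > 1e-12 * max(sum(tab$ss), 1))
    tab$ms[1L] / tab$ms[3L] else NA_real_
  list(table = tab, fStat = fStat, grandMean = mean(d$value),
       nGenotypes = nlevels(g), nBlocks = nlevels(b))
}

#' Variance components from an RCBD ANOVA
#'
#' `sigma2_e = MS_error`; `sigma2_g = (MS_genotype - MS_error) / r`,
#' truncated at 0 (with a warning) when the genotype mean square falls below
#' the error mean square.
#'
#' @param anova result of [rcbdAnova()].
#' @param nBlocks number of blocks r (defaults to the ANOVA's).
#' @return list with `sigma2_g`, `sigma2_e`.
#' @export
varianceComponents <- function(anova, nBlocks = anova$nBlocks) {
  msG <- anova$table$ms[anova$table$source == "genotype"]
  msE <- anova$table$ms[anova$table$source == "error"]
  s2g <- (msG - msE) / nBlocks
  if (s2g < 0) {
    warning("negative genotypic variance estimate truncated to 0")
    s2g <- 0
  }
  list(sigma2_g = s2g, sigma2_e = msE)
}

#' Variability parameters from variance components
#'
#' GCV and PCV are the genotypic and phenotypic standard deviations as a
#' percentage of the grand mean; broad-sense heritability is the genotypic
#' share of phenotypic variance (percent, plot basis); genetic advance is
#' `GA = k * sqrt(sigma2_p) * h2` with selection differential k (2.06 at 5%
#' selection intensity), and GAM expresses GA as percent of the mean.
#'
#' @param components list with `sigma2_g`, `sigma2_e` (see
#'   [varianceComponents()]).
#' @param grandMean trait grand mean, `> 0`.
#' @param kIntensity selection differential (default 2.06).
#' @return data.frame row with `sigma2_g`, `sigma2_e`, `sigma2_p`, `gcv`,
#'   `pcv`, `h2_broad` (all percentages where applicable), `ga` (trait
#'   units), `gam` (%), `k_intensity`.
#' @export
variabilityStats <- function(components, grandMean, kIntensity = 2.06) {
  if (grandMean <= 0) stop("domain error: grand mean must be positive")
  s2g <- components$sigma2_g
  s2e <- components$sigma2_e
  s2p <- s2g + s2e
  h2 <- if (s2p > 0) s2g / s2p else 0
  ga <- if (s2p > 0) kIntensity * sqrt(s2p) * h2 else 0
  data.frame(sigma2_g = s2g, sigma2_e = s2e, sigma2_p = s2p,
             gcv = 100 * sqrt(s2g) / grandMean,
             pcv = 100 * sqrt(s2p) / grandMean,
             h2_broad = 100 * h2, ga = ga, gam = 100 * ga / grandMean,
             k_intensity = kIntensity)
}

#' Per-trait variability table
#'
#' Runs [rcbdAnova()], [varianceComponents()] and [variabilityStats()] for
#' every trait in the table.
#'
#' @param tt a [TraitTable-class].
#' @param kIntensity selection differential (default 2.06).
#' @return data.frame, one row per trait, with the grand mean, F statistic
#'   and all variability parameters.
#' @export
analyzeVariability <- function(tt, kIntensity = 2.06) {
  trs <- unique(traitData(tt)$trait)
  do.call(rbind, lapply(trs, function(tr) {
    an <- rcbdAnova(tt, tr)
    vc <- varianceComponents(an)
    vs <- variabilityStats(vc, an$grandMean, kIntensity)
    cbind(data.frame(trait = tr, grand_mean = an$grandMean,
                     f_genotype = an$fStat, stringsAsFactors = FALSE), vs)
  }))
}

#' Genotype trait means in wide form
#'
#' Averages each genotype over blocks for every trait; the resulting
#' genotype x trait matrix feeds [traitDistance()] and [pcaTraits()].
#'
#' @param tt a [TraitTable-class].
#' @return numeric matrix, genotypes x traits.
#' @export
genotypeMeans <- function(tt) {
  d <- traitData(tt)
  tapply(d$value, list(d$genotype, d$trait), mean)
}
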