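# Informativeness statistics for dominant (presence/absence) fingerprints.
#
# Per primer: percent polymorphism, polymorphic information content (PIC),
# resolving power (Rp), effective multiplex ratio (EMR), marker index
# (MI = EMR * PIC) and effective marker index (EMI = MI * DC * QM * PR,
# where DC = 0.75 and PR = 1.0 are the standard constants for SSR bands and
# QM is the 0.25-1 marker-quality score).

.bandCols <- function(x, primer) {
  idx <- which(x@primers == primer)
  if (!length(idx)) stop("unknown primer '", primer, "'")
  idx
}

#' Band presence frequency
#'
#' Proportion of accessions carrying a band, among accessions where the band
#' was scored. The band-informativeness literature writes p as a count of
#' individuals, but the formulas it feeds only make sense for a proportion;
#' a proportion is used throughout.
#'
#' @param x a [MarkerMatrix-class].
#' @param band band label.
#' @return Presence proportion in `[0, 1]`.
#' @export
bandFrequency <- function(x, band) {
  v <- markerScores(x)[, band]
  n <- sum(!is.na(v))
  if (n == 0L) stop("undefined frequency: band '", band, "' is all-missing")
  sum(v, na.rm = TRUE) / n
}

.primerBandStats <- function(x, primer, missingPolicy = "drop_pairwise") {
  idx <- .bandCols(x, primer)
  sc <- markerScores(x)[, idx, drop = FALSE]
  hasMissing <- colSums(is.na(sc)) > 0L
  if (any(hasMissing) && missingPolicy == "error")
    stop("missing scores in primer '", primer, "' under missing_policy=error")
  keep <- !hasMissing
  if (!any(keep))
    stop("primer '", primer, "' has no fully scored band")
  sc <- sc[, keep, drop = FALSE]
  list(counts = colSums(sc),
       props = colMeans(sc),
       tnb = length(idx),
       scored = sum(keep))
}

#' Polymorphic information content of a primer
#'
#' `PIC = 1 - sum(fi^2)` over the primer's band frequencies. In
#' `"normalized_allele"` mode (default) the fi are band-presence counts
#' normalised to sum to one across the primer's bands, treating the bands as
#' an allele set; in `"per_band_mean"` mode each band contributes
#' `1 - p^2 - (1 - p)^2` with p its presence proportion, and the per-band
#' values are averaged.
#'
#' @param x a [MarkerMatrix-class].
#' @param primer primer identifier.
#' @param mode `"normalized_allele"` or `"per_band_mean"`.
#' @param missingPolicy `"drop_pairwise"` (exclude bands with missing
#'   scores) or `"error"`.
#' @return PIC in `[0, 1)`.
#' @export
primerPIC <- function(x, primer, mode = c("normalized_allele",
                                          "per_band_mean"),
                      missingPolicy = "drop_pairwise") {
  mode <- match.arg(mode)
  st <- .primerBandStats(x, primer, missingPolicy)
  if (mode == "normalized_allele") {
    tot <- sum(st$counts)
    if (tot == 0)
      stop("undefined PIC: primer '", primer, "' has zero presence counts")
    fi <- st$counts / tot
    1 - sum(fi^2)
  } else {
    mean(1 - st$props^2 - (1 - st$props)^2)
  }
}

#' Resolving power of a primer
#'
#' `Rp = sum(Ib)` over the primer's bands. In `"absolute"` mode (the
#' literature definition) `Ib = 1 - 2 * |0.5 - p|`, bounded by the band
#' count; `"signed"` mode drops the absolute value, `Ib = 1 - 2*(0.5 - p)
#' = 2p`, a variant that can exceed the absolute-mode bound and is provided
#' for comparability with published tables computed that way.
#'
#' @inheritParams primerPIC
#' @param mode `"absolute"` or `"signed"`.
#' @return Rp, `>= 0`.
#' @export
resolvingPower <- function(x, primer, mode = c("absolute", "signed"),
                           missingPolicy = "drop_pairwise") {
  mode <- match.arg(mode)
  st <- .primerBandStats(x, primer, missingPolicy)
  p <- st$props
  ib <- if (mode == "absolute") 1 - 2 * abs(0.5 - p) else 2 * p
  sum(ib)
}

#' Effective multiplex ratio of a primer
#'
#' `EMR = npb * (npb / tnb)` where npb counts polymorphic bands (presence
#' proportion strictly between 0 and 1) and tnb all the primer's bands.
#'
#' @inheritParams primerPIC
#' @return list with `emr`, `tnb`, `npb`, `pp` (percent polymorphism).
#' @export
effectiveMultiplexRatio <- function(x, primer,
                                    missingPolicy = "drop_pairwise") {
  st <- .primerBandStats(x, primer, missingPolicy)
  npb <- sum(st$props > 0 & st$props < 1)
  tnb <- st$tnb
  list(emr = npb * (npb / tnb), tnb = tnb, npb = npb,
       pp = 100 * npb / tnb)
}

#' Marker index
#'
#' @param pic polymorphic information content in `[0, 1]`.
#' @param emr effective multiplex ratio, `>= 0`.
#' @return `MI = EMR * PIC`.
#' @export
markerIndex <- function(pic, emr) {
  stopifnot(pic >= 0, pic <= 1, emr >= 0)
  emr * pic
}

#' Effective marker index
#'
#' `EMI = MI * DC * QM * PR`; the product `DC * QM * PR` is the qualitative
#' nature of the data (QND), reported alongside.
#'
#' @param mi marker index.
#' @param qm marker quality score in `[0.25, 1]`.
#' @param dc documentation capability constant (0.75 for SSR bands).
#' @param pr percent reproducibility constant (1.0 for SSR bands).
#' @return list with `emi` and `qnd`.
#' @export
effectiveMarkerIndex <- function(mi, qm = 1.0, dc = 0.75, pr = 1.0) {
  if (qm < 0.25 || qm > 1)
    stop("config error: qm must lie on the 0.25-1 scale")
  list(emi = mi * dc * qm * pr, qnd = dc * qm * pr)
}

#' Per-primer informativeness table with averages
#'
#' One row per primer with columns `TNB`, `NPB`, `PP`, `PIC`, `RP`, `EMR`,
#' `MI`, `QM`, `QND`, `EMI`, plus an `Average` row holding arithmetic means
#' over primers. Values are kept at full precision; round on display.
#'
#' @param x a [MarkerMatrix-class].
#' @param config a [RunConfig-class] supplying `qm`, `dc`, `pr` and the
#'   PIC / Rp modes.
#' @return data.frame with a `primer` column and an `Average` row.
#' @export
summarizeMarkers <- function(x, config = runConfig()) {
  prs <- primers(x)
  rows <- lapply(prs, function(pr) {
    e <- effectiveMultiplexRatio(x, pr, config@missingPolicy)
    pic <- primerPIC(x, pr, config@picMode, config@missingPolicy)
    rp <- resolvingPower(x, pr, config@rpMode, config@missingPolicy)
    mi <- markerIndex(pic, e$emr)
    em <- effectiveMarkerIndex(mi, config@qm, config@dc, config@pr)
    data.frame(primer = pr, TNB = e$tnb, NPB = e$npb, PP = e$pp,
               PIC = pic, RP = rp, EMR = e$emr, MI = mi, QM = config@qm,
               QND = em$qnd, EMI = em$emi, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(primer = "Average", TNB = mean(tab$TNB),
                    NPB = mean(tab$NPB), PP = mean(tab$PP),
                    PIC = mean(tab$PIC), RP = mean(tab$RP),
                    EMR = mean(tab$EMR), MI = mean(tab$MI),
                    QM = config@qm, QND = mean(tab$QND),
                    EMI = mean(tab$EMI), stringsAsFactors = FALSE)
  rbind(tab, avg)
}
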