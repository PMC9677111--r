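# Distance-based population genetics: one-level AMOVA with Phi-statistics
# and a permutation test, principal coordinate analysis, the Mantel test,
# and Evanno delta-K post-processing of admixture log-likelihood tables.

# Among/within sums of squares for a squared-distance matrix and a
# population assignment (integer codes); returns c(ssAmong, ssWithin).
.amovaSS <- function(d2, popCode, nPop) {
  N <- nrow(d2)
  ssTotal <- sum(d2) / (2 * N)
  ssWithin <- 0
  for (p in seq_len(nPop)) {
    idx <- which(popCode == p)
    ssWithin <- ssWithin +
      sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(ssTotal - ssWithin, ssWithin)
}

# phi here is the raw (untruncated) statistic: the permutation test needs a
# continuous statistic, otherwise truncation at 0 piles p-values at 1 under
# the null. Truncation to [0, 1] happens only in the reported result.
.phiFromSS <- function(ss, dfA, dfW, n0) {
  msA <- ss[1L] / dfA
  msW <- ss[2L] / dfW
  s2w <- msW
  s2a <- (msA - msW) / n0
  phi <- if (s2a + s2w != 0) s2a / (s2a + s2w) else NA_real_
  c(phi = phi, s2a = s2a, s2w = s2w, msA = msA, msW = msW)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise distances among and within populations:
#' `SS_total = sum_{i<j} d2_ij / N`, `SS_within = sum_pops sum_{i<j in pop}
#' d2_ij / n_pop`, `SS_among` by subtraction; variance components follow
#' from the mean squares with the average-sample-size coefficient
#' `n0 = (N - sum(n_p^2)/N) / (P - 1)`. `Phi_ST` is the among-population
#' share of molecular variance; its p-value comes from permuting individuals
#' among populations (sizes fixed) with the add-one rule
#' `(b + 1) / (m + 1)`.
#'
#' @param d a [DistanceMatrix-class]; its squared values are the molecular
#'   distances (use [bandMismatchDistance()] for binary markers, or a
#'   Jaccard-derived distance via [similarityToDistance()]).
#' @param popmap named character vector mapping every accession to its
#'   population; at least 2 populations with >= 2 members each.
#' @param nPermutations permutation count (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `table` (data.frame: source, df, ss, ms),
#'   `sigma2_among`, `sigma2_within` (negative among-component truncated to
#'   0 and flagged via `truncated`), `percent` (named, sums to 100),
#'   `phi_st`, `p_value`, `n_permutations`, `n0`.
#' @export
amova <- function(d, popmap, nPermutations = 999L, seed = 1L) {
  v <- dmValues(d)
  lab <- rownames(v)
  if (!all(lab %in% names(popmap)))
    stop("every accession must be mapped to a population; missing: ",
         paste(setdiff(lab, names(popmap)), collapse = ", "))
  pop <- factor(popmap[lab])
  sizes <- table(pop)
  if (nlevels(pop) < 2L || any(sizes < 2L))
    stop("design error: need >= 2 populations with >= 2 members each")
  d2 <- v^2
  if (all(d2 == 0))
    stop("all distances are zero: Phi_ST undefined")
  N <- length(lab)
  P <- nlevels(pop)
  dfA <- P - 1L
  dfW <- N - P
  n0 <- (N - sum(sizes^2) / N) / dfA
  code <- as.integer(pop)
  ss <- .amovaSS(d2, code, P)
  obs <- .phiFromSS(ss, dfA, dfW, n0)
  truncated <- obs["s2a"] < 0
  s2a <- max(obs[["s2a"]], 0)
  s2w <- obs[["s2w"]]
  set.seed(seed)
  b <- 0L
  for (r in seq_len(nPermutations)) {
    perm <- sample(code)
    phiP <- .phiFromSS(.amovaSS(d2, perm, P), dfA, dfW, n0)[["phi"]]
    if (!is.na(phiP) && phiP >= obs[["phi"]] - 1e-12) b <- b + 1L
  }
  pct <- 100 * c(among = s2a, within = s2w) / (s2a + s2w)
  list(table = data.frame(source = c("among populations",
                                     "within populations"),
                          df = c(dfA, dfW), ss = ss,
                          ms = c(obs[["msA"]], obs[["msW"]])),
       sigma2_among = s2a, sigma2_within = s2w, truncated = truncated,
       percent = pct, phi_st = max(obs[["phi"]], 0),
       p_value = (b + 1) / (nPermutations + 1),
       n_permutations = as.integer(nPermutations), n0 = n0)
}

#' Principal coordinate analysis (metric multidimensional scaling)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' percent-variance denominator. Axis signs are fixed by making the
#' largest-magnitude coordinate of each axis positive.
#'
#' @param d a [DistanceMatrix-class].
#' @return list with `coordinates` (accession x axis), `eigenvalues` (all,
#'   non-increasing), `percentVar` (over positive eigenvalues, sums to 100),
#'   `cumulativePercent`.
#' @export
pcoa <- function(d) {
  v <- dmValues(d)
  n <- nrow(v)
  A <- -0.5 * v^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1L], 0) * 1e-12 & ev > 0)
  if (!length(pos)) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(v), NULL))
    return(list(coordinates = coords, eigenvalues = ev,
                percentVar = numeric(0), cumulativePercent = numeric(0)))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), length(pos))
  flip <- apply(coords, 2L, function(x) sign(x[which.max(abs(x))]))
  flip[flip == 0] <- 1
  coords <- sweep(coords, 2L, flip, `*`)
  dimnames(coords) <- list(rownames(v), paste0("PCo", seq_along(pos)))
  pv <- 100 * ev[pos] / sum(ev[pos])
  list(coordinates = coords, eigenvalues = ev, percentVar = pv,
       cumulativePercent = cumsum(pv))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorised upper triangles; significance by
#' simultaneous row/column permutation of the second matrix, two-sided on r,
#' add-one rule. Matrices are aligned by label.
#'
#' @param d1,d2 [DistanceMatrix-class] objects on the same labels.
#' @param nPermutations permutation count (default 999).
#' @param seed integer seed.
#' @return list with `r`, `p_value`, `n_permutations`.
#' @export
mantelTest <- function(d1, d2, nPermutations = 999L, seed = 1L) {
  lab <- sort(dmLabels(d1))
  if (!setequal(lab, dmLabels(d2)))
    stop("alignment error: matrices have different labels")
  m1 <- dmValues(d1)[lab, lab]
  m2 <- dmValues(d2)[lab, lab]
  ut <- upper.tri(m1)
  if (stats::sd(m1[ut]) == 0 || stats::sd(m2[ut]) == 0)
    stop("undefined correlation: a matrix has zero off-diagonal variance")
  rObs <- stats::cor(m1[ut], m2[ut])
  set.seed(seed)
  b <- 0L
  n <- nrow(m1)
  for (i in seq_len(nPermutations)) {
    p <- sample.int(n)
    rP <- stats::cor(m1[ut], m2[p, p][ut])
    if (abs(rP) >= abs(rObs) - 1e-12) b <- b + 1L
  }
  list(r = rObs, p_value = (b + 1) / (nPermutations + 1),
       n_permutations = as.integer(nPermutations))
}

#' Evanno delta-K from admixture log-likelihoods
#'
#' For each K with replicate runs: mean and sd of Ln P(D), the first
#' difference `L'(K) = mean L(K) - mean L(K-1)`, the absolute second
#' difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `delta_K = |L''(K)| / sd(L(K))`, defined for interior K with positive sd.
#'
#' @param lnpd data.frame with columns `K`, `run`, `lnpd` (see
#'   [readLnPD()]); needs >= 3 consecutive K and >= 2 runs per K.
#' @return data.frame per K: `K`, `mean_lnpd`, `sd_lnpd`, `lprime`,
#'   `abs_lsecond`, `delta_k` (`NA` where undefined), plus attribute
#'   `"best_k"` (argmax of delta_k).
#' @export
evannoDeltaK <- function(lnpd) {
  ks <- sort(unique(lnpd$K))
  if (length(ks) < 3L || !all(diff(ks) == 1L))
    stop("need >= 3 consecutive K values")
  mu <- sapply(ks, function(k) mean(lnpd$lnpd[lnpd$K == k]))
  sd_ <- sapply(ks, function(k) stats::sd(lnpd$lnpd[lnpd$K == k]))
  if (anyNA(sd_)) stop("need >= 2 runs per K to estimate sd")
  lp <- c(NA, diff(mu))                       # L'(K), defined from 2nd K
  ls <- abs(c(NA, diff(lp[-1L]), NA))         # |L''(K)|, interior K only
  dk <- ls / sd_
  dk[sd_ == 0 & !is.na(ls)] <- NA_real_
  out <- data.frame(K = ks, mean_lnpd = mu, sd_lnpd = sd_, lprime = lp,
                    abs_lsecond = ls, delta_k = dk)
  if (any(!is.na(dk)))
    attr(out, "best_k") <- ks[which.max(dk)]
  out
}
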