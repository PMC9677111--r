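# Independent oracles and small fixture builders shared across tests.

# Random symmetric distance matrix with labelled rows.
randomDistanceMatrix <- function(n, seed) {
  set.seed(seed)
  p <- matrix(runif(n * 3), n)
  v <- as.matrix(dist(p))
  dimnames(v) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  DistanceMatrix(v)
}

# Naive UPGMA cophenetic oracle: at every step the between-cluster average
# distance is recomputed from the ORIGINAL matrix (no Lance-Williams
# recurrence), and the merge's average distance is recorded as the
# cophenetic distance of all cross pairs.
naiveUpgmaCophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  C <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        avg <- mean(D[clusters[[i]], clusters[[j]]])
        if (avg < bestd) { bestd <- avg; best <- c(i, j) }
      }
    }
    C[clusters[[best[1L]]], clusters[[best[2L]]]] <- bestd
    C[clusters[[best[2L]]], clusters[[best[1L]]]] <- bestd
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  C
}

# Per-pair set-arithmetic Jaccard oracle on a complete binary matrix.
bruteJaccard <- function(m) {
  n <- nrow(m)
  s <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pi <- which(m[i, ] == 1); pj <- which(m[j, ] == 1)
    s[i, j] <- length(intersect(pi, pj)) / length(union(pi, pj))
  }
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

# Brute-force one-level AMOVA on a squared-distance matrix: explicit
# pairwise-sum loops, no shared code with the package implementation.
bruteAmova <- function(d2, pop) {
  N <- nrow(d2)
  ssTot <- 0
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) ssTot <- ssTot + d2[i, j]
  ssTot <- ssTot / N
  ssW <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p); np <- length(idx); s <- 0
    if (np > 1L)
      for (a in seq_len(np - 1L)) for (b in (a + 1L):np)
        s <- s + d2[idx[a], idx[b]]
    ssW <- ssW + s / np
  }
  P <- length(unique(pop))
  sizes <- as.numeric(table(pop))
  msA <- (ssTot - ssW) / (P - 1)
  msW <- ssW / (N - P)
  n0 <- (N - sum(sizes^2) / N) / (P - 1)
  s2a <- max((msA - msW) / n0, 0)
  list(ssAmong = ssTot - ssW, ssWithin = ssW,
       phi = s2a / (s2a + msW))
}

# Pair-counting adjusted Rand index.
bruteARI <- function(p1, p2) {
  n <- length(p1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- p1[i] == p1[j]; b <- p2[i] == p2[j]
    if (a && b) n11 <- n11 + 1
    else if (!a && !b) n00 <- n00 + 1
    else if (a) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# RMS misfit after optimal orthogonal (rotation/reflection) alignment of
# the centred configurations, no scaling.
procrustesRMS <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Tiny marker matrix: 4 accessions, 2 primers x 2 bands.
tinyMarkers <- function() {
  m <- rbind(A1 = c(1, 0, 1, 1),
             A2 = c(1, 0, 0, 1),
             A3 = c(0, 1, 1, 0),
             A4 = c(1, 0, 1, 0))
  colnames(m) <- c("P1.a", "P1.b", "P2.a", "P2.b")
  MarkerMatrix(m)
}
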