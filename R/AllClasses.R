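#' @import methods
NULL

#' MarkerMatrix: binary band scores for a germplasm panel
#'
#' An accession x band matrix of dominant (presence/absence) marker scores.
#' Rows are accessions, columns are gel bands; each band belongs to exactly
#' one primer. Entries are 0 (band absent), 1 (band present) or `NA`
#' (not scored — e.g. a gel dropout); missing values are always explicit,
#' never silently treated as absence.
#'
#' @slot scores integer matrix in \{0, 1, NA\} with accession rownames and
#'   band colnames.
#' @slot primers character vector parallel to the columns giving the primer
#'   each band was amplified by.
#'
#' @seealso [MarkerMatrix()] for the validating constructor,
#'   [readMarkerMatrix()] for file input.
#' @export
setClass("MarkerMatrix",
  representation(scores = "matrix", primers = "character"))

setValidity("MarkerMatrix", function(object) {
  m <- object@scores
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "scores must be a numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    msg <- c(msg, "need at least 1 accession and 1 band")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "accession labels must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "band labels must be present and unique")
  bad <- !(m %in% c(0, 1)) & !is.na(m)
  if (any(bad)) msg <- c(msg, "scores must be 0, 1 or NA")
  if (length(object@primers) != ncol(m))
    msg <- c(msg, "primers must have one entry per band")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param scores numeric/integer matrix of 0/1/NA band scores with accession
#'   rownames and band colnames.
#' @param primers character vector assigning each band (column) to a primer.
#'   If omitted, primer identifiers are parsed from band names of the form
#'   `"PRIMER.suffix"`.
#' @return A validated [MarkerMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("P1.a", "P1.b")))
#' MarkerMatrix(m)
#' @export
MarkerMatrix <- function(scores, primers = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(primers)) {
    bn <- colnames(scores)
    if (is.null(bn))
      stop("band names are required to derive primer identifiers")
    primers <- sub("\\.[^.]*$", "", bn)
  }
  new("MarkerMatrix", scores = scores, primers = as.character(primers))
}

#' TraitTable: long-format RCBD trait observations
#'
#' Observations from a randomized complete block design: one record per
#' (genotype, block, trait) with a numeric value in trait units.
#'
#' @slot data data.frame with columns `genotype`, `block`, `trait`, `value`.
#' @slot units named character vector of measurement units per trait
#'   (may be empty).
#' @export
setClass("TraitTable",
  representation(data = "data.frame", units = "character"))

setValidity("TraitTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("genotype", "block", "trait", "value")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (!is.numeric(d$value)) msg <- c(msg, "value must be numeric")
  key <- paste(d$genotype, d$block, d$trait, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (genotype, block, trait) records")
  if (length(msg)) msg else TRUE
})

#' Construct a TraitTable
#'
#' @param data data.frame with columns `genotype`, `block`, `trait`, `value`.
#' @param units optional named character vector of units keyed by trait name.
#' @return A validated [TraitTable-class] object.
#' @export
TraitTable <- function(data, units = character()) {
  data <- as.data.frame(data)
  data$genotype <- as.character(data$genotype)
  data$block <- as.character(data$block)
  data$trait <- as.character(data$trait)
  data$value <- as.numeric(data$value)
  new("TraitTable", data = data[c("genotype", "block", "trait", "value")],
      units = units)
}

.checkSquare <- function(m, what, range01 = FALSE, unitDiag = FALSE) {
  msg <- character()
  if (!is.matrix(m) || nrow(m) != ncol(m))
    return(paste(what, "must be a square matrix"))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "row and column labels must be present and identical")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate labels")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    msg <- c(msg, paste(what, "must be symmetric"))
  if (range01) {
    if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "entries must lie in [0, 1]")
    if (unitDiag && any(abs(diag(m) - 1) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "diagonal must be 1")
  } else {
    if (any(m < -1e-12, na.rm = TRUE))
      msg <- c(msg, "entries must be non-negative")
    if (any(abs(diag(m)) > 1e-12))
      msg <- c(msg, "diagonal must be 0")
  }
  msg
}

#' DistanceMatrix: labelled symmetric distance matrix
#'
#' @slot values symmetric non-negative matrix with zero diagonal and
#'   identical row/column labels.
#' @export
setClass("DistanceMatrix", representation(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
  msg <- .checkSquare(object@values, "distance")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: labelled symmetric similarity matrix in [0, 1]
#'
#' @slot values symmetric matrix with entries in `[0, 1]` and unit diagonal.
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  msg <- .checkSquare(object@values, "similarity", range01 = TRUE,
                      unitDiag = TRUE)
  if (length(msg)) msg else TRUE
})

#' Construct a DistanceMatrix
#' @param values labelled square symmetric matrix, zero diagonal, `d >= 0`.
#' @return A validated [DistanceMatrix-class].
#' @export
DistanceMatrix <- function(values) {
  values <- as.matrix(values)
  values[abs(values) < 1e-15] <- 0
  new("DistanceMatrix", values = (values + t(values)) / 2)
}

#' Construct a SimilarityMatrix
#' @param values labelled square symmetric matrix with entries in `[0, 1]`.
#' @return A validated [SimilarityMatrix-class].
#' @export
SimilarityMatrix <- function(values) {
  values <- as.matrix(values)
  new("SimilarityMatrix", values = (values + t(values)) / 2)
}

#' Dendrogram: binary merge tree with heights
#'
#' Stores an agglomerative clustering result in `hclust` convention: row i of
#' `merge` gives the two children fused at `heights[i]`; negative entries are
#' leaf indices, positive entries earlier merges. Heights never decrease from
#' a child merge to its parent.
#'
#' @slot labels leaf (accession) labels.
#' @slot merge integer (n-1) x 2 merge matrix in `hclust` encoding.
#' @slot heights numeric merge heights, `>= 0`.
#' @export
setClass("Dendrogram",
  representation(labels = "character", merge = "matrix",
                 heights = "numeric"))

setValidity("Dendrogram", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate leaf labels")
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "need exactly n-1 merges for n leaves")
  if (length(object@heights) != n - 1L)
    msg <- c(msg, "need one height per merge")
  if (any(object@heights < -1e-12)) msg <- c(msg, "heights must be >= 0")
  h <- object@heights
  for (i in seq_len(nrow(object@merge))) {
    for (ch in object@merge[i, ]) {
      if (ch > 0 && h[ch] > h[i] + 1e-9)
        msg <- c(msg, "heights must be non-decreasing along root paths")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a Dendrogram
#' @param labels leaf labels.
#' @param merge `hclust`-style merge matrix.
#' @param heights merge heights.
#' @return A validated [Dendrogram-class].
#' @export
Dendrogram <- function(labels, merge, heights) {
  storage.mode(merge) <- "integer"
  new("Dendrogram", labels = as.character(labels), merge = merge,
      heights = as.numeric(heights))
}

#' RunConfig: analysis configuration
#'
#' Bundles the tunable constants and modes of the whole analysis. `qm`
#' (marker quality, scale 0.25-1), `dc` (documentation capability, constant
#' 0.75 for SSR bands) and `pr` (percent reproducibility, constant 1.0) feed
#' the effective marker index; the remaining fields select statistic variants
#' and control the stochastic operations.
#'
#' @slot qm marker quality score in `[0.25, 1]`.
#' @slot dc documentation capability constant (default 0.75).
#' @slot pr reproducibility constant (default 1.0).
#' @slot picMode `"normalized_allele"` or `"per_band_mean"`.
#' @slot rpMode `"absolute"` or `"signed"`.
#' @slot nPermutations permutation count for AMOVA and Mantel tests.
#' @slot seed integer seed used by every stochastic operation.
#' @slot linkage `"upgma"`, `"complete"` or `"ward"`.
#' @slot kRange integer vector of candidate cluster counts.
#' @slot fusionWeights non-negative weights for distance fusion.
#' @slot missingPolicy `"drop_pairwise"` or `"error"`.
#' @export
setClass("RunConfig",
  representation(qm = "numeric", dc = "numeric", pr = "numeric",
                 picMode = "character", rpMode = "character",
                 nPermutations = "integer", seed = "integer",
                 linkage = "character", kRange = "integer",
                 fusionWeights = "numeric", missingPolicy = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@qm < 0.25 || object@qm > 1)
    msg <- c(msg, "qm must lie in [0.25, 1]")
  if (!object@picMode %in% c("normalized_allele", "per_band_mean"))
    msg <- c(msg, "unknown picMode")
  if (!object@rpMode %in% c("absolute", "signed"))
    msg <- c(msg, "unknown rpMode")
  if (!object@linkage %in% c("upgma", "complete", "ward"))
    msg <- c(msg, "unknown linkage")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (any(object@fusionWeights < 0) || all(object@fusionWeights == 0))
    msg <- c(msg, "fusionWeights must be non-negative, not all zero")
  if (!object@missingPolicy %in% c("drop_pairwise", "error"))
    msg <- c(msg, "unknown missingPolicy")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param qm,dc,pr effective-marker-index constants (see [RunConfig-class]).
#' @param picMode,rpMode,linkage,missingPolicy statistic variants.
#' @param nPermutations,seed permutation count and master seed.
#' @param kRange candidate cluster counts for k selection and tree cuts.
#' @param fusionWeights weights for [fuseDistances()] in the joint analysis.
#' @return A validated [RunConfig-class].
#' @export
runConfig <- function(qm = 1.0, dc = 0.75, pr = 1.0,
                      picMode = "normalized_allele", rpMode = "absolute",
                      nPermutations = 999L, seed = 1L,
                      linkage = "upgma", kRange = 2:10,
                      fusionWeights = c(1, 1, 1),
                      missingPolicy = "drop_pairwise") {
  new("RunConfig", qm = qm, dc = dc, pr = pr, picMode = picMode,
      rpMode = rpMode, nPermutations = as.integer(nPermutations),
      seed = as.integer(seed), linkage = linkage,
      kRange = as.integer(kRange), fusionWeights = fusionWeights,
      missingPolicy = missingPolicy)
}
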