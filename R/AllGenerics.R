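#' Accessors for MarkerDiversity containers
#'
#' `accessions()`, `bands()`, `primers()` expose the labelling of a
#' [MarkerMatrix-class]; `markerScores()` its 0/1/NA matrix;
#' `dmLabels()` / `dmValues()` the labels and values of distance and
#' similarity matrices; `leafLabels()`, `mergeMatrix()` and `mergeHeights()`
#' the parts of a [Dendrogram-class].
#'
#' @param x a MarkerDiversity object.
#' @return The requested component (character vector, matrix or numeric
#'   vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))
#' @rdname accessors
#' @export
setGeneric("primers", function(x) standardGeneric("primers"))
#' @rdname accessors
#' @export
setGeneric("markerScores", function(x) standardGeneric("markerScores"))
#' @rdname accessors
#' @export
setGeneric("dmLabels", function(x) standardGeneric("dmLabels"))
#' @rdname accessors
#' @export
setGeneric("dmValues", function(x) standardGeneric("dmValues"))
#' @rdname accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname accessors
#' @export
setGeneric("mergeMatrix", function(x) standardGeneric("mergeMatrix"))
#' @rdname accessors
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))
#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @rdname accessors
setMethod("accessions", "MarkerMatrix", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("bands", "MarkerMatrix", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("primers", "MarkerMatrix", function(x) unique(x@primers))
#' @rdname accessors
setMethod("markerScores", "MarkerMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("traitData", "TraitTable", function(x) x@data)
#' @rdname accessors
setMethod("dmLabels", "DistanceMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("dmLabels", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("dmValues", "DistanceMatrix", function(x) x@values)
#' @rdname accessors
setMethod("dmValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("leafLabels", "Dendrogram", function(x) x@labels)
#' @rdname accessors
setMethod("mergeMatrix", "Dendrogram", function(x) x@merge)
#' @rdname accessors
setMethod("mergeHeights", "Dendrogram", function(x) x@heights)

setMethod("show", "MarkerMatrix", function(object) {
  cat("MarkerMatrix:", nrow(object@scores), "accessions x",
      ncol(object@scores), "bands (", length(unique(object@primers)),
      "primers )\n")
  cat("  missing cells:", sum(is.na(object@scores)), "\n")
})

setMethod("show", "TraitTable", function(object) {
  d <- object@data
  cat("TraitTable:", length(unique(d$genotype)), "genotypes x",
      length(unique(d$block)), "blocks,",
      length(unique(d$trait)), "traits,", nrow(d), "records\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix on", nrow(object@values), "labels; max off-diagonal",
      format(max(object@values), digits = 4), "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  off <- object@values[row(object@values) != col(object@values)]
  cat("SimilarityMatrix on", nrow(object@values), "labels; range",
      format(min(off), digits = 4), "-", format(max(off), digits = 4), "\n")
})

setMethod("show", "Dendrogram", function(object) {
  cat("Dendrogram with", length(object@labels), "leaves; root height",
      format(max(object@heights), digits = 6), "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: qm =", object@qm, "dc =", object@dc, "pr =", object@pr,
      "\n  picMode =", object@picMode, ", rpMode =", object@rpMode,
      ", linkage =", object@linkage,
      "\n  nPermutations =", object@nPermutations,
      ", seed =", object@seed, "\n")
})
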