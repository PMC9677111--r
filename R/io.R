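# Readers/writers for the delimited-text interchange formats. All I/O is
# UTF-8; the delimiter is auto-detected among comma and tab unless forced;
# labels are whitespace-trimmed and case-sensitive.

.detectSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) == 0L) stop("format error: empty file '", path, "'")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

.readDelim <- function(path, sep = NULL) {
  sep <- .detectSep(path, sep)
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"", comment.char = "",
                         fileEncoding = "UTF-8",
                         colClasses = "character")
  names(d) <- trimws(names(d))
  d
}

#' Read a binary band-scoring matrix
#'
#' First column: accession labels; remaining header fields: band identifiers,
#' by convention `"PRIMER.suffix"` so each band carries its primer. Cells
#' must be 0, 1 or the missing token. Anything else is rejected with its
#' coordinates.
#'
#' @param path delimited text file (comma or tab separated).
#' @param sep optional explicit separator; auto-detected by default.
#' @param missingToken string treated as a missing score (default `"NA"`;
#'   empty cells are missing too).
#' @param primerMap optional two-column file (band, primer) overriding the
#'   header-name convention.
#' @return A [MarkerMatrix-class].
#' @export
readMarkerMatrix <- function(path, sep = NULL, missingToken = "NA",
                             primerMap = NULL) {
  d <- .readDelim(path, sep)
  if (ncol(d) < 2L) stop("format error: no band columns in '", path, "'")
  acc <- trimws(d[[1L]])
  if (anyDuplicated(acc))
    stop("format error: duplicate accession labels: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  cells <- as.matrix(d[-1L])
  cells[] <- trimws(cells)
  vals <- matrix(NA_real_, nrow(cells), ncol(cells),
                 dimnames = list(acc, colnames(cells)))
  ok <- matrix(cells %in% c("0", "1"), nrow(cells))
  vals[ok] <- as.numeric(cells[ok])
  miss <- matrix(is.na(cells) | cells %in% c(missingToken, "", "NA"),
                 nrow(cells))
  bad <- !ok & !miss
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("format error: cell '", cells[bad][1L], "' at accession '",
         acc[idx[1L]], "', band '", colnames(cells)[idx[2L]],
         "' is not 0/1/", missingToken)
  }
  primers <- NULL
  if (!is.null(primerMap)) {
    pm <- .readDelim(primerMap)
    primers <- trimws(pm[[2L]])[match(colnames(vals), trimws(pm[[1L]]))]
    if (anyNA(primers))
      stop("format error: primer map misses bands: ",
           paste(colnames(vals)[is.na(primers)], collapse = ", "))
  }
  MarkerMatrix(vals, primers = primers)
}

#' Read an RCBD trait table
#'
#' Accepts the long layout (columns `genotype`, `block`, `trait`, `value`) or
#' a wide layout (columns `genotype`, `block`, one column per trait), which
#' is melted to long form.
#'
#' @param path delimited text file.
#' @param sep optional explicit separator.
#' @param units optional named character vector of trait units.
#' @return A [TraitTable-class].
#' @export
readTraitTable <- function(path, sep = NULL, units = character()) {
  d <- .readDelim(path, sep)
  for (col in c("genotype", "block"))
    if (!col %in% names(d))
      stop("format error: required column '", col, "' missing in '",
           path, "'")
  if (all(c("trait", "value") %in% names(d))) {
    long <- d[c("genotype", "block", "trait", "value")]
  } else {
    traitCols <- setdiff(names(d), c("genotype", "block"))
    if (!length(traitCols))
      stop("format error: no trait columns in '", path, "'")
    long <- do.call(rbind, lapply(traitCols, function(tr)
      data.frame(genotype = d$genotype, block = d$block, trait = tr,
                 value = d[[tr]], stringsAsFactors = FALSE)))
  }
  suppressWarnings(v <- as.numeric(long$value))
  if (anyNA(v) && !all(is.na(v) == (trimws(long$value) %in% c("", "NA")))) {
    bad <- which(is.na(v) & !trimws(long$value) %in% c("", "NA"))[1L]
    stop("format error: non-numeric value '", long$value[bad],
         "' for genotype '", long$genotype[bad], "', trait '",
         long$trait[bad], "'")
  }
  long$value <- v
  long <- long[!is.na(long$value), ]
  TraitTable(long, units = units)
}

#' Read an accession-to-population map
#'
#' @param path two-column delimited file: accession label, population label.
#' @param sep optional explicit separator.
#' @return Named character vector mapping accession to population.
#' @export
readPopulationMap <- function(path, sep = NULL) {
  d <- .readDelim(path, sep)
  if (ncol(d) < 2L) stop("format error: population map needs 2 columns")
  acc <- trimws(d[[1L]])
  if (anyDuplicated(acc))
    stop("format error: duplicate accessions in population map")
  stats::setNames(trimws(d[[2L]]), acc)
}

#' Read an admixture log-likelihood table
#'
#' @param path 3-column delimited file with columns `K`, `run`, `lnpd`
#'   (log-probability of the data for each admixture run).
#' @param sep optional explicit separator.
#' @return data.frame with integer `K`, `run` and numeric `lnpd`.
#' @export
readLnPD <- function(path, sep = NULL) {
  d <- .readDelim(path, sep)
  need <- c("K", "run", "lnpd")
  if (!all(need %in% names(d)))
    stop("format error: log-likelihood table needs columns K, run, lnpd")
  data.frame(K = as.integer(d$K), run = as.integer(d$run),
             lnpd = as.numeric(d$lnpd))
}

#' Write / read a labelled square distance matrix
#'
#' Full square layout with a leading label column; symmetry is re-validated
#' on read (tolerance 1e-8).
#'
#' @param x a [DistanceMatrix-class] (or [SimilarityMatrix-class]) to write.
#' @param path file path.
#' @param digits significant digits written (default 12).
#' @return `writeSquareDistance()` returns `path` invisibly;
#'   `readSquareDistance()` returns a [DistanceMatrix-class].
#' @export
writeSquareDistance <- function(x, path, digits = 12) {
  v <- dmValues(x)
  out <- cbind(label = rownames(v),
               as.data.frame(signif(v, digits), check.names = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeSquareDistance
#' @param sep optional explicit separator.
#' @export
readSquareDistance <- function(path, sep = NULL) {
  d <- .readDelim(path, sep)
  lab <- trimws(d[[1L]])
  m <- as.matrix(d[-1L])
  storage.mode(m) <- "double"
  dimnames(m) <- list(lab, trimws(colnames(m)))
  if (!identical(rownames(m), colnames(m)))
    stop("format error: row and column labels disagree in '", path, "'")
  if (max(abs(m - t(m))) > 1e-8)
    stop("format error: matrix in '", path, "' is asymmetric beyond 1e-8")
  DistanceMatrix(m)
}

# ---- Newick ----------------------------------------------------------------

.nodeChildren <- function(dend, i) dend@merge[i, ]

#' Serialize a Dendrogram to Newick
#'
#' Branch lengths are parent height minus child height (leaves sit at depth
#' equal to their merge height), so an ultrametric tree round-trips through
#' [readNewick()] within 1e-9.
#'
#' @param dend a [Dendrogram-class].
#' @param path file path; when `NULL`, the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
writeNewick <- function(dend, path = NULL) {
  h <- mergeHeights(dend)
  m <- mergeMatrix(dend)
  fmt <- function(x) sprintf("%.17g", x)
  rec <- function(node, parentH) {
    if (node < 0) {
      paste0(leafLabels(dend)[-node], ":", fmt(parentH))
    } else {
      bl <- parentH - h[node]
      if (bl < -1e-9)
        stop("serialization error: negative branch length at merge ", node)
      paste0("(", rec(m[node, 1L], h[node]), ",",
             rec(m[node, 2L], h[node]), "):", fmt(max(bl, 0)))
    }
  }
  root <- nrow(m)
  if (root == 0L) stop("cannot serialize a single-leaf tree")
  s <- paste0("(", rec(m[root, 1L], h[root]), ",",
              rec(m[root, 2L], h[root]), ");")
  if (!is.null(path)) {
    writeLines(s, path, useBytes = TRUE)
    return(invisible(s))
  }
  s
}

#' Parse a Newick file into a Dendrogram
#'
#' Uses \pkg{ape} to parse, then converts the (ultrametric, rooted, binary)
#' tree back into merge-list form.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text optional Newick string overriding `path`.
#' @return A [Dendrogram-class].
#' @export
readNewick <- function(path = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  hc <- ape::as.hclust.phylo(phy)
  # ape doubles node depths on conversion (hclust trees place leaves at
  # half the merge height); undo to recover this package's height scale
  Dendrogram(hc$labels, hc$merge, hc$height / 2)
}

#' Read a flat YAML run configuration
#'
#' Flat key: value file mirroring [runConfig()]'s arguments (keys in
#' snake_case: `qm`, `dc`, `pr`, `pic_mode`, `rp_mode`, `n_permutations`,
#' `seed`, `linkage`, `k_range` as `[lo, hi]`, `fusion_weights`,
#' `missing_policy`).
#'
#' @param path YAML file.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  map <- c(qm = "qm", dc = "dc", pr = "pr", pic_mode = "picMode",
           rp_mode = "rpMode", n_permutations = "nPermutations",
           seed = "seed", linkage = "linkage",
           fusion_weights = "fusionWeights", missing_policy = "missingPolicy")
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[[k]]]] <- y[[k]]
  if (!is.null(y$k_range)) {
    kr <- as.integer(y$k_range)
    args$kRange <- if (length(kr) == 2L) seq(kr[1L], kr[2L]) else kr
  }
  do.call(runConfig, args)
}
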