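# End-to-end orchestration: markers -> informativeness + Jaccard/UPGMA/
# AMOVA/PCoA; traits -> ANOVA/variability/PCA/k-means/hierarchical; chem ->
# clustering; Mantel between chem and marker distances; delta-K; joint
# fused-distance clustering. Every stage writes plain-text artifacts under
# the run directory and is recorded in a JSON manifest.

.writeCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

.asMatrixInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full diversity analysis
#'
#' Executes every stage whose inputs are present: marker informativeness,
#' Jaccard similarity and UPGMA tree, band-mismatch AMOVA and PCoA (popmap
#' required), RCBD variability and trait clustering (hierarchical, k-means,
#' PCA), chemotype clustering, Mantel test between the chemotype and marker
#' distances, Evanno delta-K, and — when at least two distance matrices
#' exist — joint clustering of the fused distances. Missing inputs skip
#' their stages (logged in the manifest). All randomness is seeded from the
#' config.
#'
#' @param outDir run directory (created).
#' @param markers [MarkerMatrix-class] or path for [readMarkerMatrix()].
#' @param popmap named character vector or path for [readPopulationMap()].
#' @param traits [TraitTable-class] or path for [readTraitTable()].
#' @param chem accession x compound matrix or path to a CSV with an
#'   `accession` first column.
#' @param lnpd data.frame or path for [readLnPD()].
#' @param config a [RunConfig-class].
#' @param cutK named integer vector of report cut levels for the
#'   `marker`, `agro`, `chem` and `joint` trees.
#' @return The manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
runDiversityAnalysis <- function(outDir, markers = NULL, popmap = NULL,
                                 traits = NULL, chem = NULL, lnpd = NULL,
                                 config = runConfig(),
                                 cutK = c(marker = 2L, agro = 3L,
                                          chem = 2L, joint = 2L)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(markers) && is.null(traits) && is.null(chem))
    stop("at least one of markers, traits, chem is required")
  markers <- if (!is.null(markers))
    .asMatrixInput(markers, readMarkerMatrix)
  traits <- if (!is.null(traits)) .asMatrixInput(traits, readTraitTable)
  popmap <- if (!is.null(popmap)) .asMatrixInput(popmap, readPopulationMap)
  lnpd <- if (!is.null(lnpd)) .asMatrixInput(lnpd, readLnPD)
  if (is.character(chem) && length(chem) == 1L) {
    d <- .readDelim(chem)
    chem <- as.matrix(d[-1L])
    storage.mode(chem) <- "double"
    rownames(chem) <- trimws(d[[1L]])
  }

  sets <- list()
  if (!is.null(markers)) sets$markers <- accessions(markers)
  if (!is.null(traits)) sets$traits <- unique(traitData(traits)$genotype)
  if (!is.null(chem)) sets$chem <- rownames(chem)
  if (length(sets) > 1L) {
    ref <- sets[[1L]]
    for (nm in names(sets)[-1L])
      if (!setequal(ref, sets[[nm]]))
        stop("alignment error: accession sets differ between '",
             names(sets)[1L], "' and '", nm, "': ",
             paste(union(setdiff(ref, sets[[nm]]),
                         setdiff(sets[[nm]], ref)), collapse = ", "))
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("MarkerDiversity")),
                   seed = config@seed,
                   config = list(qm = config@qm, dc = config@dc,
                                 pr = config@pr, pic_mode = config@picMode,
                                 rp_mode = config@rpMode,
                                 n_permutations = config@nPermutations,
                                 linkage = config@linkage,
                                 missing_policy = config@missingPolicy,
                                 trait_standardization = "population (n)"),
                   outputs = list(), results = list(),
                   skipped = character(), warnings = character())
  dists <- list()

  if (!is.null(markers)) {
    mk <- summarizeMarkers(markers, config)
    manifest$outputs$marker_stats <-
      .writeCsv(mk, file.path(outDir, "marker_stats.csv"))
    sim <- jaccardSimilarity(markers)
    jd <- similarityToDistance(sim)
    dists$markers <- jd
    manifest$outputs$jaccard_distance <-
      writeSquareDistance(jd, file.path(outDir, "jaccard_distance.csv"))
    tre <- upgma(jd)
    manifest$outputs$marker_tree <- file.path(outDir, "marker_upgma.nwk")
    writeNewick(tre, manifest$outputs$marker_tree)
    part <- cutDendrogram(tre, cutK[["marker"]])
    manifest$outputs$marker_partition <-
      .writeCsv(data.frame(accession = names(part), cluster = part),
                file.path(outDir, "marker_partition.csv"))
    manifest$results$jaccard_min_similarity <-
      min(dmValues(sim)[upper.tri(dmValues(sim))])
    if (!is.null(popmap)) {
      am <- amova(bandMismatchDistance(markers), popmap,
                  config@nPermutations, config@seed)
      manifest$outputs$amova <-
        .writeCsv(cbind(am$table,
                        percent = c(am$percent),
                        phi_st = c(am$phi_st, NA),
                        p_value = c(am$p_value, NA)),
                  file.path(outDir, "amova.csv"))
      manifest$results$amova_percent <- as.list(am$percent)
      manifest$results$phi_st <- am$phi_st
      manifest$results$amova_p <- am$p_value
      pc <- pcoa(bandMismatchDistance(markers))
      manifest$outputs$pcoa <-
        .writeCsv(data.frame(accession = rownames(pc$coordinates),
                             pc$coordinates, check.names = FALSE),
                  file.path(outDir, "pcoa_coordinates.csv"))
      manifest$results$pcoa_percent <-
        pc$percentVar[seq_len(min(3L, length(pc$percentVar)))]
    } else {
      manifest$skipped <- c(manifest$skipped,
                            "amova/pcoa (no population map)")
    }
  } else manifest$skipped <- c(manifest$skipped, "marker stages (no input)")

  if (!is.null(traits)) {
    vs <- analyzeVariability(traits)
    manifest$outputs$variability <-
      .writeCsv(vs, file.path(outDir, "variability.csv"))
    gm <- genotypeMeans(traits)
    dists$agro <- traitDistance(gm)
    tre <- hierarchicalCluster(dists$agro,
                               if (config@linkage == "upgma") "complete"
                               else config@linkage)
    manifest$outputs$agro_tree <- file.path(outDir, "agro_tree.nwk")
    writeNewick(tre, manifest$outputs$agro_tree)
    part <- cutDendrogram(tre, cutK[["agro"]])
    manifest$outputs$agro_partition <-
      .writeCsv(data.frame(accession = names(part), cluster = part),
                file.path(outDir, "agro_partition.csv"))
    z <- scale(gm)
    km <- kmeansSelect(z, config@kRange, seed = config@seed)
    manifest$outputs$agro_silhouette <-
      .writeCsv(km$silhouette, file.path(outDir, "agro_silhouette.csv"))
    manifest$results$agro_kmeans_k <- km$k
    pca <- pcaTraits(gm)
    manifest$outputs$agro_pca <-
      .writeCsv(data.frame(component = seq_along(pca$percentVar),
                           eigenvalue = pca$eigenvalues,
                           percent_var = pca$percentVar),
                file.path(outDir, "agro_pca_variance.csv"))
    manifest$results$agro_pc12_percent <- sum(pca$percentVar[1:2])
  } else manifest$skipped <- c(manifest$skipped, "trait stages (no input)")

  if (!is.null(chem)) {
    dists$chem <- traitDistance(chem)
    tre <- hierarchicalCluster(dists$chem,
                               if (config@linkage == "upgma") "complete"
                               else config@linkage)
    manifest$outputs$chem_tree <- file.path(outDir, "chem_tree.nwk")
    writeNewick(tre, manifest$outputs$chem_tree)
    part <- cutDendrogram(tre, cutK[["chem"]])
    manifest$outputs$chem_partition <-
      .writeCsv(data.frame(accession = names(part), cluster = part),
                file.path(outDir, "chem_partition.csv"))
    km <- kmeansSelect(scale(chem), config@kRange, seed = config@seed)
    manifest$results$chem_kmeans_k <- km$k
    pca <- pcaTraits(chem)
    manifest$results$chem_pc12_percent <- sum(pca$percentVar[1:2])
  } else manifest$skipped <- c(manifest$skipped, "chem stages (no input)")

  if (!is.null(dists$chem) && !is.null(dists$markers)) {
    mt <- mantelTest(dists$chem, dists$markers, config@nPermutations,
                     config@seed)
    manifest$results$mantel_r <- mt$r
    manifest$results$mantel_r2 <- mt$r^2
    manifest$results$mantel_p <- mt$p_value
  } else manifest$skipped <- c(manifest$skipped,
                               "mantel (needs chem + markers)")

  if (!is.null(lnpd)) {
    dk <- evannoDeltaK(lnpd)
    manifest$outputs$delta_k <-
      .writeCsv(dk, file.path(outDir, "delta_k.csv"))
    manifest$results$best_k <- attr(dk, "best_k")
  } else manifest$skipped <- c(manifest$skipped, "delta-k (no input)")

  if (length(dists) >= 2L) {
    w <- rep_len(config@fusionWeights, length(dists))
    fused <- fuseDistances(unname(dists), w)
    tre <- upgma(fused)
    manifest$outputs$joint_tree <- file.path(outDir, "joint_tree.nwk")
    writeNewick(tre, manifest$outputs$joint_tree)
    part <- cutDendrogram(tre, cutK[["joint"]])
    manifest$outputs$joint_partition <-
      .writeCsv(data.frame(accession = names(part), cluster = part),
                file.path(outDir, "joint_partition.csv"))
    manifest$results$joint_fused <- names(dists)
  } else manifest$skipped <- c(manifest$skipped,
                               "joint clustering (needs >= 2 distances)")

  manifest$digests <- as.list(tools::md5sum(
    unlist(manifest$outputs, use.names = FALSE)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a human-readable run summary
#'
#' @param manifest result of [runDiversityAnalysis()].
#' @param path optional file to write the markdown summary to.
#' @return Character vector of markdown lines (invisibly when written).
#' @export
reportRun <- function(manifest, path = NULL) {
  ln <- c("# Diversity analysis report", "")
  res <- manifest$results
  if (!is.null(manifest$outputs$marker_stats)) {
    mk <- utils::read.csv(manifest$outputs$marker_stats)
    ln <- c(ln, "## Marker informativeness", "",
            paste(utils::capture.output(print(
              cbind(mk[1], round(mk[-1], 3)), row.names = FALSE)),
              collapse = "\n"), "")
  }
  if (!is.null(manifest$outputs$variability)) {
    vs <- utils::read.csv(manifest$outputs$variability)
    ln <- c(ln, "## Trait variability", "",
            paste(utils::capture.output(print(
              cbind(vs[1], round(vs[-1], 2)), row.names = FALSE)),
              collapse = "\n"), "")
  }
  if (!is.null(res$amova_percent))
    ln <- c(ln, "## AMOVA", "",
            sprintf("- among populations: %.1f%%, within: %.1f%%",
                    res$amova_percent$among, res$amova_percent$within),
            sprintf("- Phi_ST = %.4f (p = %.4g)", res$phi_st,
                    res$amova_p), "")
  if (!is.null(res$pcoa_percent))
    ln <- c(ln, sprintf("- PCoA axes 1-3: %s%%",
                        paste(sprintf("%.2f", res$pcoa_percent),
                              collapse = " / ")), "")
  if (!is.null(res$mantel_r))
    ln <- c(ln, "## Mantel test", "",
            sprintf("- r = %.4f (R^2 = %.4f), p = %.4g", res$mantel_r,
                    res$mantel_r2, res$mantel_p), "")
  if (!is.null(res$best_k))
    ln <- c(ln, sprintf("- delta-K optimum: K = %d", res$best_k), "")
  for (nm in intersect(c("marker_partition", "agro_partition",
                         "chem_partition", "joint_partition"),
                       names(manifest$outputs))) {
    pt <- utils::read.csv(manifest$outputs[[nm]])
    ln <- c(ln, sprintf("## %s (k = %d)", nm, max(pt$cluster)), "",
            vapply(sort(unique(pt$cluster)), function(k)
              sprintf("- cluster %d: %s", k,
                      paste(pt$accession[pt$cluster == k],
                            collapse = ", ")), ""), "")
  }
  if (length(manifest$skipped))
    ln <- c(ln, "## Skipped stages", "",
            paste0("- ", manifest$skipped), "")
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
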