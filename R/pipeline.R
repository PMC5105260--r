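#' Run the full diversity analysis over several libraries
#'
#' Convenience wrapper chaining the whole pipeline for a set of curated
#' libraries: chemotype tabulation, scaffold summary (with SSE grid),
#' intra-library fingerprint similarity, per-molecule properties and the
#' pooled-scaled set-distance matrix. The pieces feed [assembleCDP()]
#' directly.
#'
#' @param sets List of curated [CompoundSet-class] objects (e.g. from
#'   [loadLibrary()]).
#' @param fingerprint Fingerprint kind for the similarity summaries.
#' @param sseGrid Integer grid of top-n values for the SSE columns.
#' @param scale Pooled z-scoring before property distances (see
#'   [standardizeProperties()]).
#' @param keepExocyclic Passed to [extractChemotype()].
#' @return List with elements `tables` (ChemotypeTables), `scaffold`
#'   (data.frame incl. `sse<n>` columns), `similarity` (data.frame),
#'   `properties` (list of per-molecule data.frames), `distances`
#'   (set-distance matrix), `intraDistances` (named diagonal).
#' @export
analyzeLibraries <- function(sets, fingerprint = c("maccs166", "ecfp4"),
                             sseGrid = seq(5L, 70L, by = 5L),
                             scale = TRUE, keepExocyclic = FALSE) {
  fingerprint <- match.arg(fingerprint)
  stopifnot(is.list(sets), length(sets) >= 1)
  nm <- vapply(sets, setName, character(1))
  names(sets) <- nm
  tables <- lapply(sets, tabulateChemotypes, keepExocyclic = keepExocyclic)
  scaffold <- do.call(rbind, lapply(tables, function(tab) {
    s <- summarizeScaffolds(tab)
    sse <- vapply(sseGrid, function(k) scaledShannonEntropy(tab, k)$sse,
                  numeric(1))
    names(sse) <- sprintf("sse%d", sseGrid)
    cbind(s, as.data.frame(as.list(sse)))
  }))
  rownames(scaffold) <- NULL
  similarity <- do.call(rbind, lapply(sets, intraSimilaritySummary,
                                      kind = fingerprint))
  rownames(similarity) <- NULL
  properties <- lapply(sets, computeProperties)
  mats <- lapply(properties, propertyMatrix)
  distances <- setDistanceMatrix(mats, scale = scale)
  list(tables = tables, scaffold = scaffold, similarity = similarity,
       properties = properties, distances = distances,
       intraDistances = diag(distances))
}

#' Build classified consensus records from an analysis
#'
#' @param analysis Result of [analyzeLibraries()].
#' @param yMetric Scaffold metric for the y axis (`"auc"`, `"f50"`, or an
#'   `sse<n>` column name).
#' @param xThreshold,yThreshold Passed to [resolveThresholds()].
#' @return List with `records` (classified) and `thresholds`.
#' @export
consensusRecords <- function(analysis, yMetric = "auc",
                             xThreshold = "median",
                             yThreshold = if (yMetric == "auc") 0.75
                                          else "median") {
  records <- assembleCDP(analysis$scaffold, analysis$similarity,
                         analysis$intraDistances, yMetric = yMetric)
  thresholds <- resolveThresholds(records, xThreshold = xThreshold,
                                  yThreshold = yThreshold)
  list(records = classifyQuadrants(records, thresholds),
       thresholds = thresholds)
}
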