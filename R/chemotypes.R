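#' Chemotype (scaffold) sentinel for ring-free molecules
#'
#' All acyclic molecules in a library share this single chemotype key, so a
#' library dominated by open-chain compounds collapses onto one heavily
#' populated chemotype — the behaviour that drives the characteristic
#' scaffold-diversity profile of such collections.
#' @export
ACYCLIC_SENTINEL <- "ACYCLIC"

# Prune one kekulized ctab to its framework: iteratively delete degree-1
# atoms (with keepExocyclic, degree-1 atoms held by a bond of order >= 2
# are retained). Returns the logical keep mask over atoms.
.pruneFramework <- function(ab, bb, keepExocyclic = FALSE) {
  n <- nrow(ab)
  keep <- rep(TRUE, n)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
  repeat {
    deg <- tabulate(c(bb[, 1], bb[, 2]), nbins = n)
    term <- which(keep & deg == 1L)
    if (keepExocyclic && length(term)) {
      ord <- integer(length(term))
      for (j in seq_along(term)) {
        hit <- which(bb[, 1] == term[j] | bb[, 2] == term[j])
        ord[j] <- bb[hit[1], 3]
      }
      term <- term[ord < 2L]
    }
    if (!length(term)) break
    keep[term] <- FALSE
    bb <- bb[!(bb[, 1] %in% term | bb[, 2] %in% term), , drop = FALSE]
  }
  keep
}

#' Extract the chemotype of each molecule
#'
#' The chemotype of a cyclic molecule is its framework: all ring systems
#' plus the linkers between them, obtained by iteratively deleting terminal
#' (degree-1) atoms until none remain. Atom and bond types are retained (no
#' generic-graph abstraction), and the framework is reported as a canonical
#' SMILES key. Ring-free molecules map to the shared
#' [ACYCLIC_SENTINEL] key.
#'
#' Exocyclic atoms attached by a double bond (e.g. a carbonyl oxygen on a
#' ring) are terminal atoms and are pruned by default; set
#' `keepExocyclic = TRUE` to retain any terminal atom held by a bond of
#' order two or higher (which also retains the chains carrying them).
#'
#' @param x A curated [CompoundSet-class], or a character vector of valid
#'   SMILES.
#' @param keepExocyclic Retain multiply-bonded terminal atoms.
#' @return Character vector of chemotype keys, one per molecule (named by
#'   record ID for a CompoundSet).
#' @examples
#' extractChemotype(c("CCO", "Cc1ccccc1"))  # "ACYCLIC", benzene framework
#' @export
extractChemotype <- function(x, keepExocyclic = FALSE) {
  if (methods::is(x, "CompoundSet")) {
    smi <- x@records$smiles_canonical
    ids <- x@records$id
  } else {
    stopifnot(is.character(x))
    smi <- .obCanonical(x)
    if (anyNA(smi)) stop("unparseable SMILES at position ",
                         which(is.na(smi))[1])
    ids <- names(x)
  }
  n <- length(smi)
  keys <- rep(ACYCLIC_SENTINEL, n)
  if (!n) return(keys)
  # single-heavy-atom molecules are trivially acyclic; a one-atom ctab is
  # not a valid SDF record, so they never reach the converter
  multi <- which(.formulaHeavy(.obProps(smi)$formula)$heavy >= 2L)
  if (!length(multi)) {
    if (!is.null(ids)) names(keys) <- ids
    return(keys)
  }
  sdfset <- .obSdf(smi[multi])
  frag_text <- character(0)
  frag_idx <- integer(0)
  for (j in seq_along(multi)) {
    k <- multi[j]
    ab <- ChemmineR::atomblock(sdfset[[j]])
    bb <- ChemmineR::bondblock(sdfset[[j]])
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
    ncomp <- .graphComponents(nrow(ab), bb[, 1:2, drop = FALSE])
    n_rings <- nrow(bb) - nrow(ab) + ncomp
    if (n_rings < 1L) next
    keep <- .pruneFramework(ab, bb, keepExocyclic)
    frag_text <- c(frag_text, .sdfSubgraphText(ab, bb, keep, title = k))
    frag_idx <- c(frag_idx, k)
  }
  if (length(frag_idx)) {
    res <- .obCanonicalFromSdfText(paste(frag_text, collapse = "\n"), n)
    bad <- frag_idx[is.na(res[frag_idx])]
    if (length(bad))
      stop("framework canonicalization failed for molecule ", bad[1])
    keys[frag_idx] <- res[frag_idx]
  }
  if (!is.null(ids)) names(keys) <- ids
  keys
}

#' Tabulate chemotype populations of a library
#'
#' Aggregates [extractChemotype()] over all records of a library into a
#' [ChemotypeTable-class]: the chemotype-to-count mapping that underlies
#' every scaffold-diversity metric (counts, CSR curves, AUC, F50, entropy).
#'
#' @param set A curated [CompoundSet-class].
#' @param keepExocyclic Passed to [extractChemotype()].
#' @return A [ChemotypeTable-class].
#' @examples
#' s <- librarySetFromSmiles(c("Cc1ccccc1", "CCc1ccccc1", "CCO", "CC(C)=O"))
#' tabulateChemotypes(s)  # benzene: 2, ACYCLIC: 2
#' @export
tabulateChemotypes <- function(set, keepExocyclic = FALSE) {
  stopifnot(methods::is(set, "CompoundSet"))
  if (!nrow(set@records)) stop("cannot tabulate an empty library")
  keys <- extractChemotype(set, keepExocyclic = keepExocyclic)
  tab <- table(keys)
  ChemotypeTable(stats::setNames(as.integer(tab), names(tab)),
                 setName = set@name)
}

#' Write a chemotype census as TSV
#'
#' Columns `set_name`, `chemotype_key`, `count`, sorted by descending count
#' then key.
#'
#' @param table A [ChemotypeTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeChemotypeTable <- function(table, path) {
  stopifnot(methods::is(table, "ChemotypeTable"))
  cnt <- chemotypeCounts(table)
  utils::write.table(
    data.frame(set_name = setName(table), chemotype_key = names(cnt),
               count = as.integer(cnt)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
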