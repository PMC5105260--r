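#' @title Generics for library and chemotype containers
#' @name ConsensusDiversity-generics
#' @keywords internal
NULL

#' Library name of an object
#' @param x A CompoundSet, ChemotypeTable or CSRCurve.
#' @return Length-1 character.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname setName
#' @export
setMethod("setName", "CompoundSet", function(x) x@name)
#' @rdname setName
#' @export
setMethod("setName", "ChemotypeTable", function(x) x@setName)
#' @rdname setName
#' @export
setMethod("setName", "CSRCurve", function(x) x@setName)

#' Per-chemotype compound counts
#' @param x A ChemotypeTable.
#' @return Named integer vector sorted by descending count then key.
#' @export
setGeneric("chemotypeCounts", function(x) standardGeneric("chemotypeCounts"))
#' @rdname chemotypeCounts
#' @export
setMethod("chemotypeCounts", "ChemotypeTable", function(x) x@counts)

#' Number of distinct chemotypes N
#' @param x A ChemotypeTable.
#' @export
setGeneric("nChemotypes", function(x) standardGeneric("nChemotypes"))
#' @rdname nChemotypes
#' @export
setMethod("nChemotypes", "ChemotypeTable", function(x) length(x@counts))

#' Number of compounds M
#' @param x A ChemotypeTable or CompoundSet.
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))
#' @rdname nCompounds
#' @export
setMethod("nCompounds", "ChemotypeTable", function(x) sum(x@counts))
#' @rdname nCompounds
#' @export
setMethod("nCompounds", "CompoundSet", function(x) nrow(x@records))

#' Number of singleton chemotypes N_sing
#' @param x A ChemotypeTable.
#' @export
setGeneric("nSingletons", function(x) standardGeneric("nSingletons"))
#' @rdname nSingletons
#' @export
setMethod("nSingletons", "ChemotypeTable", function(x) sum(x@counts == 1L))

#' Molecule records of a CompoundSet
#' @param x A CompoundSet.
#' @return data.frame with columns id, smiles_raw, smiles_canonical,
#'   n_heavy_atoms, n_rings.
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))
#' @rdname compoundData
#' @export
setMethod("compoundData", "CompoundSet", function(x) x@records)

#' Canonical SMILES of a CompoundSet
#' @param x A CompoundSet.
#' @return Named character vector (names = record ids).
#' @export
setGeneric("smilesOf", function(x) standardGeneric("smilesOf"))
#' @rdname smilesOf
#' @export
setMethod("smilesOf", "CompoundSet", function(x)
  stats::setNames(x@records$smiles_canonical, x@records$id))

#' Curation / deduplication audit trail
#' @param x A CompoundSet.
#' @return List with stage and skip/rejection/duplicate counts.
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
#' @rdname processingLog
#' @export
setMethod("processingLog", "CompoundSet", function(x) x@processing)
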