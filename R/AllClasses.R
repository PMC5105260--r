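#' CompoundSet: a curated compound library
#'
#' An ordered collection of molecule records for one compound library.
#' Each record carries the input structure string, its canonical form, and
#' basic graph counts filled in during curation. `processing` tracks the
#' pipeline stage (`"raw"`, `"curated"`, `"unique"`) together with skip,
#' rejection and duplicate counts, so the number of unique compounds M is
#' auditable against the raw input.
#'
#' @slot name Library name (length-1 character).
#' @slot records data.frame with columns `id`, `smiles_raw`,
#'   `smiles_canonical`, `n_heavy_atoms`, `n_rings`.
#' @slot processing list with elements `stage`, `n_input`, `n_skipped`,
#'   `n_rejected`, `n_duplicates`, `rejections` (data.frame id/reason).
#'
#' @aliases CompoundSet
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(name = "character", records = "data.frame",
                 processing = "list"),
  prototype(name = "library",
            records = data.frame(id = character(0),
                                 smiles_raw = character(0),
                                 smiles_canonical = character(0),
                                 n_heavy_atoms = integer(0),
                                 n_rings = integer(0)),
            processing = list(stage = "raw", n_input = 0L, n_skipped = 0L,
                              n_rejected = 0L, n_duplicates = 0L,
                              rejections = NULL)))

setValidity("CompoundSet", function(object) {
  msgs <- character(0)
  need <- c("id", "smiles_raw", "smiles_canonical", "n_heavy_atoms",
            "n_rings")
  if (length(object@name) != 1L || is.na(object@name))
    msgs <- c(msgs, "'name' must be a single non-NA string")
  if (!all(need %in% names(object@records)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(need, collapse = ", ")))
  st <- object@processing$stage
  if (!is.null(st) && identical(st, "unique")) {
    can <- object@records$smiles_canonical
    if (anyDuplicated(can[!is.na(can)]))
      msgs <- c(msgs, "duplicate canonical SMILES in a deduplicated set")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CompoundSet Number of records (library size M at the current
#'   stage).
#' @param x A `CompoundSet`.
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@records))

setMethod("show", "CompoundSet", function(object) {
  p <- object@processing
  cat("CompoundSet '", object@name, "': ", nrow(object@records),
      " molecules [stage: ", p$stage, "]\n", sep = "")
  cat("  input records: ", p$n_input, "; skipped: ", p$n_skipped,
      "; rejected: ", p$n_rejected, "; duplicates removed: ",
      p$n_duplicates, "\n", sep = "")
  if (nrow(object@records)) {
    k <- min(3L, nrow(object@records))
    cat("  head:", paste(utils::head(object@records$smiles_canonical, k),
                         collapse = "  "), "\n")
  }
})

#' ChemotypeTable: chemotype population counts for one library
#'
#' Maps each chemotype key (a canonical scaffold SMILES, or the reserved
#' sentinel `"ACYCLIC"` shared by all ring-free molecules) to the number of
#' compounds c_i carrying it. Counts are stored sorted by descending count
#' with ties broken by ascending key, the order used by CSR curves, F50 and
#' the top-n entropy selection. N = number of chemotypes, M = sum of counts,
#' N_sing = number of chemotypes with c_i = 1.
#'
#' @slot setName Library name.
#' @slot counts Named integer vector of per-chemotype compound counts.
#'
#' @aliases ChemotypeTable
#' @exportClass ChemotypeTable
setClass("ChemotypeTable",
  representation(setName = "character", counts = "integer"),
  prototype(setName = "library", counts = integer(0)))

setValidity("ChemotypeTable", function(object) {
  msgs <- character(0)
  cnt <- object@counts
  if (!length(cnt)) msgs <- c(msgs, "counts must be nonempty")
  if (any(is.na(cnt)) || any(cnt < 1L))
    msgs <- c(msgs, "every chemotype count must be >= 1")
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))) ||
      anyDuplicated(names(cnt)))
    msgs <- c(msgs, "counts must have unique nonempty chemotype keys")
  if (length(cnt) > 1L) {
    o <- order(-cnt, names(cnt), method = "radix")
    if (!identical(o, seq_along(cnt)))
      msgs <- c(msgs, "counts must be sorted by descending count, then key")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChemotypeTable from raw counts
#'
#' Chemistry-free entry point: build the substrate of all scaffold metrics
#' directly from a (possibly unsorted) named count vector, e.g. from a
#' published chemotype census or an external scaffold engine.
#'
#' @param counts Integer vector of per-chemotype compound counts, all >= 1.
#'   Names are chemotype keys; unnamed vectors get keys `ct001, ...`.
#' @param setName Library name attached to the table.
#' @return A [ChemotypeTable-class] object.
#' @examples
#' tab <- ChemotypeTable(c(pyridine = 4L, benzene = 3L, ACYCLIC = 3L))
#' nChemotypes(tab); nCompounds(tab); nSingletons(tab)
#' @export
ChemotypeTable <- function(counts, setName = "library") {
  stopifnot(is.numeric(counts))
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  if (is.null(names(counts)))
    names(counts) <- sprintf("ct%03d", seq_along(counts))
  o <- order(-counts, names(counts), method = "radix")
  methods::new("ChemotypeTable", setName = setName, counts = counts[o])
}

setMethod("show", "ChemotypeTable", function(object) {
  cnt <- object@counts
  cat("ChemotypeTable '", object@setName, "': N=", length(cnt),
      " chemotypes, M=", sum(cnt), " compounds, N_sing=",
      sum(cnt == 1L), "\n", sep = "")
  k <- min(5L, length(cnt))
  cat("  top:", paste0(names(cnt)[seq_len(k)], " (", cnt[seq_len(k)], ")",
                       collapse = ", "), "\n")
})

#' CSRCurve: a cyclic system recovery curve
#'
#' Ordered curve points for one library: the fraction of chemotypes
#' considered (x, chemotypes taken in descending population order) against
#' the fraction of compounds they contain (y). Points run from (0,0) to
#' (1,1); a maximally diverse (all-singleton) library traces the diagonal,
#' a single-chemotype library jumps straight to y = 1.
#'
#' @slot points data.frame with numeric columns `x` and `y`.
#' @slot convention Integration convention the curve is paired with,
#'   `"trapezoid"` or `"staircase"`.
#' @slot setName Library name.
#'
#' @aliases CSRCurve
#' @exportClass CSRCurve
setClass("CSRCurve",
  representation(points = "data.frame", convention = "character",
                 setName = "character"),
  prototype(points = data.frame(x = numeric(0), y = numeric(0)),
            convention = "trapezoid", setName = "library"))

setValidity("CSRCurve", function(object) {
  p <- object@points
  msgs <- character(0)
  if (!all(c("x", "y") %in% names(p)))
    msgs <- c(msgs, "points must have columns x and y")
  else if (nrow(p) < 2L) {
    msgs <- c(msgs, "curve needs at least 2 points")
  } else {
    if (abs(p$x[1]) > 1e-12 || abs(p$y[1]) > 1e-12)
      msgs <- c(msgs, "curve must start at (0,0)")
    if (abs(p$x[nrow(p)] - 1) > 1e-12 || abs(p$y[nrow(p)] - 1) > 1e-12)
      msgs <- c(msgs, "curve must end at (1,1)")
    if (any(diff(p$x) <= 0)) msgs <- c(msgs, "x must be strictly increasing")
    if (any(diff(p$y) < -1e-12)) msgs <- c(msgs, "y must be non-decreasing")
  }
  if (!object@convention %in% c("trapezoid", "staircase"))
    msgs <- c(msgs, "convention must be 'trapezoid' or 'staircase'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CSRCurve", function(object) {
  cat("CSRCurve '", object@setName, "': ", nrow(object@points) - 1L,
      " chemotypes, convention=", object@convention,
      ", AUC=", format(csrAUC(object), digits = 4), "\n", sep = "")
})
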