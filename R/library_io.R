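#' Read a compound library from a SMILES or SDF file
#'
#' SMILES files hold one record per line, either bare SMILES or
#' `SMILES<TAB>ID`; lines starting with `#` and blank lines are ignored;
#' records without an ID get `row<k>` (1-based over the retained lines).
#' SDF input is read with [ChemmineR::read.SDFset()] and the molecule title
#' is used as the ID when present. Records whose structure fails to parse
#' are skipped and counted in the processing log.
#'
#' The returned set is at stage `"raw"`: structures are canonicalized but
#' not yet washed. Follow with [curateLibrary()] and [deduplicateLibrary()]
#' (or use [loadLibrary()] which chains all three).
#'
#' @param path Path to the input file.
#' @param format `"smi"` or `"sdf"`. Defaults from the file extension.
#' @param name Library name; defaults to the file base name.
#' @return A [CompoundSet-class] at stage `"raw"`.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO\tethanol", "c1ccccc1", "CC(=O)O"), f)
#' readLibrary(f)
#' @export
readLibrary <- function(path, format = c("auto", "smi", "sdf"),
                        name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE))
      "sdf" else "smi"
  }
  if (is.null(name))
    name <- sub("\\.[A-Za-z]+$", "", basename(path))
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines, which = "right")
    keep <- nzchar(lines) & !grepl("^\\s*#", lines)
    lines <- lines[keep]
    if (!length(lines)) stop("empty library: no records in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, function(p) trimws(p[1]), character(1))
    id <- vapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      if (length(p) >= 2 && nzchar(trimws(p[2]))) trimws(p[2])
      else sprintf("row%d", k)
    }, character(1))
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ok <- ChemmineR::validSDF(sdfset)
    sdfset <- sdfset[ok]
    if (!length(sdfset)) stop("empty library: no parseable records in ", path)
    smi <- as.character(ChemmineR::sdf2smiles(sdfset))
    titles <- unname(ChemmineR::sdfid(sdfset))
    id <- ifelse(nzchar(titles), titles,
                 sprintf("row%d", seq_along(titles)))
  }
  can <- .obCanonical(smi)
  parsed <- !is.na(can)
  n_skipped <- sum(!parsed)
  if (!any(parsed)) stop("empty library: no parseable records in ", path)
  records <- data.frame(id = id[parsed], smiles_raw = smi[parsed],
                        smiles_canonical = can[parsed],
                        n_heavy_atoms = NA_integer_, n_rings = NA_integer_,
                        stringsAsFactors = FALSE)
  methods::new("CompoundSet", name = name, records = records,
               processing = list(stage = "raw", n_input = length(smi),
                                 n_skipped = n_skipped, n_rejected = 0L,
                                 n_duplicates = 0L, rejections = NULL))
}

# Connected components of a molecular graph given bond endpoints.
.graphComponents <- function(n_atoms, bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  comp <- seq_len(n_atoms)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    ri <- find(bonds[b, 1]); rj <- find(bonds[b, 2])
    if (ri != rj) comp[ri] <- rj
  }
  length(unique(vapply(seq_len(n_atoms), find, integer(1))))
}

# Heavy-atom and SSSR ring counts for a vector of valid SMILES.
# Single-heavy-atom molecules are resolved from the formula alone (a
# one-atom ctab is not a valid SDF record).
.graphCounts <- function(smiles) {
  n <- length(smiles)
  fh <- .formulaHeavy(.obProps(smiles)$formula)
  heavy <- as.integer(fh$heavy)
  rings <- integer(n)
  multi <- which(heavy >= 2L)
  if (!length(multi)) return(list(heavy = heavy, rings = rings))
  sdfset <- .obSdf(smiles[multi])
  for (j in seq_along(multi)) {
    k <- multi[j]
    ab <- ChemmineR::atomblock(sdfset[[j]])
    bb <- ChemmineR::bondblock(sdfset[[j]])
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
    ncomp <- .graphComponents(nrow(ab), bb[, 1:2, drop = FALSE])
    rings[k] <- nrow(bb) - nrow(ab) + ncomp
  }
  list(heavy = heavy, rings = rings)
}

# Wash one canonical SMILES: keep the largest carbon-containing component
# (ties: lexicographically smallest canonical string), neutralize formal
# charges where a proton can be added or removed, re-canonicalize.
# Returns list(smiles=..., reason=NA) or list(smiles=NA, reason=...).
.curateOne <- function(canonical) {
  comps <- strsplit(canonical, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (!length(comps)) return(list(smiles = NA_character_,
                                  reason = "unparseable"))
  props <- .obProps(comps)
  fh <- .formulaHeavy(props$formula)
  ok <- fh$has_carbon
  if (!any(ok)) return(list(smiles = NA_character_,
                            reason = "no_organic_component"))
  cand <- which(ok)
  cand <- cand[fh$heavy[cand] == max(fh$heavy[cand])]
  if (length(cand) > 1L) {
    cansmi <- .obCanonical(comps[cand])
    cand <- cand[order(cansmi, method = "radix")][1]
  }
  out <- .obCanonical(comps[cand], neutralize = TRUE)
  if (is.na(out)) list(smiles = NA_character_, reason = "wash_failed")
  else list(smiles = out, reason = NA_character_)
}

#' Curate (wash) a compound library
#'
#' Applies a documented simplification of the usual library wash to every
#' record: multi-component structures (salts, mixtures) are split and the
#' component with the most heavy atoms that contains at least one carbon is
#' kept (ties broken by lexicographically smallest canonical SMILES); formal
#' charges are neutralized where a proton can be added or removed without
#' changing connectivity; the result is re-canonicalized and annotated with
#' heavy-atom and ring counts. Records with no carbon-containing component
#' (pure inorganic salts) are rejected with a reason code. Curation is
#' idempotent.
#'
#' @param set A [CompoundSet-class] (stage `"raw"` or `"curated"`).
#' @return A [CompoundSet-class] at stage `"curated"`.
#' @seealso [deduplicateLibrary()], [loadLibrary()]
#' @examples
#' s <- librarySetFromSmiles(c(na_acetate = "CC(=O)[O-].[Na+]"))
#' compoundData(curateLibrary(s))$smiles_canonical  # "CC(=O)O"
#' @export
curateLibrary <- function(set) {
  stopifnot(methods::is(set, "CompoundSet"))
  rec <- set@records
  n <- nrow(rec)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    r <- .curateOne(rec$smiles_canonical[k])
    out[k] <- r$smiles
    reason[k] <- r$reason
  }
  keep <- !is.na(out)
  rej <- data.frame(id = rec$id[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  rec <- rec[keep, , drop = FALSE]
  rec$smiles_canonical <- out[keep]
  if (!nrow(rec)) stop("empty library after curation: ", set@name)
  gc <- .graphCounts(rec$smiles_canonical)
  rec$n_heavy_atoms <- gc$heavy
  rec$n_rings <- gc$rings
  p <- set@processing
  p$stage <- "curated"
  p$n_rejected <- p$n_rejected + nrow(rej)
  p$rejections <- rbind(p$rejections, rej)
  methods::new("CompoundSet", name = set@name, records = rec,
               processing = p)
}

#' Deduplicate a curated library
#'
#' Keeps exactly one record per distinct canonical SMILES (first occurrence
#' wins), yielding the unique-compound count M used by all downstream
#' metrics.
#'
#' @param set A curated [CompoundSet-class].
#' @return A [CompoundSet-class] at stage `"unique"`.
#' @export
deduplicateLibrary <- function(set) {
  stopifnot(methods::is(set, "CompoundSet"))
  rec <- set@records
  dup <- duplicated(rec$smiles_canonical)
  rec <- rec[!dup, , drop = FALSE]
  if (!nrow(rec)) stop("empty library after deduplication: ", set@name)
  p <- set@processing
  p$stage <- "unique"
  p$n_duplicates <- p$n_duplicates + sum(dup)
  methods::new("CompoundSet", name = set@name, records = rec,
               processing = p)
}

#' Read, curate and deduplicate a library in one step
#'
#' @inheritParams readLibrary
#' @return A [CompoundSet-class] at stage `"unique"`.
#' @export
loadLibrary <- function(path, format = c("auto", "smi", "sdf"),
                        name = NULL) {
  deduplicateLibrary(curateLibrary(readLibrary(path, format, name)))
}

#' Build a CompoundSet directly from SMILES strings
#'
#' Programmatic entry point mirroring [readLibrary()]: structures are
#' canonicalized, unparseable entries are skipped and counted. The result is
#' at stage `"raw"`; chain with [curateLibrary()] and
#' [deduplicateLibrary()] as needed.
#'
#' @param smiles Character vector of SMILES; names become record IDs
#'   (unnamed entries get `row<k>`).
#' @param name Library name.
#' @return A [CompoundSet-class] at stage `"raw"`.
#' @export
librarySetFromSmiles <- function(smiles, name = "library") {
  stopifnot(is.character(smiles), length(smiles) > 0)
  id <- names(smiles)
  if (is.null(id)) id <- rep("", length(smiles))
  id <- ifelse(nzchar(id), id, sprintf("row%d", seq_along(smiles)))
  can <- .obCanonical(unname(smiles))
  parsed <- !is.na(can)
  if (!any(parsed)) stop("empty library: no parseable SMILES")
  records <- data.frame(id = id[parsed], smiles_raw = unname(smiles)[parsed],
                        smiles_canonical = can[parsed],
                        n_heavy_atoms = NA_integer_, n_rings = NA_integer_,
                        stringsAsFactors = FALSE)
  methods::new("CompoundSet", name = name, records = records,
               processing = list(stage = "raw", n_input = length(smiles),
                                 n_skipped = sum(!parsed), n_rejected = 0L,
                                 n_duplicates = 0L, rejections = NULL))
}

#' Drop acyclic molecules from a curated library
#'
#' Rebuilds the library keeping only molecules with at least one ring —
#' the construction used to compare a library against its cyclic-systems
#' subset.
#'
#' @param set A curated [CompoundSet-class] (ring counts populated).
#' @param suffix Appended to the library name of the subset.
#' @return A [CompoundSet-class] restricted to cyclic molecules.
#' @export
cyclicSubset <- function(set, suffix = " subset") {
  stopifnot(methods::is(set, "CompoundSet"))
  if (any(is.na(set@records$n_rings)))
    stop("cyclicSubset requires a curated set (run curateLibrary first)")
  rec <- set@records[set@records$n_rings > 0L, , drop = FALSE]
  if (!nrow(rec)) stop("no cyclic molecules in ", set@name)
  methods::new("CompoundSet", name = paste0(set@name, suffix),
               records = rec, processing = set@processing)
}

#' Write a library as a SMILES file
#'
#' One `SMILES<TAB>ID` record per line, the dialect read by
#' [readLibrary()].
#'
#' @param set A [CompoundSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSmiles <- function(set, path) {
  stopifnot(methods::is(set, "CompoundSet"))
  writeLines(paste0(set@records$smiles_canonical, "\t", set@records$id),
             path)
  invisible(path)
}
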