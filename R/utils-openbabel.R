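# Internal bridge to the OpenBabel toolkit via ChemmineR/ChemmineOB.
# All chemistry I/O (parsing, canonicalization, fingerprints, descriptors)
# funnels through these helpers so toolkit behaviour is pinned in one place.

#' @importFrom ChemmineOB convertFormat forEachMol prop_OB fingerprint_OB
#'   smartsSearch_OB
#' @importFrom ChemmineR smiles2sdf atomblock bondblock
NULL

# Standard rotatable-bond SMARTS: acyclic single bonds between two
# non-terminal atoms, excluding bonds adjacent to a triple bond.
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

# Canonicalize SMILES, vectorized, NA for unparseable records.
# OpenBabel stops a multi-record conversion at the first bad record, so the
# batch is retried on the missing tail until no further progress is made;
# titles carry the record index for re-alignment.
.obCanonical <- function(smiles, neutralize = FALSE) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  if (!length(smiles)) return(out)
  opts <- if (neutralize) data.frame(names = "neutralize", args = "")
          else data.frame(names = character(0), args = character(0))
  pending <- which(!is.na(smiles) & nzchar(smiles))
  repeat {
    if (!length(pending)) break
    src <- paste0(smiles[pending], "\t", pending, "\n", collapse = "")
    res <- tryCatch(
      suppressWarnings(convertFormat("SMI", "CAN", source = src,
                                     options = opts)),
      error = function(e) "")
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      i <- suppressWarnings(as.integer(parts[2]))
      if (!is.na(i) && i %in% pending && nzchar(parts[1])) {
        out[i] <- parts[1]
        got <- c(got, i)
      }
    }
    remaining <- setdiff(pending, got)
    if (length(remaining) == length(pending)) {
      # no progress: the head record is unparseable; drop it and continue
      remaining <- remaining[-1]
    }
    pending <- remaining
  }
  out
}

# OBMol handles for a vector of valid SMILES (order preserved).
.obMols <- function(smiles) {
  forEachMol("SMILES", paste0(smiles, collapse = "\n"), identity)
}

# Descriptor table from prop_OB for valid SMILES.
.obProps <- function(smiles) {
  prop_OB(.obMols(smiles))
}

# Parse a Hill formula ("C6H5NaO2") into element counts.
.parseFormula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  stats::setNames(n, el)
}

# Heavy-atom count and carbon flag from a vector of formulas.
.formulaHeavy <- function(formulas) {
  res <- lapply(formulas, .parseFormula)
  heavy <- vapply(res, function(x) sum(x[names(x) != "H"]), integer(1))
  has_c <- vapply(res, function(x) any(names(x) == "C"), logical(1))
  list(heavy = heavy, has_carbon = has_c)
}

# Rotatable-bond counts for valid SMILES.
.obRotors <- function(smiles) {
  as.integer(smartsSearch_OB(.obMols(smiles), ROTOR_SMARTS,
                             uniqueMatches = TRUE))
}

# SDFset for valid SMILES (kekulized ctabs, implicit hydrogens).
.obSdf <- function(smiles) {
  nm <- paste0("m", seq_along(smiles))
  smiles2sdf(stats::setNames(smiles, nm))
}

# ctab charge codes -> formal charges
.CTAB_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                  `7` = -3L)

# Serialize a subgraph of one SDF molecule back to V2000 text.
# keep: logical over atoms; bonds restricted to kept atoms.
.sdfSubgraphText <- function(ab, bb, keep, title = "frag") {
  idx <- which(keep)
  remap <- integer(nrow(ab))
  remap[idx] <- seq_along(idx)
  bb <- bb[bb[, 1] %in% idx & bb[, 2] %in% idx, , drop = FALSE]
  el <- sub("_.*$", "", rownames(ab))
  chg_code <- if (ncol(ab) >= 5) ab[idx, 5] else rep(0, length(idx))
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    ab[idx, 1], ab[idx, 2], 0, el[idx])
  bond_lines <- if (nrow(bb)) {
    sprintf("%3d%3d%3d  0", remap[bb[, 1]], remap[bb[, 2]], bb[, 3])
  } else character(0)
  chg <- .CTAB_CHARGE[as.character(chg_code)]
  chg_lines <- character(0)
  ci <- which(!is.na(chg))
  if (length(ci)) {
    chg_lines <- sprintf("M  CHG%3d%s", length(ci),
                         paste0(sprintf("%4d%4d", ci, chg[ci]),
                                collapse = ""))
  }
  paste(c(title, "  ConsensusDiversity", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(idx), nrow(bb)),
          atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES for a block of $$$$-separated V2000 records.
# Titles must carry 1-based indices; returns a vector aligned to n.
.obCanonicalFromSdfText <- function(sdf_text, n) {
  out <- rep(NA_character_, n)
  res <- convertFormat("SDF", "CAN", source = paste0(sdf_text, "\n"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    i <- suppressWarnings(as.integer(parts[2]))
    if (!is.na(i)) out[i] <- parts[1]
  }
  out
}
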