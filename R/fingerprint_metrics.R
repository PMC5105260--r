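#' Structural fingerprints for a library
#'
#' Computes binary fingerprints for every molecule: 166-bit MACCS
#' structural keys or extended-connectivity fingerprints of diameter 4
#' (ECFP4) hashed into the toolkit's native 4096-bit space. Fingerprints
#' are computed from canonical SMILES, so input variants of the same
#' structure yield identical bit sets.
#'
#' @param x A curated [CompoundSet-class] or a character vector of valid
#'   SMILES.
#' @param kind `"maccs166"` or `"ecfp4"`.
#' @return Integer 0/1 matrix, one row per molecule (rownames = record
#'   IDs), with attributes `kind` and `toolkit`.
#' @export
moleculeFingerprints <- function(x, kind = c("maccs166", "ecfp4")) {
  kind <- match.arg(kind)
  if (methods::is(x, "CompoundSet")) {
    smi <- x@records$smiles_canonical
    ids <- x@records$id
  } else {
    stopifnot(is.character(x))
    smi <- .obCanonical(x)
    if (anyNA(smi)) stop("unparseable SMILES at position ",
                         which(is.na(smi))[1])
    ids <- if (!is.null(names(x))) names(x) else seq_along(x)
  }
  obname <- c(maccs166 = "MACCS", ecfp4 = "ECFP4")[[kind]]
  fp <- fingerprint_OB(.obMols(smi), obname)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (kind == "maccs166") fp <- fp[, seq_len(166L), drop = FALSE]
  storage.mode(fp) <- "integer"
  rownames(fp) <- ids
  attr(fp, "kind") <- kind
  attr(fp, "toolkit") <- paste0("ChemmineOB ",
                                as.character(utils::packageVersion("ChemmineOB")))
  fp
}

#' Tanimoto similarity of two fingerprints
#'
#' |A intersect B| / |A union B| over set bits. If both bit sets are empty
#' the pair is reported as 0 (maximally dissimilar) with a warning.
#'
#' @param a,b Binary vectors of equal length (rows of a fingerprint
#'   matrix). If both carry a `kind` attribute it must match.
#' @return Similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    stop("fingerprint kinds differ: ", ka, " vs ", kb)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) {
    warning("both fingerprints empty; similarity reported as 0")
    return(0)
  }
  inter / uni
}

#' Full pairwise Tanimoto similarity matrix
#'
#' @param fp Binary fingerprint matrix (rows = molecules).
#' @return Symmetric M x M similarity matrix.
#' @export
tanimotoMatrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  pop <- rowSums(fp)
  uni <- outer(pop, pop, "+") - inter
  if (any(pop == 0))
    warning(sum(pop == 0), " molecule(s) with empty fingerprints; ",
            "their pairwise similarities reported as 0")
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(fp), rownames(fp))
  sim
}

#' Intra-library fingerprint similarity summary
#'
#' Seven-number summary (minimum, first quartile, median, mean, third
#' quartile, maximum, sample standard deviation) of the Tanimoto
#' similarities over all M(M-1)/2 unordered distinct molecule pairs.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); the standard deviation uses the n-1
#' denominator and is reported as 0 (flagged in `sd_defined`) when only one
#' pair exists.
#'
#' @param x A curated [CompoundSet-class], a character vector of SMILES, or
#'   a precomputed fingerprint matrix.
#' @param kind Fingerprint kind when `x` holds molecules.
#' @param setName Library name for the summary row (defaults to the set's
#'   name).
#' @return One-row data.frame: `set_name`, `kind`, `n_pairs`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, `sd`, `sd_defined`.
#' @export
intraSimilaritySummary <- function(x, kind = c("maccs166", "ecfp4"),
                                   setName = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    fp <- x
    if (!is.null(attr(fp, "kind"))) kind <- attr(fp, "kind")
    if (is.null(setName)) setName <- "library"
  } else {
    if (is.null(setName))
      setName <- if (methods::is(x, "CompoundSet")) x@name else "library"
    fp <- moleculeFingerprints(x, kind)
  }
  M <- nrow(fp)
  if (M < 2L) stop("intra-library similarity needs at least 2 molecules")
  sim <- tanimotoMatrix(fp)
  vals <- sim[upper.tri(sim)]
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  one_pair <- length(vals) < 2L
  data.frame(set_name = setName, kind = kind,
             n_pairs = length(vals), min = min(vals), q1 = q[1],
             median = q[2], mean = mean(vals), q3 = q[3], max = max(vals),
             sd = if (one_pair) 0 else stats::sd(vals),
             sd_defined = !one_pair, stringsAsFactors = FALSE)
}

#' Write intra-library similarity summaries as TSV
#'
#' @param summaries data.frame of rows from [intraSimilaritySummary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSimilaritySummary <- function(summaries, path) {
  out <- summaries
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_pairs"
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
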