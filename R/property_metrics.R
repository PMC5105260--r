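#' Physicochemical property profile of a library
#'
#' Computes the six descriptors of pharmaceutical relevance per molecule:
#' hydrogen-bond donors (HBD), hydrogen-bond acceptors (HBA,
#' SMARTS-defined acceptor count), the octanol/water partition coefficient
#' (logP, Wildman-Crippen-type), molecular weight (MW, Da), topological
#' polar surface area (TPSA, A^2, Ertl), and rotatable-bond count (RTB:
#' acyclic single bonds between non-terminal atoms, triple-bond-adjacent
#' bonds excluded — so ethanol scores 0).
#'
#' @param x A curated [CompoundSet-class] or a character vector of valid
#'   SMILES.
#' @return data.frame with columns `id`, `hbd`, `hba`, `logp`, `mw`,
#'   `tpsa`, `rtb`, plus a `toolkit` attribute recording the descriptor
#'   engine version.
#' @examples
#' computeProperties(c(benzene = "c1ccccc1"))[, c("hbd", "hba", "rtb")]
#' @export
computeProperties <- function(x) {
  if (methods::is(x, "CompoundSet")) {
    smi <- x@records$smiles_canonical
    ids <- x@records$id
  } else {
    stopifnot(is.character(x))
    smi <- .obCanonical(x)
    if (anyNA(smi)) stop("unparseable SMILES at position ",
                         which(is.na(smi))[1])
    ids <- if (!is.null(names(x))) names(x) else
      sprintf("row%d", seq_along(x))
  }
  pr <- .obProps(smi)
  out <- data.frame(id = ids, hbd = as.integer(pr$HBD),
                    hba = as.integer(pr$HBA2), logp = pr$logP, mw = pr$MW,
                    tpsa = pr$TPSA, rtb = .obRotors(smi),
                    stringsAsFactors = FALSE)
  attr(out, "toolkit") <- paste0("ChemmineOB ",
                                 as.character(utils::packageVersion("ChemmineOB")))
  out
}

#' Extract the 6-column numeric property matrix
#'
#' @param props data.frame from [computeProperties()].
#' @return Numeric matrix with columns hbd, hba, logp, mw, tpsa, rtb.
#' @export
propertyMatrix <- function(props) {
  cols <- c("hbd", "hba", "logp", "mw", "tpsa", "rtb")
  stopifnot(all(cols %in% names(props)))
  m <- as.matrix(props[cols])
  rownames(m) <- props$id
  m
}

#' Pooled z-score standardization of property matrices
#'
#' Centers each of the six property columns by the mean and scales by the
#' sample standard deviation computed over the pooled rows of all compared
#' sets, so one common scale applies across libraries and distances are
#' invariant to the raw units of each column. Zero-variance columns are
#' centered with a unit divisor and flagged.
#'
#' @param matrices List of numeric property matrices (same columns).
#' @return List with `scaled` (list of matrices), `center`, `scale`
#'   (numeric vectors) and `zero_variance` (logical vector).
#' @export
standardizeProperties <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  pooled <- do.call(rbind, matrices)
  if (nrow(pooled) < 2) stop("pooled standardization needs >= 2 rows")
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, stats::sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero))
    warning("zero-variance property column(s): ",
            paste(colnames(pooled)[zero], collapse = ", "),
            " (centered, unit divisor)")
  scl[zero] <- 1
  scaled <- lapply(matrices, function(m)
    sweep(sweep(m, 2, ctr), 2, scl, "/"))
  list(scaled = scaled, center = ctr, scale = scl, zero_variance = zero)
}

#' Mean pairwise Euclidean property distance between two sets
#'
#' The inter-set distance is the mean Euclidean distance between the
#' property vectors of every ordered pair (i in U, j in V), i.e.
#' (1/UV) * sum_i sum_j ||x_i - y_j||. Applied with `u = v` the same
#' formula (self-pairs included, divisor U^2) gives the intra-set
#' distance, the property-diversity measure mapped to colour in the
#' consensus plot. Set `excludeSelf = TRUE` to drop the U zero-distance
#' self pairs in the intra case.
#'
#' @param du,dv Numeric matrices with identical column count (rows =
#'   molecules); pass the same matrix (or omit `dv`) for the intra-set
#'   distance.
#' @param excludeSelf Intra-set only: use divisor U(U-1) without self
#'   pairs.
#' @return Non-negative numeric distance.
#' @examples
#' setDistance(matrix(c(0, 1, rep(0, 10)), 2, 6))  # mean of {0,1,1,0}/4 = 0.5
#' @export
setDistance <- function(du, dv = du, excludeSelf = FALSE) {
  du <- as.matrix(du); dv <- as.matrix(dv)
  if (ncol(du) != ncol(dv))
    stop("property matrices must have the same number of columns")
  intra <- identical(dim(du), dim(dv)) && isTRUE(all.equal(du, dv,
                                                           check.attributes = FALSE))
  # canonical argument order so the summation order (and hence the exact
  # floating-point result) is symmetric in (u, v)
  if (!intra) {
    swap <- if (nrow(du) != nrow(dv)) nrow(du) > nrow(dv) else {
      i <- which(du != dv)[1]
      !is.na(i) && du[i] > dv[i]
    }
    if (isTRUE(swap)) { tmp <- du; du <- dv; dv <- tmp }
  }
  if (intra) {
    d <- as.matrix(stats::dist(du))
  } else {
    U <- nrow(du)
    d <- as.matrix(stats::dist(rbind(du, dv)))[seq_len(U),
                                               U + seq_len(nrow(dv)),
                                               drop = FALSE]
  }
  if (excludeSelf) {
    if (!intra) stop("excludeSelf applies only to the intra-set case")
    U <- nrow(du)
    if (U < 2) stop("excludeSelf needs at least 2 rows")
    return((sum(d) - sum(diag(d))) / (U * (U - 1)))
  }
  mean(d)
}

#' Pairwise set-distance matrix over libraries
#'
#' Square symmetric matrix of mean pairwise Euclidean property distances
#' with intra-set values on the diagonal. Matrices are pooled-z-scored
#' first unless `scale = FALSE`.
#'
#' @param matrices Named list of raw property matrices.
#' @param scale Standardize via [standardizeProperties()] first.
#' @return Numeric matrix with set names on both dimensions.
#' @export
setDistanceMatrix <- function(matrices, scale = TRUE) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  nm <- names(matrices)
  if (is.null(nm)) nm <- sprintf("set%d", seq_along(matrices))
  if (scale) matrices <- standardizeProperties(matrices)$scaled
  n <- length(matrices)
  out <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in i:n) {
    out[i, j] <- out[j, i] <- setDistance(matrices[[i]], matrices[[j]])
  }
  out
}

#' Write per-molecule properties as TSV
#' @param props data.frame from [computeProperties()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProperties <- function(props, path) {
  utils::write.table(props, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
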