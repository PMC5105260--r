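#' Cyclic system recovery (CSR) curve
#'
#' With chemotypes sorted by descending population (ties by ascending key),
#' point k of the curve is (k/N, cumulative compound fraction after the k
#' most populated chemotypes), for k = 0..N. An all-singleton library traces
#' the diagonal; concentrating compounds into few chemotypes pushes the
#' curve toward the upper-left.
#'
#' @param table A [ChemotypeTable-class].
#' @param convention Integration convention the curve is paired with
#'   (`"trapezoid"`, the default, or `"staircase"`); stored on the curve and
#'   used by [csrAUC()].
#' @return A [CSRCurve-class].
#' @examples
#' tab <- ChemotypeTable(c(a = 4, b = 3, c = 2, d = 1))
#' csrCurve(tab)  # (0,0), (0.25,0.4), (0.5,0.7), (0.75,0.9), (1,1)
#' @export
csrCurve <- function(table, convention = c("trapezoid", "staircase")) {
  stopifnot(methods::is(table, "ChemotypeTable"))
  convention <- match.arg(convention)
  cnt <- chemotypeCounts(table)  # already sorted desc count, asc key
  N <- length(cnt)
  M <- sum(cnt)
  pts <- data.frame(x = (0:N) / N, y = c(0, cumsum(as.numeric(cnt))) / M)
  methods::new("CSRCurve", points = pts, convention = convention,
               setName = setName(table))
}

#' Area under the CSR curve
#'
#' Under the default trapezoid convention the area of the piecewise-linear
#' curve through all points including the (0,0) anchor is returned, so an
#' all-singleton library scores exactly 0.5 and areas approach 1 as the
#' population concentrates into a single chemotype. The staircase
#' convention instead sums (1/N) * y at each step's right edge.
#'
#' @param x A [CSRCurve-class] or a [ChemotypeTable-class].
#' @param convention Used when `x` is a table; ignored for a curve (the
#'   curve carries its own convention).
#' @return Numeric area.
#' @export
setGeneric("csrAUC", function(x, ...) standardGeneric("csrAUC"))

#' @rdname csrAUC
#' @param ... Passed through to the table method.
#' @export
setMethod("csrAUC", "CSRCurve", function(x, ...) {
  p <- x@points
  dx <- diff(p$x)
  if (x@convention == "trapezoid")
    sum(dx * (utils::head(p$y, -1) + utils::tail(p$y, -1)) / 2)
  else
    sum(dx * utils::tail(p$y, -1))
})

#' @rdname csrAUC
#' @export
setMethod("csrAUC", "ChemotypeTable",
  function(x, convention = c("trapezoid", "staircase"), ...) {
    csrAUC(csrCurve(x, convention = match.arg(convention)))
  })

#' Fraction of chemotypes recovering half the library (F50)
#'
#' With chemotypes sorted by descending count (ties by ascending key),
#' returns k*/N where k* is the smallest number of chemotypes whose
#' cumulative compound fraction reaches at least 0.5. No interpolation: the
#' value is a discrete coverage fraction in (0, 1]. Larger F50 means higher
#' scaffold diversity (the opposite direction of AUC).
#'
#' @param x A [ChemotypeTable-class] or a numeric vector of counts.
#' @return Numeric fraction.
#' @examples
#' f50(ChemotypeTable(c(a = 5, b = 3, c = 1, d = 1)))  # 0.25
#' @export
setGeneric("f50", function(x) standardGeneric("f50"))

#' @rdname f50
#' @export
setMethod("f50", "ChemotypeTable", function(x) {
  cnt <- as.numeric(chemotypeCounts(x))
  kstar <- which(cumsum(cnt) >= sum(cnt) / 2)[1]
  kstar / length(cnt)
})

#' @rdname f50
#' @export
setMethod("f50", "numeric", function(x) f50(ChemotypeTable(x)))

#' Shannon entropy of a chemotype population
#'
#' SE = -sum(p_i log2 p_i) with p_i = c_i / P over the supplied counts,
#' where P is their total. Ranges from 0 when all compounds share one
#' chemotype to log2(n) when compounds are spread evenly over the n
#' chemotypes.
#'
#' @param counts Numeric vector of chemotype counts, all >= 1.
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(c(2, 2, 2, 2))  # 2 bits
#' @export
shannonEntropy <- function(counts) {
  if (!length(counts)) stop("counts must be nonempty")
  stopifnot(all(counts >= 1))
  p <- counts / sum(counts)
  -sum(p * log2(p)) + 0  # + 0 normalizes IEEE negative zero
}

#' Scaled Shannon entropy over the most populated chemotypes
#'
#' Selects the `nTop` most populated chemotypes (ties broken by ascending
#' key; `nTop` is clamped to the number of chemotypes N), renormalizes the
#' population to the selected counts, and scales the resulting entropy by
#' log2(number selected) so values fall in [0, 1]: 0 when a single
#' chemotype is selected or holds everything, 1 for a perfectly even
#' spread. SSE probes how compounds distribute among the dominant
#' chemotypes rather than across the whole census.
#'
#' @param table A [ChemotypeTable-class].
#' @param nTop Number of most populated chemotypes to consider (>= 1).
#' @return One-row data.frame with columns `n_top`, `n_selected`, `se`,
#'   `sse`.
#' @examples
#' scaledShannonEntropy(ChemotypeTable(rep(10, 8)), nTop = 8)$sse  # 1
#' @export
scaledShannonEntropy <- function(table, nTop) {
  stopifnot(methods::is(table, "ChemotypeTable"), nTop >= 1)
  cnt <- chemotypeCounts(table)
  n_sel <- min(as.integer(nTop), length(cnt))
  sel <- as.numeric(cnt[seq_len(n_sel)])
  se <- shannonEntropy(sel)
  sse <- if (n_sel >= 2L) se / log2(n_sel) else 0
  data.frame(n_top = as.integer(nTop), n_selected = n_sel, se = se,
             sse = sse)
}

#' SSE profile over a grid of top-n values
#'
#' @param table A [ChemotypeTable-class].
#' @param n Integer grid of top-n values (default 5, 10, ..., 70).
#' @return data.frame with one row per grid point (columns of
#'   [scaledShannonEntropy()]).
#' @export
sseProfile <- function(table, n = seq(5L, 70L, by = 5L)) {
  stopifnot(length(n) >= 1)
  do.call(rbind, lapply(n, function(k) scaledShannonEntropy(table, k)))
}

#' Scaffold-diversity summary of a library
#'
#' All whole-library scaffold metrics in one row: chemotype count N,
#' library size M, singleton count N_sing, the ratios N/M, N_sing/N and
#' N_sing/M, the trapezoid CSR AUC and F50. Values are kept at full
#' precision; round at output time (conventionally to 3 decimals).
#'
#' @param table A [ChemotypeTable-class].
#' @param convention AUC convention, see [csrAUC()].
#' @return One-row data.frame with columns `set_name`, `N`, `M`,
#'   `N_over_M`, `N_sing`, `Nsing_over_N`, `Nsing_over_M`, `auc`, `f50`.
#' @export
summarizeScaffolds <- function(table,
                               convention = c("trapezoid", "staircase")) {
  stopifnot(methods::is(table, "ChemotypeTable"))
  N <- nChemotypes(table)
  M <- nCompounds(table)
  Ns <- nSingletons(table)
  data.frame(set_name = setName(table), N = N, M = M, N_over_M = N / M,
             N_sing = Ns, Nsing_over_N = Ns / N, Nsing_over_M = Ns / M,
             auc = csrAUC(table, convention = match.arg(convention)),
             f50 = f50(table), stringsAsFactors = FALSE)
}

#' Write scaffold summaries (with an SSE grid) as TSV
#'
#' One row per library with the [summarizeScaffolds()] columns plus one
#' `sse<n>` column per grid point, ratios rounded to 3 decimals
#' (round-half-even).
#'
#' @param tables List of [ChemotypeTable-class] objects.
#' @param path Output path.
#' @param sseGrid Integer grid for the SSE columns.
#' @return The written data.frame, invisibly.
#' @export
writeScaffoldSummary <- function(tables, path,
                                 sseGrid = seq(5L, 70L, by = 5L)) {
  rows <- lapply(tables, function(tab) {
    s <- summarizeScaffolds(tab)
    sse <- vapply(sseGrid,
                  function(k) scaledShannonEntropy(tab, k)$sse, numeric(1))
    names(sse) <- sprintf("sse%d", sseGrid)
    cbind(s, as.data.frame(as.list(sse)))
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("N", "M", "N_sing")
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Write CSR curves in long format
#'
#' Columns `set_name`, `x`, `y` for external plotting.
#'
#' @param curves List of [CSRCurve-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCsrCurves <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    cbind(set_name = setName(cv), cv@points))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
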