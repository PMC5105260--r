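# Synthetic libraries with known chemotype ground truth. Scaffolds come
# from a shipped pool of curated ring-system frameworks; decoration uses a
# fixed menu of acyclic substituents attached by SMILES prefixing, which
# provably cannot create or destroy rings — so the intended chemotype of
# every generated molecule is exact, not statistical.

.poolCache <- new.env(parent = emptyenv())

#' Built-in scaffold pool for the synthetic generator
#'
#' Curated ring-system frameworks (every atom degree >= 2, so each entry is
#' a fixed point of [extractChemotype()]) whose first atom can carry one
#' additional substituent.
#'
#' @return Character vector of scaffold SMILES.
#' @export
scaffoldPool <- function() {
  if (is.null(.poolCache$pool)) {
    f <- system.file("extdata", "scaffold_pool.smi",
                     package = "ConsensusDiversity", mustWork = TRUE)
    x <- readLines(f)
    .poolCache$pool <- x[!grepl("^#", x) & nzchar(x)]
  }
  .poolCache$pool
}

# Acyclic substituent prefixes; "" = undecorated scaffold.
.substituentMenu <- function() {
  if (is.null(.poolCache$menu)) {
    f <- system.file("extdata", "substituent_menu.smi",
                     package = "ConsensusDiversity", mustWork = TRUE)
    x <- readLines(f)
    .poolCache$menu <- c("", x[!grepl("^#", x) & nzchar(x)])
  }
  .poolCache$menu
}

# Distinct acyclic molecules: alkyl chain of length a plus a terminal
# group; enumeration order is fixed so generation is reproducible.
.acyclicFamily <- function(n) {
  suffixes <- c("", "O", "N", "Cl", "F", "Br", "C#N", "OC", "N(C)C",
                "C(=O)O", "C(=O)N", "C(=O)OC")
  out <- character(0)
  a <- 1L
  while (length(out) < n) {
    out <- c(out, paste0(strrep("C", a), suffixes))
    a <- a + 1L
    if (a > 200L) stop("cannot construct ", n, " distinct acyclic molecules")
  }
  out[seq_len(n)]
}

#' Specification of a synthetic compound library
#'
#' Describes a library with a known chemotype population: how many ring
#' scaffolds, how compounds distribute over them (`"uniform"`, a Zipf law
#' with exponent `zipfExponent`, or an `"explicit"` count list), what
#' fraction of molecules is acyclic, how many side-chain variants each
#' scaffold may receive, and the RNG seed that fixes every draw.
#'
#' @param nScaffolds Number of distinct ring scaffolds.
#' @param nMolecules Total library size (cyclic + acyclic).
#' @param countDistribution `"uniform"`, `"zipf"`, or `"explicit"`.
#' @param zipfExponent Zipf exponent s > 0 (rank-r scaffold gets weight
#'   r^-s); larger s concentrates compounds into the top scaffolds.
#' @param counts Explicit per-scaffold counts (must sum to the cyclic
#'   total) when `countDistribution = "explicit"`.
#' @param acyclicFraction Fraction of molecules generated as ring-free
#'   structures (all sharing the `ACYCLIC` chemotype).
#' @param decoration Maximum number of side-chain variants per scaffold;
#'   must cover the largest per-scaffold count. Default: exactly as many
#'   as needed.
#' @param seed Integer seed controlling scaffold choice, substituent
#'   draws and record shuffling.
#' @return A `librarySpec` list, validated.
#' @export
librarySpec <- function(nScaffolds, nMolecules,
                        countDistribution = c("uniform", "zipf",
                                              "explicit"),
                        zipfExponent = 1, counts = NULL,
                        acyclicFraction = 0, decoration = NULL,
                        seed = 1L) {
  countDistribution <- match.arg(countDistribution)
  stopifnot(nScaffolds >= 0, nMolecules >= 1,
            acyclicFraction >= 0, acyclicFraction <= 1)
  nAcyclic <- as.integer(round(acyclicFraction * nMolecules))
  nCyclic <- nMolecules - nAcyclic
  if (nScaffolds == 0 && nCyclic > 0)
    stop("cyclic molecules requested but nScaffolds = 0")
  if (countDistribution == "explicit") {
    if (is.null(counts) || length(counts) != nScaffolds)
      stop("explicit distribution needs one count per scaffold")
    if (sum(counts) != nCyclic)
      stop("explicit counts must sum to the cyclic total (", nCyclic, ")")
    if (any(counts < 1)) stop("explicit counts must all be >= 1")
  } else if (nCyclic > 0 && nCyclic < nScaffolds) {
    stop("fewer cyclic molecules (", nCyclic, ") than scaffolds (",
         nScaffolds, ")")
  }
  if (countDistribution == "zipf" && zipfExponent <= 0)
    stop("zipf exponent must be > 0")
  structure(list(nScaffolds = as.integer(nScaffolds),
                 nMolecules = as.integer(nMolecules),
                 countDistribution = countDistribution,
                 zipfExponent = zipfExponent, counts = counts,
                 acyclicFraction = acyclicFraction,
                 nAcyclic = nAcyclic, nCyclic = as.integer(nCyclic),
                 decoration = decoration, seed = as.integer(seed)),
            class = "librarySpec")
}

# Deterministic largest-remainder apportionment of total over weights,
# guaranteeing every scaffold at least one compound.
.apportion <- function(weights, total) {
  n <- length(weights)
  stopifnot(total >= n)
  extra <- total - n
  share <- weights / sum(weights) * extra
  base <- floor(share)
  rem <- extra - sum(base)
  if (rem > 0) {
    o <- order(-(share - base), seq_len(n))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base + 1L)
}

#' Generate a synthetic library with known chemotype ground truth
#'
#' Each cyclic molecule is a pool scaffold decorated with a side chain
#' drawn (deterministically from the seed) from a fixed acyclic
#' substituent menu; acyclic molecules come from a distinct-by-construction
#' family of functionalized chains. Decoration cannot change the ring
#' system, so the intended chemotype of every molecule is exact. Record
#' order is a seeded shuffle; the same spec yields byte-identical output.
#'
#' @param spec A [librarySpec()].
#' @return List with `set` (a [CompoundSet-class], stage `"raw"`),
#'   `groundTruth` (data.frame `id`, `chemotype_key`), and
#'   `scaffoldCounts` (named integer vector: intended population per
#'   chemotype key, including `ACYCLIC` when present).
#' @examples
#' spec <- librarySpec(10, 100, "explicit", counts = rep(10, 10), seed = 42)
#' lib <- generateLibrary(spec)
#' table(lib$groundTruth$chemotype_key)
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "librarySpec"))
  pool <- scaffoldPool()
  if (spec$nScaffolds > length(pool))
    stop("requested ", spec$nScaffolds, " scaffolds; pool holds ",
         length(pool))
  menu <- .substituentMenu()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  scaffolds <- sample(pool, spec$nScaffolds)
  cnt <- switch(spec$countDistribution,
    uniform = .apportion(rep(1, spec$nScaffolds), spec$nCyclic),
    zipf = .apportion(seq_len(spec$nScaffolds)^(-spec$zipfExponent),
                      spec$nCyclic),
    explicit = as.integer(spec$counts))
  maxDecor <- if (is.null(spec$decoration)) max(cnt, 0L)
              else as.integer(spec$decoration)
  if (length(cnt) && max(cnt) > maxDecor)
    stop("infeasible spec: a scaffold needs ", max(cnt),
         " variants but decoration allows ", maxDecor)
  if (maxDecor > length(menu))
    stop("infeasible spec: decoration ", maxDecor,
         " exceeds the substituent menu (", length(menu), ")")

  smi <- character(0); truth <- character(0)
  if (spec$nScaffolds > 0 && spec$nCyclic > 0) {
    keys <- .obCanonical(scaffolds)
    for (i in seq_len(spec$nScaffolds)) {
      subs <- sample(menu, cnt[i])
      smi <- c(smi, paste0(subs, scaffolds[i]))
      truth <- c(truth, rep(keys[i], cnt[i]))
    }
  }
  if (spec$nAcyclic > 0) {
    smi <- c(smi, .acyclicFamily(spec$nAcyclic))
    truth <- c(truth, rep(ACYCLIC_SENTINEL, spec$nAcyclic))
  }
  o <- sample(length(smi))
  smi <- smi[o]; truth <- truth[o]
  ids <- sprintf("mol%05d", seq_along(smi))

  can <- .obCanonical(smi)
  if (anyNA(can))
    stop("generator produced unparseable SMILES: ", smi[is.na(can)][1])
  if (anyDuplicated(can))
    stop("generator produced duplicate structures: ",
         can[duplicated(can)][1])
  records <- data.frame(id = ids, smiles_raw = smi,
                        smiles_canonical = can,
                        n_heavy_atoms = NA_integer_,
                        n_rings = NA_integer_, stringsAsFactors = FALSE)
  set <- methods::new("CompoundSet",
                      name = sprintf("synthetic_seed%d", spec$seed),
                      records = records,
                      processing = list(stage = "raw",
                                        n_input = length(smi),
                                        n_skipped = 0L, n_rejected = 0L,
                                        n_duplicates = 0L,
                                        rejections = NULL))
  gt_counts <- table(truth)
  list(set = set,
       groundTruth = data.frame(id = ids, chemotype_key = truth,
                                stringsAsFactors = FALSE),
       scaffoldCounts = stats::setNames(as.integer(gt_counts),
                                        names(gt_counts)))
}

#' Write a generated library and its ground truth to disk
#'
#' @param lib Result of [generateLibrary()].
#' @param smiPath Output SMILES path.
#' @param truthPath Output TSV path for the (id, chemotype_key) map, or
#'   NULL to skip.
#' @return `smiPath`, invisibly.
#' @export
writeGeneratedLibrary <- function(lib, smiPath, truthPath = NULL) {
  writeLines(paste0(lib$set@records$smiles_raw, "\t",
                    lib$set@records$id), smiPath)
  if (!is.null(truthPath))
    utils::write.table(lib$groundTruth, truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(smiPath)
}
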