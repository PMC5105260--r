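# Shared fixtures and independent oracles, built in code at test time.

# A ChemotypeTable realizing a printed (N, M, N_sing) census: N_sing
# singletons plus N - N_sing chemotypes of >= 2 compounds sharing the rest.
tableFromCensus <- function(N, M, Nsing, setName = "census") {
  stopifnot(Nsing <= N, M >= Nsing + 2 * (N - Nsing))
  n_multi <- N - Nsing
  counts <- rep(1L, Nsing)
  if (n_multi > 0) {
    multi <- rep(2L, n_multi)
    multi[1] <- multi[1] + (M - Nsing - 2L * n_multi)
    counts <- c(multi, counts)
  }
  ChemotypeTable(stats::setNames(counts, sprintf("k%04d", seq_len(N))),
                 setName = setName)
}

# Random chemotype table under the current RNG state.
randomTable <- function(maxN = 40, maxC = 50) {
  N <- sample(1:maxN, 1)
  ChemotypeTable(stats::setNames(sample(1:maxC, N, replace = TRUE),
                                 sprintf("k%03d", seq_len(N))))
}

# Midpoint-Riemann oracle for the area under the piecewise-linear CSR
# curve: the midpoint rule is exact on each linear segment, so subdividing
# every segment gives the area independently of the trapezoid formula.
riemannAUC <- function(curve, subdiv = 64L) {
  p <- curve@points
  total <- 0
  for (k in seq_len(nrow(p) - 1L)) {
    h <- (p$x[k + 1L] - p$x[k]) / subdiv
    mids <- p$x[k] + (seq_len(subdiv) - 0.5) * h
    ymid <- p$y[k] + (mids - p$x[k]) / (p$x[k + 1L] - p$x[k]) *
      (p$y[k + 1L] - p$y[k])
    total <- total + sum(ymid) * h
  }
  total
}

# Set-arithmetic Tanimoto oracle on bit-index sets.
tanimotoOracle <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  u <- length(union(ia, ib))
  if (u == 0) 0 else length(intersect(ia, ib)) / u
}

# Plain double-loop oracle for the mean pairwise Euclidean set distance.
setDistanceOracle <- function(du, dv) {
  tot <- 0
  for (i in seq_len(nrow(du))) for (j in seq_len(nrow(dv)))
    tot <- tot + sqrt(sum((du[i, ] - dv[j, ])^2))
  tot / (nrow(du) * nrow(dv))
}

# Small curated set from SMILES without touching disk.
curatedSet <- function(smiles, name = "test") {
  deduplicateLibrary(curateLibrary(librarySetFromSmiles(smiles, name)))
}
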