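---
title: "Consensus diversity analysis of compound libraries"
author: "ConsensusDiversity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus diversity analysis of compound libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(ConsensusDiversity))
```

## The problem

"How diverse is this screening library?" has no single answer: a set of
compounds can look diverse through one molecular representation and
monotonous through another. A collection dominated by open-chain
(acyclic) molecules has almost no scaffold diversity — nearly everything
shares one chemotype — while its whole-molecule fingerprints can be very
dissimilar, because the diversity lives in the side chains. Conversely, a
set of singleton scaffolds can still be tightly clustered in property
space. This package quantifies library diversity under three independent
representations and condenses them into one low-dimensional display, the
*Consensus Diversity Plot* (CDP), in which each library is a single point
classified into one of four high/low diversity quadrants.

## Chemotypes and scaffold diversity

The unit of scaffold counting is the **chemotype**: the framework of a
molecule obtained by iteratively deleting terminal (degree-1) atoms until
none remain, which leaves all rings plus the linkers between them with
atom and bond types intact. All ring-free molecules share the single
reserved chemotype `ACYCLIC`. Collapsing the acyclic compounds onto one
chemotype is deliberate: it reproduces the characteristic behaviour of
food-additive and toxicant collections in which a large fraction of the
molecules share a single chemotype precisely because they are open
chains.

Two conventions were genuinely open and are settable:

* **Exocyclic multiply-bonded atoms.** A carbonyl oxygen on a ring is a
  degree-1 atom and is pruned by default; `keepExocyclic = TRUE` retains
  any terminal atom held by a bond of order ≥ 2 (and consequently the
  chain carrying it). Scaffold conventions differ on this point; the
  default follows the plain terminal-deletion rule.
* **Chemotype keys** are canonical SMILES of the framework, produced by
  the OpenBabel canonicalizer (via ChemmineOB), so keys are invariant
  under input atom ordering. Stereo annotations inside rings are not part
  of the key.

From a `ChemotypeTable` (counts $c_i$ over $N$ chemotypes, $M = \sum c_i$
compounds, $N_{sing}$ singletons) the package computes:

* **Count ratios** $N/M$, $N_{sing}/N$, $N_{sing}/M$, kept at full
  precision and conventionally rounded to 3 decimals (round-half-even)
  in written outputs.
* **Cyclic system recovery (CSR) curves**: with chemotypes sorted by
  descending population (ties broken by ascending key so output is
  deterministic), point $k$ is $(k/N,\ \sum_{i \le k} c_i / M)$, anchored
  at $(0,0)$. The **AUC** integrates this curve; the default trapezoid
  rule reproduces the exact bound $AUC = 1/2$ for an all-singleton
  library. A staircase convention ($\sum (1/N)\, y_k$ over right edges)
  is available. For $N = 1$ the two-point trapezoid curve degenerates to
  the diagonal and yields 0.5; the minimum-diversity limit 1.0 is
  approached asymptotically as one chemotype dominates a large table (the
  staircase convention does return 1.0 at $N = 1$).
* **$F_{50}$**: the smallest $k/N$ whose cumulative compound fraction
  reaches 0.5 — a discrete coverage fraction, no interpolation. Low AUC
  and high $F_{50}$ both indicate high scaffold diversity.
* **Shannon entropy** $SE = -\sum_i p_i \log_2 p_i$ with $p_i = c_i/P$,
  and the **scaled Shannon entropy** $SSE = SE / \log_2 n$ over the $n$
  most populated chemotypes. The selected top-$n$ population is
  renormalized ($P$ = compounds in the selected chemotypes), $n$ is
  clamped to $N$, and $SSE = 0$ when a single chemotype is selected. The
  default profile grid is $n = 5, 10, \dots, 70$, which probes whether
  the dominant chemotypes are evenly or unevenly populated.

## Fingerprint diversity

Whole-molecule structural diversity is measured over all
$M(M-1)/2$ unordered compound pairs with the Tanimoto coefficient
$|A \cap B| / |A \cup B|$ on either 166-bit MACCS keys or ECFP4
fingerprints (OpenBabel's implementations; ECFP4 is hashed into the
toolkit's native 4096-bit space, wide enough that collisions are
negligible at desk scale). No pair sampling is done. The distribution is
reported as a seven-number summary; quartiles use linear interpolation
between order statistics (`stats::quantile` type 7, the convention of
the statistical environment these summaries are usually produced in),
and the standard deviation uses the $n-1$ denominator. A pair of empty
fingerprints is reported as similarity 0 — featureless molecules are
treated as maximally dissimilar rather than identical — with a warning.
The median similarity is the fingerprint axis of the CDP: *lower*
similarity means *higher* diversity.

## Property diversity

Six descriptors of pharmaceutical relevance are computed per molecule:
hydrogen-bond donors and acceptors, Wildman–Crippen-type logP, molecular
weight (Da), Ertl topological polar surface area (Å²), and rotatable
bonds. The rotor definition counts acyclic single bonds between two
non-terminal atoms, excluding bonds adjacent to a triple bond — under
this rule ethanol has RTB = 0. The acceptor count is the SMARTS-defined
(not N+O) variant. Descriptor values come from published open algorithms
and will differ slightly from proprietary engines; the toolkit version is
recorded on every output.

The distance between libraries $D_u$ and $D_v$ is the mean Euclidean
distance over all ordered pairs of property vectors,

$$I_{uv} = \frac{1}{UV} \sum_{i=1}^{U} \sum_{j=1}^{V}
  \mathrm{euclidean}(\mathbf{x}_i, \mathbf{y}_j),$$

applied verbatim with $u = v$ for the intra-set distance (self-pairs
included, divisor $U^2$; an `excludeSelf` option drops them). Because raw
MW and TPSA would otherwise dominate the sum, the six columns are
standardized by pooled z-scoring over all compared sets before distances
are taken (`--no-scale` disables this). Published intra-set distances in
the low single digits are only reproducible on a standardized scale,
which is why scaling is the default; whether and how the original
analyses scaled is not documented, so both modes exist. Zero-variance
columns are centered with a unit divisor and flagged.

## The consensus plot

Each library becomes one record: median fingerprint similarity on x, a
scaffold metric on y (AUC, $F_{50}$, or an $SSE_n$), intra-set property
distance mapped to a green → orange → red fill (normalized min–max over
exactly the compared sets, red = most property-diverse), and point
*area* proportional to library size $M$ (square-root radius, the
standard perceptual choice). Thresholds given as `"median"` resolve over
the compared sets; the conventional worked default for AUC is a fixed
0.75. Fingerprint diversity is HIGH iff the median similarity is
strictly below the x threshold; scaffold diversity is HIGH iff y beats
its threshold in the metric's own direction (below for AUC, above for
$F_{50}$/SSE — the direction is forced by the metric, not settable).
Values exactly on a threshold classify as LOW: a conservative,
documented tie rule. Quadrants: red = high/high, white = low/low, blue =
fingerprint-only, yellow = scaffold-only. The x axis plots similarity
itself (not 1 − similarity); the axis label states the direction to
avoid misreading.

## The synthetic generator

Because the historical test collections are commercial or undeposited,
correctness is established on synthetic libraries with *exact* ground
truth. A `librarySpec` fixes the number of scaffolds, the count
distribution (uniform, Zipf with exponent $s$, or explicit counts), the
acyclic fraction, the decoration budget and the seed. Each cyclic
molecule is a pool scaffold (122 curated ring systems shipped as plain
text; every entry is a framework fixed point) decorated with a side
chain drawn from a fixed menu of 70 acyclic substituents, attached by
SMILES prefixing. Substituents cannot create or destroy rings, and the
menu was validated pairwise-distinct on a reference scaffold, so the
generated census equals the intended census exactly — the pipeline is
required to recover it molecule for molecule, not statistically.
Acyclic members come from a distinct-by-construction family of
functionalized chains. Deterministic largest-remainder apportionment
turns Zipf weights into counts (every scaffold gets at least one
compound), and increasing $s$ provably concentrates the population —
the monotone diversity control used in the tests.

What the generator does *not* emulate: realistic medicinal-chemistry
size/property distributions, stereochemistry, tautomerism, or salt
forms. Passing the recovery tests therefore demonstrates the counting
and metric machinery is exact, not that curation handles every
real-world registration artifact.

## Curation

The wash is a documented simplification: split multi-component
structures, keep the component with the most heavy atoms that contains
at least one carbon (ties broken by lexicographically smallest canonical
SMILES), neutralize formal charges where a proton can be added or
removed without changing connectivity (OpenBabel's `neutralize`
transform), re-canonicalize, then deduplicate on canonical SMILES (first
occurrence wins). Records with no carbon-containing component are
rejected with a reason code. The procedure is idempotent, which the test
suite asserts. No tautomer or stereo normalization is attempted; what
protonation "rebalancing" should mean beyond neutralization is
underdetermined, and the chosen rule is flagged here deliberately.

## Numerical choices and problem sizes

Ratios and entropies are computed in double precision from integer
counts; sorting ties break by chemotype key; reported rounding is 3
decimals, round-half-even. The AUC implementation is cross-checked
against a midpoint-Riemann oracle (exact on linear segments) to 1e-12 on
1000 random tables per test run, entropy against an independent ecology
implementation, and the set distance against a double loop on sets of up
to 30 rows; distances are computed with `stats::dist` rather than the
Gram-matrix expansion to avoid catastrophic cancellation near zero. The
test suite exercises synthetic libraries of up to 1000 molecules and
pairwise similarity sets of up to a few hundred pairs, sizes at which
the whole suite completes in about a minute on a single core while still
covering every code path end to end.

## A worked example

```{r example, eval = FALSE}
specs <- list(
  diverse = librarySpec(60, 60, "uniform", seed = 1),
  skewed  = librarySpec(12, 120, "zipf", zipfExponent = 2, seed = 2),
  acyclic = librarySpec(5, 80, "uniform", acyclicFraction = 0.6, seed = 3))
sets <- lapply(names(specs), function(nm) {
  s <- deduplicateLibrary(curateLibrary(generateLibrary(specs[[nm]])$set))
  s@name <- nm
  s
})
an <- analyzeLibraries(sets)
cr <- consensusRecords(an, yMetric = "auc")
cr$records[, c("set_name", "x_fp", "y_value", "quadrant")]
plotCDP(cr$records, cr$thresholds)
```

## Known limitations

* The chemotype definition is a Murcko-style framework; scaffold engines
  that use ring-assembly naming or generic graph abstraction will count
  differently in edge cases.
* Descriptor values are toolkit-specific; comparisons against numbers
  produced with other engines hold at the level of trends, not digits.
* The trapezoid AUC of an $N = 1$ table is 0.5 (see above); single-
  chemotype libraries are better compared via $F_{50} = 1$ or the
  staircase convention.
* Property distances depend on the standardization population: adding a
  library to a comparison changes the pooled scale and hence every
  distance slightly.
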