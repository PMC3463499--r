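---
title: "Inferring and assessing gene regulatory networks with msanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and assessing gene regulatory networks with msanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msanet)
```

## The problem

A developmental cell-fate decision — for instance the choice between
mesodermal (muscle) and ectodermal (skin) fate in an embryonic cell
lineage — is controlled by a network of mutually regulating transcription
factors. Perturbation experiments (gene knockdown followed by expression
profiling, one-hybrid DNA-binding assays, genetic-interaction tests) reveal
that network directly, but they are expensive and rarely exhaustive.
Wild-type developmental time courses, by contrast, are cheap and abundant.
`msanet` implements a complete pipeline for asking: *how much of the
perturbation-derived network can be recovered from wild-type time-course
data alone?*

Three kinds of networks are involved:

* a **gold standard network** (GSN) built by explicit evidence rules from a
  curated table of perturbation, one-hybrid and genetic-interaction
  results;
* a **mathematically inferred model** (MIM) reverse-engineered from
  wild-type expression time courses by combining covariance analysis with
  the Minimal Sets Algorithm;
* optional **knowledge-driven models** encoded from published network
  figures under temporal-phase and tissue blocking constraints.

A bespoke assessment framework compares any model to the gold standard with
half-right-aware precision/recall and ROC statistics, per-module feature
subnetworks, and signed distances from the random-guess diagonals.

## The mixed-graph container

All networks share one representation (`gene_network`): a square adjacency
matrix over node identifiers where entry $(i, j)$ describes the ordered
pair (target $i$, source $j$):

* $+1$ — a directed edge, gene $j$ regulates gene $i$ (the regulator sits
  in the **column**);
* $-1$ — an undirected interaction, stored symmetrically, so one
  undirected edge occupies two cells;
* $0$ — an evidenced **non-interaction**, which is information, not
  absence of information;
* `NA` — an unknown pair.

The distinction between $0$ and `NA` drives the whole assessment design:
only pairs where *both* matrices commit to something are scored. The
canonical file format is an adjacency CSV whose unknown cells carry the
token `-`, never an empty cell.

Self-regulation cannot be detected by knockdown assays, so gene-level
networks have a structural $0$ diagonal; probe-level matrices may carry
self-loops internally (the inference machinery can propose them) but they
are discarded when probes are collapsed to genes.

## Building the gold standard

For an ordered pair (target $i$, regulator $j$) an evidence record carries
`sig` (Z-score significance of the expression change after perturbing
$j$), `mag` (fold change), `y1h` (number of one-hybrid interactions), and
`gen` (signed count of genetic-interaction reports; positive =
directional expression reports, negative = non-directional synthetic
interactions). `classify_evidence()` applies, in priority order:

1. $+1$ if (`sig` $\ge 2$ and `mag` $\ge 2$) or (`sig` $\ge 2$ and
   `y1h` $\ge 1$) or (`gen` $\ge 2$) or (`sig` $\ge 2$ and $|$`gen`$| = 1$);
2. $-1$ if $|$`gen`$| \ge 2$;
3. $0$ if `mag` $=$ `sig` $=$ `y1h` $= 0$;
4. unknown otherwise.

Every directed call therefore rests on at least two independent pieces of
evidence. The priority order means directional evidence beats undirected
evidence (e.g. `gen` $= +3$ satisfies both the first and second
predicates and is called $+1$), and an explicit all-zero record is the
only way to assert a non-interaction — a missing record stays unknown.
Two rules are deliberately configurable because the underlying
conventions vary between curation efforts: the one-hybrid clause can
require exactly one hit (`exact_y1h`), and when an undirected call meets
a directed call on the reverse ordered pair `build_gsn()` keeps the
directed edge and drops the undirected mark with a warning.

## The inference pipeline

`run_pipeline()` executes, deterministically:

1. **Discretization** (`discretize()`). Each probe is binned independently
   into at most $q$ states (default $q = 7$), jointly across all series so
   bins are shared. When a probe takes $k \le q$ distinct values each value
   becomes its own state; otherwise equal-frequency (rank) binning is used,
   with equal-width and single-linkage agglomerative binning selectable.
   The distinct-value rule makes discretization an exact inverse of the
   synthetic state-to-abundance map at zero noise, which is what allows the
   round-trip tests to demand exact recovery.
2. **Transition extraction** (`extract_transitions()`). Consecutive time
   points within a series form (input state vector, output state) pairs;
   series are independent replicates and transitions never cross a series
   boundary, so $S$ series of length $T$ yield $S(T-1)$ transitions.
3. **Minimal Sets Algorithm** (`minimal_sets()`). For each target, every
   pair of transitions with different target outputs contributes a
   *difference set* — the variables whose inputs differ. Any set of
   regulators able to explain the target must intersect every difference
   set, so the complete space of minimal explanations is the antichain of
   minimal hitting sets, enumerated exactly (Berge-style incremental
   construction, verified against exhaustive subset search in the tests).
   A constant target yields the empty set: no regulators are needed.
   Inconsistent transitions (identical inputs, different outputs — possible
   after discretization) are an error by default; a lenient mode drops the
   later transition with a warning.
4. **Model selection** (`select_model()`). Candidate sets violating the
   no-crosstalk constraint (an ectoderm probe regulating a mesoderm-module
   target or vice versa) are discarded unless all candidates violate it —
   the constraint is applied *wherever possible*. Among survivors the set
   with the strongest **consistency evidence** wins: a set whose input
   projection partitions the $u$ unique transitions into $m$ classes was
   consistent with the data with probability $q^{-(u-m)}$ under a
   random-function null, so $u - m$ measures how surprising — hence how
   credible — its consistency is. Ties are broken by a frequency score
   (the normalized product of each member's frequency across the family, a
   reconstruction of a published model-scoring scheme), then by smaller
   size, then lexicographically. We rank the evidence score first because
   the frequency score alone leaves large tie strata whose lexicographic
   resolution systematically favours whichever probe happens to sort
   first, producing correlated false positives; the evidence ranking is
   data-driven and removes that bias. A `scorer` hook allows substituting
   any other scheme.
5. **Covariance adjacency** (`covariance_adjacency()`). The probe × probe
   sample covariance matrix (pooled over all time points, $n-1$ divisor)
   is thresholded at the **median of the entire matrix** (diagonal
   included, ties at the median kept, signed values by default with an
   absolute-value switch). Cells at or above the threshold become
   undirected interactions. The median is chosen because it reliably
   couples the probe sets of multi-probe genes — duplicate probes covary
   near-maximally — while halving the candidate pair space.
6. **Combination** (`combine_msa_cov()` / `combine_cov_msa()`). MSA-COV
   keeps every directed MSA edge and adds undirected covariance edges for
   pairs with no directed edge in either direction; COV-MSA lets
   covariance decide *which* pairs interact and MSA only orient them, so
   its directed edges are always a subset of MSA-COV's. Undirected
   self-loops are discarded, and multi-probe genes are collapsed by
   unanimity: a gene-pair entry is $\pm 1$ only if **all** probe-pair
   entries agree, otherwise $0$.

A provenance record (parameters, covariance threshold, every family with
scores, chosen and discarded sets) accompanies the result and serializes
to JSON.

## Assessment

Models are scored against a gold standard over six ordered-pair domains:
`Overall` (all off-diagonal pairs), `P` (pairs whose source is the master
regulator), and strict/wide module subnetworks `E(s)`, `E(w)`, `M(s)`,
`M(w)` (both endpoints in the module vs at least one). Per pair:

| model \\ gold | $+1$ | $-1$ | $0$ |
|---|---|---|---|
| $+1$ | TP | TP | FP |
| $-1$ | HR | TP\* | FP\* |
| $0$ | FN | FN | TN |

Pairs with an unknown cell in either matrix are skipped. HR
("half-right") is a model's undirected edge where the gold standard is
directed; it contributes weight $0.5$ to the modified rates:

$$\mathrm{TPR} = \frac{TP + 0.5\,HR}{TP + 0.5\,HR + FN + 0.5\,HR},\qquad
  \mathrm{PPV} = \frac{TP + 0.5\,HR}{TP + 0.5\,HR + FP},\qquad
  \mathrm{FPR} = \frac{FP}{FP + TN}.$$

The starred cells are combinations the scheme leaves open; the defaults
(model $-1$ vs gold $-1$ = TP, both assert the interaction; model $-1$ vs
gold $0$ = FP) are configurable and recorded in every report. Zero
denominators yield *undefined* rates — a value, not an error — which
contribute $0$ to summaries and are flagged.

Because each feature yields a single classifier point rather than a
curve, performance is summarized by the signed Euclidean distance of that
point from the random-guess diagonal: in ROC space
$\sqrt{2}\,(\mathrm{TPR}-\mathrm{FPR})/2$ from $y = x$, in PR space
$\sqrt{2}\,(\mathrm{recall}-1+\mathrm{precision})/2$ from $y = 1 - x$,
negative below the line. A single point can be at most $\sqrt{2}/2
\approx 0.7$ from the diagonal; the **total distance** — the sum over the
six features in both spaces, 12 signed terms — is at most $6\sqrt{2}
\approx 8.49$ and is the headline comparison statistic. A model also gets
a prediction count ($TP+TN+HR+FP$ over `Overall`) and a correct count
($TP+TN+0.5\,HR$).

Scoring is over ordered pairs by default, so a symmetric undirected edge
occupies two cells and is counted twice; an unordered mode (each pair
counted once, the two cell classifications merged with precedence
TP > HR > FP > FN > TN) is available.

## The synthetic ground truth

Because the real curated tables and time courses live in external
supplements, the package carries a generator that emulates every input
kind with known structure. `generate_network()` draws a random directed
graph (each ordered pair an edge with probability `density`, default
0.15), assigns module labels in the study's proportions (initiation 3 :
ectoderm 4 : mesoderm 3 : mixed 3 : other 2), and equips each node with a
random $q$-state update table over its parents, defining a finite
dynamical system. `simulate_timecourse()` runs independent trajectories
from random initial states (defaults: 2 series, emulating two genotypes
profiled over one developmental window; 10 time points each) and maps
states to abundances affinely, with optional Gaussian noise.
`generate_evidence()` writes an evidence table whose records satisfy a
randomly chosen directed-rule clause for every true edge and are all-zero
for every non-edge, with an optional corruption rate into the unknown
region. `probe_split()` duplicates selected genes' rows into jittered
probes to exercise the collapse and covariance-coupling machinery.

What the generator does *not* emulate: realistic microarray noise (dye
bias, saturation), unequal series lengths, missing values, and continuous
dynamics. Passing the recovery tests therefore demonstrates the
correctness of the machinery and the identifiability behaviour of the
method under its own model class — not performance on real microarray
data.

### What recovery runs show

On noise-free data from a 10-gene, density-0.15, $q = 3$ truth (20 time
points × 2 series), the MSA-COV pipeline's directed edges score a
positive total distance against the truth in roughly nine out of ten
seeded replicates, with the median comfortably positive. The failures are
informative: they are replicates whose dynamics freeze early (only a
handful of unique state vectors among the 38 transitions), leaving
minimal-set families too ambiguous for any data-driven selector — a
selection oracle with access to the truth still resolves them, confirming
the gap is identifiability of the data draw, not the enumeration. Noise
degrades recovery monotonically on average. Recovery is scored on the
directed edges because the undirected covariance layer asserts roughly
half the pair space by construction of the median threshold, which
against a fully known truth measures the threshold, not recovery.

## Numerical and design choices

* **Path lengths** treat undirected edges as traversable both ways and
  exclude unreachable pairs from the mean by default (counting them as
  $|nodes|$ is available); degrees count directed edges only, with
  undirected degree reported separately, and hubs are nodes with
  out-degree strictly greater than half the network.
* **Diagonal** cells are excluded from collapse output, path lengths,
  motifs, degrees, and every assessment domain.
* **Mixed collapse conflicts** (some probe pairs $+1$, others $-1$)
  yield $0$: the unanimity rule fails for both signs.
* **Problem sizes in the test-suite**: oracle-equivalence suites run
  1000 random hitting-set instances (≤ 10 variables) and dozens of random
  mixed graphs (≤ 20 nodes); recovery runs 50 replicates of the 10-gene
  system. These sizes give exact, exhaustive cross-checks while keeping
  the default suite fast.
* **Determinism**: every generator takes a seed and every pipeline stage
  is deterministic given its inputs; repeated runs produce byte-identical
  artifacts.

## Limitations

The evidence-rule thresholds are those of the source curation and are not
re-estimated; the scoring scheme for minimal sets is a reconstruction
(the original algorithm's publication is not reproduced here) behind a
pluggable interface; covariance thresholding always asserts about half
the matrix, so the undirected layer should be read as a candidate
coupling set rather than calibrated interaction calls; and assessment
counts each feature once per space with equal weight, which overweights
small module domains when summed.
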