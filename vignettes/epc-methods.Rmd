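---
title: "SSE-graph structure comparison: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSE-graph structure comparison: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epcr)
```

## The model

A protein chain is reduced to its secondary structure elements (SSEs) and
represented as a mixed graph `G = (V, A, E)`: vertices are the helices and
strands in N-to-C order, the arcs form the directed path `0 -> 1 -> ... ->
n-1` given by chain order (stored implicitly), and undirected edges mark
spatial contacts between SSEs. Comparing two structures then asks for a
largest common subgraph respecting vertex kinds, chain order (optionally)
and contacts.

The central reduction: every candidate correspondence `g_i -> h_j` becomes
a vertex of an auxiliary *conflict* graph, and two candidates are joined
exactly when they cannot coexist in one valid alignment —

1. they reuse an endpoint (`i = k` or `j = l`);
2. they cross in chain order (`i < k` and `j > l`, or the mirror image);
   applied only in sequential mode;
3. the query SSEs are in contact but the host SSEs are not.

Independent sets of this graph are exactly the valid partial alignments
(the package asserts this equivalence exhaustively in its tests), so
alignment reduces to enumerating top-K maximal independent sets. Condition
2 is stated once in the literature with a single orientation; since
conflict edges are unordered both crossing orientations must be penalised,
and that is what the implementation does. Dropping condition 2 yields
non-sequential alignment: element correspondences free of chain order,
useful for permuted folds.

Condition 3 is deliberately asymmetric. The query plays the "motif" role:
its contacts must be realised in the host, while extra host contacts are
harmless. `epc_compare()` always assigns the query role to the structure
with fewer SSEs.

## Scoring

Residue-level similarity compares local backbone geometry through

`D(d1, d2) = 0.1 - |d1 - d2| / (d1 + d2)`,

which is 0.1 exactly when the two distances agree and decays towards -0.9.
`L_ij` is the minimum of `D` over three Cα distance windows around residue
`i` of one chain and `j` of the other: `(i-2, i+2)`, `(i-2, i+1)` and
`(i-1, i+2)` (the same offsets on the `j` side). An SSE pair's score slides
the shorter element ungapped along the longer and keeps the best sum of
`L_ij`; an alignment's raw score `S` sums its SSE-pair scores.

Numerical edge cases, fixed as follows:

* `D(0, 0) = 0.1` — two degenerate identical segments are identical.
* Near chain ends, `L_ij` minimises over the windows whose residues all
  exist in both chains; a residue pair with no valid window contributes 0.
  This keeps every SSE scorable, at the price that the first/last chain
  residues carry no signal.
* `L_ij` windows deliberately extend beyond the SSE into flanking loops,
  so an identical element transplanted into a different chain context
  scores below its self-match at the edges. This is what makes
  self-recognition sharp.

`Sn = S / (lA * lB)` is used only for cross-protein ranking. The plain
product of chain lengths is dimensionally unusual (many methods normalise
by the geometric mean); it is implemented exactly as defined, and because
ranking is the only use, any strictly monotone renormalisation would
reorder nothing within one query. CORE-COV is the matched fraction of the
smaller structure's SSEs.

## Parameters

* `r` (default 5) — candidate images per query SSE, chosen per SSE as the
  top-r same-kind partners by pair score. Bounds the auxiliary graph at
  `r * n` vertices. Candidates never cross kinds: the mixed-graph model
  distinguishes helix and strand vertices.
* `K` (default 1000) — number of enumerated maximal independent sets kept
  for rescoring. The first set is always a maximum independent set; larger
  K lets a slightly smaller set with better geometric scores win.
* `contact_threshold` (default 8 Å) — minimum inter-Cα distance defining
  an SSE contact; 8 Å is the standard Cα-contact convention.
* Trimming (off by default) — an optional score filter on auxiliary
  vertices (`min_score` floor or per-query-SSE `keep_frac`). The
  literature mentions trimming for speed without specifying a rule, so it
  is an explicit opt-in rather than a hidden heuristic; any trimming rule
  changes which top-K sets are reachable.
* SSE segmentation: helix = runs of DSSP `H` of length >= 4, strand = runs
  of `E` of length >= 3; `G`, `I` and `B` count as loop. The source method
  assumes SSEs given and states no minima; these follow common SSE-graph
  practice and keep small fixtures predictable.

## Enumeration and determinism

The enumerator is a pivoted branch-and-bound over (chosen, candidate,
excluded) sets in the compatibility (complement) relation, recording
maximal independent sets and pruning any branch whose `|chosen| +
|candidates|` cannot reach the current K-th best cardinality. Sets are
ordered by cardinality (descending), then total vertex score (descending),
then lexicographically by member ids — a total order, so outputs are
byte-reproducible and the top-K list for a smaller K is a prefix of the
list for a larger K. "Top-K" is read over *maximal* sets: this makes
K = 1000 meaningful even when the maximum independent set is unique. An
exhaustive subset-scan oracle (`brute_force_top_k`, guarded to 20
vertices) validates the enumerator on hundreds of random graphs in the
test suite.

**Best-alignment selection.** Any subset of an independent set is itself a
valid alignment. Each enumerated set is therefore reduced to its
non-negative-score members before the final S maximisation: a
negative-scoring pair is a geometrically dissimilar match that could only
lower S, and — because enumeration returns only *maximal* sets — keeping
such pairs would even break the expected monotone improvement of S in K
and r (a bad candidate admitted at larger r forces itself into every
maximal superset of the previous optimum). Ties in S go to the larger
set, then to the lexicographically first pair list.

## The width-2 exact solver

When every query SSE is restricted to at most two images, exact embedding
is polynomial: one Boolean variable per (vertex, image), clauses enforcing
(a) exactly one image per vertex, (b) injectivity plus order preservation
along the two spanning paths, and (c) contact preservation; the formula is
2-CNF and solved by the implication-graph / strongly-connected-components
algorithm, with the satisfying assignment chosen by condensation
topological order (deterministic). Because both arc sets are spanning
paths, the order condition for a total injective map reduces to index
comparison, and its biconditional and one-directional variants coincide;
the verifier still exposes both modes for clarity.

## Synthetic data: what it emulates, what it does not

`toy_protein()` builds idealized Cα traces — helices with 1.5 Å rise,
2.3 Å radius and 100° turn per residue, strands with 3.5 Å steps, loops of
3 residues between elements — and emits matching PDB and DSSP text, so the
full parsing pipeline is exercised without downloads. Layouts from
`random_toy_spec()` space elements 4–12 Å apart (plus the helix radius per
neighbour) so realistic contact graphs of varying density arise.

Ideal geometry has one unrealistic consequence: every helix is
geometrically identical to every other helix, which would make
self-recognition vacuous. Protein banks for ranking tests therefore apply
0.3 Å Gaussian jitter to each protein's coordinates (deterministic per
seed), emulating the structural individuality of real chains; planted
substructure targets reuse the query's *jittered* coordinates verbatim, so
"the target contains the query" holds exactly. What passing these tests
shows: the pipeline recovers correspondences that are geometrically
present and conflict-free. What it does not show: performance on real
folds with distorted, bent or partially unwound elements, alternative
DSSP dialects, or crystal-structure artifacts — no claim is made there.

The CLIQUE reduction supplies instances whose optimum is known from an
independent brute-force clique search, tying parser-free ground truth to
the whole independent-set route at map width 1.

## Problem sizes in the shipped tests

Enumeration is verified against the exhaustive oracle on 200+ random
graphs of 8–15 vertices at edge densities 0.2/0.4/0.6; the
independence/validity equivalence exhaustively on 100+ instance pairs with
up to ~10 auxiliary vertices in both order modes; the 2-SAT solver on 200+
width-2 instances with up to 6 query SSEs against full list-choice
enumeration; the CLIQUE triangle on 100+ graphs of up to 9 vertices;
self-query and planted-substructure recovery on 20-protein banks; and the
K/r monotonicity of best S on 10 fixture pairs with K up to 1000 and r up
to 9. These sizes keep the whole suite under two minutes on one CPU while
leaving every property asserted at full strength.

## Known limitations

* Enumeration is exponential in the auxiliary graph size (`r * n`
  vertices); comfortable for SSE-scale graphs (tens of vertices), not for
  residue-scale ones.
* Secondary structure must be supplied (DSSP output or the exchange
  format); the package does not assign it from geometry, and mmCIF input
  is out of scope.
* One chain per comparison; multiple-structure alignment is not
  implemented.
* No residue-level superposition, RMSD or TM-score; scores are SSE-level
  only.
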