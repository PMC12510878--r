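---
title: "Joint RNA structure and 3D motif prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint RNA structure and 3D motif prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structured RNAs conserve more than their canonical helices. Short recurrent
arrangements of non-Watson-Crick pairs in loop regions — RNA 3D motifs such
as the GNRA tetraloop, the K-turn, loop E, or junction motifs — shape the
tertiary fold. These motifs are short (4–20 nt), sequence-variable, and
carry little covariation of their own, so scanning for them in isolation
produces many false positives. Helices, in contrast, do covary: compensatory
substitutions in alignments identify them reliably. RNAMotifFold exploits
this asymmetry: covariation pins down the helices, the helices pin down the
loops, and a single probabilistic grammar then decides jointly which loops
harbour which motifs.

## The model

### A probabilistic sequence

The object folded is not one sequence but an alignment summarized as a
*probabilistic sequence*: for every retained column $o$ a nucleotide
frequency vector $p_o(a)$, $a \in \{A,C,G,U\}$, and for every column pair a
joint $4 \times 4$ frequency computed from the sequences ungapped at both
columns. Columns with more than 75% gaps (tunable, `gapMax`) are removed
first; such columns are dominated by alignment insertions that do not
belong to the conserved core. All emission terms of the grammar are
mixtures over these distributions, e.g. a match state with emission
$P_S(a)$ scores a column as $\sum_a p_o(a) P_S(a)$; on a single sequence
the distributions are point masses and the model reduces to ordinary
sequence scoring.

### The helix/loop grammar

The core is a stochastic context-free grammar over nonterminals
S, F0, F5, P, J3, J4, JN, BB, BT, M1 and R:

```
S  -> a S | F0 S | end
F0 -> a F5 a' | a P a'          (base-pair emission)
F5 -> a F5 a' | a P a'          (stacked-pair emission)
P  -> m..m                      (hairpin loop, >= 3 nt)
    | m..m F0 | F0 m..m         (left / right bulge, >= 1 nt)
    | m..m F0 m..m              (internal loop, >= 1 nt per side)
    | J3 | J4 | JN              (multiloops)
J3 -> BB BB BT                  J4 -> BB BB BB BT
JN -> BB BB BB M1 R             M1 -> BB M1 | BB
BB -> m..m F0                   BT, R -> m..m
```

F0 opens a helix, F5 extends it with stacking-aware pair emissions, and P
chooses the loop that ends it. Three-way (J3) and four-way (J4) junctions
are singled out from higher multiloops (JN) because they are by far the
most common junctions in structured RNAs and host many known motifs.
Unpaired runs `m..m` follow geometric length laws with context-specific
minima (hairpin 3, bulge 1, internal loop 1 per side, multiloop segment 0).
The grammar is unambiguous: a given set of base pairs and motif placements
has exactly one derivation, which is what makes training by counting and
probability-based model comparison meaningful. The test suite verifies
unambiguity by exhaustive enumeration of all derivations on small inputs.

### Motif sub-grammars

A motif library (a plain-text descriptor file, one motif per line) assigns
each motif to one of six architectures: hairpin loop (HL), bulge (BL),
internal loop (IL), three-way junction (J3), four-way junction (J4), and
branch segment (BS). A descriptor lists consensus *segments* — for an HL,
correlated flanks L1/R1 (up to three nested pairs of flanks) around a loop;
for an IL, outer and inner stem segments plus the two loop strands; for
junctions, one segment per branch; for BS, a single strand. Motifs bounded
by more than one helix are expanded into all their topological *variants*
(which helix is the external attachment): 2 for BL and IL, 3 for J3, 4 for
J4. Variants whose (class, ordered element tuple) coincide are redundant
and merged; the count of nonredundant variants is reported in the run log.

Each loop-bearing rule of the grammar gains one alternative per matching
variant. The probability split is mass-conserving: a trained generic loop
probability $p$ and a curated class fraction $f$ give the generic rule
$p(1-f)$ and each of the $n$ motifs in the class $pf/n$ — equal shares by
maximum entropy, deliberately avoiding any per-motif weighting for which
no training data exist. The class fractions default to
(HL, BL, IL, J3, J4, BS) = (0.4, 0.4, 0.5, 0.2, 0.2, 0.2).

### Motif sequence segments: profile HMMs

Each consensus segment is scored by a small profile HMM with one match
state per consensus position, emission on transition, a shared insert
distribution (uniform by default, overridable from a parameter file) and
deletion bypasses. Match emissions follow the mismatch rule: a consensus
class of size $c$ gives each in-class residue $(1-(4-c)\varepsilon)/c$ and
each out-of-class residue $\varepsilon = 10^{-4}$; so a 'U' position emits
U with 0.9997 and an 'R' position emits A and G with 0.4999 each.

The transition layout is a two-parameter family chosen for its closed form:
a geometric insert-extension probability $q$ at each of the $L_c+1$ slots
and a fixed per-position delete probability $d = 0.01$. The expected
emitted length is $L_c(1-d) + (L_c+1)\,q/(1-q)$, and $q$ is solved so this
equals $L_c + \min(0.1\,L_c,\ 1.5)$ — segments slightly longer than
consensus on average, capped at 1.5 extra. An empty consensus keeps an
expected length of 0.5 so that empty segments can still absorb insertions
(otherwise an empty-segment motif could never match a divergent instance).
Segment probabilities are forward sums over all state paths; within a
motif, the split of a loop region into its consecutive segments is part of
the emission model (optimized in the CYK, summed in the inside algorithm),
not a separate derivation choice.

## Decoding

`foldCYK()` computes the maximum-probability derivation by dynamic
programming over spans of the probabilistic sequence, `insideLogProb()`
the summed probability; both honour constraints. Multiway rules are
binarized through internal helper tables, keeping the cost at
$O(L^3 \times M)$ for $M$ motif nonterminals. Forced pairs are hard: a
forced position may pair only with its partner and may not stay unpaired.
Forbidden pairs and unpairable positions score $-\infty$.

Numerical choices worth knowing:

* All arithmetic is in log space; probability-zero cells are $-\infty$.
* Stacked pairs condition the inner pair on the outer pair. On alignments
  the exact 4-column joint is unavailable from pairwise statistics, so the
  stacked emission mixes the stack table over the product of the two pair
  joints.
* Tie-breaking in the traceback is a fixed deterministic order: generic
  loop before motif, unpaired before paired, shortest run and leftmost
  split first. Outputs are therefore reproducible run to run.
* Generic bulge/internal runs are capped at 30 nt per side and motif
  segments at consensus length + 8 columns (options `maxBulge`,
  `maxIntLoop`, `maxMlRun`, `segSlack`); these bound the inner loops of the
  DP and are far above the sizes the geometric run laws or the profile
  HMMs give appreciable mass to.
* Bulge and internal-loop *motif* regions may match zero columns (all
  segments deleted); the call is still reported, with an empty span, which
  keeps the grammar's variant semantics uniform across classes.

## Covariation layers

Positive (significantly covarying) and negative pairs normally come from an
external covariation analyzer via a TSV (`readPairsTSV()`). A built-in
approximate statistic (`covariationStandin()`) is available for
self-contained runs: average-product-corrected mutual information with
E-values estimated as the mean count of equal-or-better pairs in
column-shuffled controls (an expected-false-positive-count estimate). It is
deliberately labelled an approximation — it implements no phylogenetic
correction, so on deeply structured phylogenies it will over-count
covariation relative to a phylogeny-aware analysis.

`decomposeLayers()` splits the positive pairs into mutually nested layers,
layer 1 of maximum cardinality (interval dynamic programming, verified
against exhaustive search in the tests). Layer 1 is folded with the full
motif grammar, forcing its pairs and forbidding negatives. Each later layer
is folded with a small unambiguous nested grammar
(`S -> L S | L; L -> aFa' | a; F -> aFa' | L S`, stacking-aware pair
emissions), forcing that layer's pairs and forbidding negatives and all
pairs already placed; of its output only helices containing a forced
covarying pair are retained, since later layers exist solely to place
non-nested covariation (pseudoknots, triplets, alternative helices).
Overlaps between layers are reported, never resolved.

A motif call is flagged *supported* when at least one of its bounding
helices — the helix closed by its loop's closing pair plus, for
multibranch motifs, each enclosed helix — contains a positive pair. For
branch-segment motifs the bounding helices are taken as the multiloop's
closing helix and, when the segment precedes a branch helix, that helix.
Helices are maximal stacks of adjacent pairs; a lone pair counts.

## Training

`trainByCounting()` estimates all transition probabilities and emission
tables from (sequence, structure) pairs; unambiguity makes each annotated
structure a unique derivation (`structureToParse()`). Every rule and
emission cell carries a +1 pseudocount. The default parameter set is
trained on a small bundled collection of literature-style secondary
structures and then anchored: the generic hairpin-loop probability is set
to 0.3475 and the multiloop mass is split 51% / 32% / 17% among three-way,
four-way and higher junctions, reflecting the junction frequencies
observed in large curated structure sets; the remaining loop-rule mass is
rescaled proportionally. Everything can be overridden from a JSON parameter
file with a bit-exact round trip (`writeParamsJSON()`/`readParamsJSON()`).

## The synthetic generator, and what passing tests mean

`generateAlignment()` plants covarying helices (each sequence keeps a
reference canonical pair with probability $1-\text{rate}$, else draws a
random canonical pair — a compensatory substitution) and motif instances
(consensus with iid per-position mutations) into iid background columns.
The benchmark conditions (`benchmarkSpecs()`) use 40 sequences,
compensatory rate 0.6 and motif mutation rate 0.05 — a moderately diverged
structural alignment — with a GNRA tetraloop closed by a covarying helix
and a K-turn internal loop framed by covarying outer and inner helices.
The generator has no phylogeny, no indels, and no alignment error; passing
the benchmark therefore shows that covariation constraints help when the
alignment is correct and the null model is iid, not that the method is
robust to misalignment or phylogenetic autocorrelation. Test problem sizes
(alignments of 46–60 columns, 20 replicates; enumeration oracles at length
up to 8; 10^4 sampled derivations for parameter recovery) were chosen so
the full suite exercises every code path at desk scale.

## Known limitations

* The covariation stand-in is not phylogeny-aware; external pair lists are
  the intended evidence path.
* Motif boundaries are reported as the loop span of the hosting rule; for
  internal-loop and junction motifs this span includes the enclosed
  helices.
* Sequence weighting is accepted but defaults to uniform; no tree-based
  weighting is implemented.
* The bundled motif library covers a core set of well-documented motifs;
  it is meant to be extended through descriptor files rather than being
  exhaustive.
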