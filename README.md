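# RNAMotifFold

Joint prediction of RNA consensus secondary structure and RNA 3D motifs
from multiple sequence alignments, constrained by covarying base pairs.

## What it does, and for whom

Structured RNAs place recurrent 3D motifs — GNRA tetraloops, K-turns,
loop E, junction motifs, protein-binding branch segments — in the loop
regions between their canonical helices. These motifs are short and
sequence-variable, so scanning for them on their own floods you with false
positives. Helices, however, reveal themselves through compensatory
(covarying) substitutions in an alignment. RNAMotifFold is for RNA
bioinformaticians who have a structural alignment (e.g. a curated seed
alignment) and want, in one shot: the consensus secondary structure
(including pseudoknots with covariation support), the 3D motifs placed in
its loops, and a statement of which motif calls are backed by covariation
in their bounding helices.

## The model in brief

The fold is a maximum-probability parse of a *probabilistic sequence* —
per-column nucleotide frequencies $p_o(a)$ and per-column-pair joint
frequencies — under one stochastic context-free grammar:

* a helix/loop grammar (`S, F0, F5, P, J3, J4, JN, BB, BT, M1, R`) with
  stacked-pair emissions and explicit three-way/four-way junction rules;
* one sub-grammar per motif *variant* from a plain-text descriptor library
  (six architectures: hairpin, bulge, internal loop, J3, J4, branch
  segment), whose consensus segments are scored by profile HMMs with
  mismatch probability $\varepsilon = 10^{-4}$ and expected length
  $L_c + \min(0.1 L_c, 1.5)$;
* a mass-conserving split of each generic loop probability $p$ into
  $p(1-f)$ (generic) and $pf/n$ per motif (equal shares by maximum
  entropy), with class fractions $f$ = (0.4, 0.4, 0.5, 0.2, 0.2, 0.2) for
  (HL, BL, IL, J3, J4, BS).

Covarying pairs (from an external analyzer's TSV, or a built-in
approximate statistic) are decomposed into nested layers: layer 1 — the
maximum nested subset — constrains the CYK parse of the full motif
grammar; later layers place pseudoknotted/tertiary helices with a small
nested grammar. Motif calls are flagged *supported* when a bounding helix
contains a covarying pair. See `vignettes/motif-folding.Rmd` for the
complete model description.

## Worked example

Plant a GNRA tetraloop (loop columns 16–19) closed by a covarying helix in
a 40-sequence synthetic alignment, then run the pipeline with the known
pairs as covariation evidence:

```r
library(RNAMotifFold)
spec <- plantSpec(nSeq = 40, length = 46,
  helices = data.frame(i5 = 12, j3 = 23, len = 4, rate = 0.6),
  motifs = list(list(name = "GNRA", consensus = "GAAA", start = 16,
                     end = 19, mutRate = 0.05)),
  seed = 7)
ga <- generateAlignment(spec)
writeStockholm(ga$msa, "example.sto")
writeLines(c("i\tj\tE\tclass",
  sprintf("%d\t%d\t0.0010\tpositive",
          ga$truth$pairs[, 1], ga$truth$pairs[, 2])), "pairs.tsv")
res <- runPipeline("example.sto", pairs = "pairs.tsv", outDir = "out")
motifCalls(res)[, c("name", "class", "start", "end", "logScore", "supported")]
```

which prints

```
input: example.sto (40 sequences x 46 columns)
motif library: 10 descriptors (bundled)
total nonredundant motif variants: 17
parameters: bundled defaults
gap filter (gapMax = 0.75): kept 46 of 46 columns
covariation: external pair list pairs.tsv
positive pairs: 4 in 1 layer(s); negative pairs: 0
fold: log probability -77.0456; 19 pair(s) in layer 1; 1 motif call(s)

  name class start end  logScore supported
1 GNRA    HL    16  19 -5.666547      TRUE
```

The four forced pairs seeded a helix that the grammar extended; the GNRA
call sits exactly on the planted loop (columns 16–19), and it is
`supported` because its closing helix carries covarying pairs. The log
score is the motif subtree's log-probability contribution. `out/` holds an
annotated Stockholm file (`#=GC SS_cons` consensus structure in WUSS-style
brackets, pseudoknot layers in letter brackets, plus a `#=GC R3D` line
marking motif spans), a motif TSV, and a run log:

```
#=GC SS_cons <<<<<<<<<<.<<<<....>>>>>>>>>>>>>><<<<<...>>>>>
#=GC R3D     ...............1111...........................
```

A shell front end with the same options (including `--r3dfile` for a
custom motif descriptor library) is in `inst/scripts/foldrna.R`.

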