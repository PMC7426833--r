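---
title: "Assembly-based PAP genotyping of Gag-like retroelements: models and methods"
author: "retropap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-based PAP genotyping of Gag-like retroelements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-terminal-repeat (LTR) retrotransposons move by a copy-and-paste
mechanism, so related plant accessions differ in which insertions they
carry: a locus occupied in one genome can be empty in another.  These
presence/absence polymorphisms (PAPs) matter for fruit biology because an
element inserted near a gene can rewire its expression — in melon,
sequences carrying the retrotransposon Gag domain (InterPro IPR005162) are
frequently induced in post-harvest ripening fruit, and the genes flanking
them often share that expression pattern.

`retropap` implements the full comparative-genomics workflow around this
observation as reusable, tested R functions: genotyping element PAPs
directly from genome assemblies, classifying cross-genome gene
partnerships, linking element PAPs to ripening-inducible expression of
flanking genes, and testing candidate sets for term enrichment.  Because
the real multi-gigabase accession assemblies are not tractable on a
desktop, the package ships a synthetic-genome simulator with exact ground
truth; every claim the pipeline makes is validated by recovery of known
simulated events.

## Alignment model

The aligner is a k-mer seed-and-chain local aligner, the desk-scale
stand-in for whole-genome aligners used on real assemblies:

* **Anchors** are maximal runs of strictly contiguous shared exact
  k-mers (default `k = 15`, both strands; k-mers seen more than 64 times
  in the target are ignored as repetitive).  There are no
  substitution-tolerant seeds; SNP-level divergence is handled by chaining
  across broken anchors, which is adequate because simulated divergence is
  held at or below 1%.
* **Chains** maximize matched bp minus a linear gap penalty
  (0.01/bp, gaps capped at 20 kb per join) by sparse dynamic programming.
  Anchors may overlap a chain join by up to `k` bp — a chance k-mer can
  extend an anchor a few bases across a breakpoint — and the overlap is
  trimmed off the downstream block, so reported blocks are strictly
  colinear and non-overlapping on both axes.
* **Alignment ratio** of a query interval is the fraction covered by the
  union of aligned block query-intervals: 1.0 means the interval is
  completely present in the target, 0 that it is absent.

Where the original assembly workflows invoke BLAST with stringent
thresholds (e-value ≤ 1e−150, score ≥ 1000), the package maps that intent
to a minimum chain score of 1000 matched bp; there is no attempt to
reproduce BLAST statistics or any specific aligner's output block for
block.

## PAP genotyping

For each Gag-like element the reference window `[start − flank,
end + flank)` is extracted (default flank 50 kb; values up to 100 kb are
accepted, matching the 50–100 kb windows used on real genomes).  The
window is located in each target assembly by best-matching region (the
BLAST-n analog, chain score ≥ 1000), the window is re-aligned against that
region, and the alignment ratio is measured **over the element span
only** — the only denominator under which 1.0 can mean "the element is
completely present".  Calls use an explicit three-state rule: `present`
at ratio ≥ 0.8, `absent` at ≤ 0.2, `ambiguous` between; if the flank
itself cannot be located the cell is `missing`.  The 0.8/0.2 thresholds
are a design choice — only the endpoints (1.0 present, 0 absent) are
externally defined — and both are exposed as parameters.

Accessions are clustered on the numeric ratio matrix (not the binarized
calls) with `stats::hclust`, complete linkage on Euclidean distances —
plain R `hclust` defaults.  Missing ratios are imputed by the element mean
for clustering only; rows are sorted lexicographically first so the tree
does not depend on input order.  Dendrograms serialize to Newick with leaf
branch lengths equal to merge heights.

## Orthology and CNV/PAP classification

Gene partnership between two annotated genomes uses two similarity
channels: transcript DNA 15-mers and protein 4-mers, scored by set
containment (|shared k-mers| / |query k-mers|; hits below 0.3 dropped).
A pair is a **one-to-one orthologue** when it is reciprocal best in both
channels *and* the query transcript's best-matching genomic region in the
partner genome overlaps the partner gene's locus (the transcript-alignment
confirmation).  A query whose top containment is tied between several
subjects — the signature of a recent duplication — is deliberately not
paired; such pairs demote to homologue partners.  With diverged (SNP
carrying) copies the tie resolves genuinely, and whichever copy loses the
reciprocal-best contest is classified as the tandem CNV; recovery is
therefore asserted per duplication *event* (exactly one partner and at
least one `tandem_dup_cnv` among parent and copy), not per copy label.

Unpartnered genes are classified by position: `tandem_dup_cnv` when the
best within-genome homologue (containment ≥ 0.5) lies on the same sequence
within 100 kb and at most 5 intervening genes (the tandem definition is a
package choice; no external definition exists), `non_tandem_cnv_pap` when
homologues exist elsewhere or when the transcript has no genomic hit in
the partner at all (the PAP signature), and `unanchored` for genes on
non-chromosome sequences.  One-to-one partners receive consensus ids
`<partner_id>.jh1`.

## Expression analysis

FPKM matrices are filtered at 0.1 by default in keep-if-any-sample mode;
the stricter all-samples reading is available via `mode = "all"` because
the two natural readings of a "below 0.1" filter genuinely differ, and
the at-least-one-sample reading is the one consistent with counting
expressed genes.  A feature is **ripening-inducible** iff its
ripening-group mean is strictly the maximum across tissue-group means
(a `min_fold` parameter can require dominance over the runner-up; the
default 1.0 is a pure argmax).  **Neighbor co-expression** takes, for each
query locus, the nearest annotated gene on each side within 50 kb
(edge-to-edge; "neighboring gene" has no external definition, and 50 kb is
a safe superset of the promoter-scale distances that motivate the
analysis), computes Pearson r on raw FPKM vectors (a `log2p1` switch
exists but is off, matching correlation "based on FPKM values"), and
reports the fraction of pairs with r > 0.8 for three query sets: all genes
(control), ripening-inducible elements, and other elements.

## Term enrichment

Fisher's exact test is implemented directly from the hypergeometric
distribution (two-sided: the sum over tables with the observed margins
whose probability does not exceed the observed table's) and is verified
exhaustively against enumeration for every table with total ≤ 40.
Multiple testing uses Benjamini–Hochberg step-up values — equivalent to
Storey q-values with the null proportion fixed at 1, hence a deterministic,
conservative upper bound that needs no density estimation.  The background
excludes the foreground by default (`bg_includes_fg` switches the
convention, which is otherwise unspecified).

## Assembly-editing rules

Two bespoke rules are implemented exactly: contigs are split where
per-base read depth is **less than four** (retained runs shorter than
100 bp are dropped — a floor the package defines, since none is externally
given), and scaffolds are joined when the two terminal windows of a hint
sequence align to two *distinct* scaffolds with chain identity ≥ 0.99,
aligned length ≥ 5000 bp and score ≥ 1000.  Joins insert a fixed 100-N gap
(gap sizing is otherwise unspecified; a fixed sentinel keeps outputs
deterministic) and are resolved greedily by descending combined score,
each scaffold end used at most once, cycles refused.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested.  Defaults: 10 accessions, two 1-Mb chromosomes, 200 protein-coding
genes (one or two exons, both strands, clean reading frames), 40 Gag-like
elements of 2–7 kb (bracketing the 1956 bp and 6941 bp elements that
motivate the analysis), presence flips at 0.15 per unit branch, 0.5%/bp
SNPs, 0.05%/bp small indels, 2% tandem duplication and 2% gene loss per
gene, contig N50 target 200 kb, eight tissue groups × 3 samples, ripening
fraction 0.386 and neighbor co-expression fraction 0.594 (the empirical
fractions the pipeline must recover).

Design choices worth knowing:

* **Tree.** Accessions evolve along a fixed caterpillar tree whose last
  three leaves form a tight clade with branch lengths 0.1 (versus 1
  elsewhere); branch length scales the flip probability as
  `1 − (1 − p)^len`.  The short clade mimics a cultivar trio of common
  recent origin and gives the clustering-recovery test a known answer: the
  expected clade-internal Hamming distance (~2.6 of 40 elements) sits far
  below the nearest outsider's (~11).  Any Newick tree can be substituted.
* **Guard zones.** SNPs land anywhere except within 50 bp of a feature
  boundary; indels are restricted to intergenic space.  This keeps truth
  coordinates exact and reading frames intact — testability is valued
  over mutational realism.
* **Excision.** Element deletion removes the exact span (clean PAP); the
  `ragged_breakpoints` option jitters each breakpoint by up to ±200 bp so
  the alignment-ratio score is also exercised on partial states.
* **Duplication.** A tandem duplicate is the *ancestral* sequence inserted
  immediately right of the (SNP-carrying) parent, so the two copies differ
  slightly — the realistic hard case for reciprocal-best orthology.
* **Expression.** Log-scale group-mean model: baseline Normal(2,1) plus
  Normal(0,1) per-group effects; ripening elements replace their ripening
  effect with a fixed +3; co-expressed flanking genes inherit their
  element's group-mean profile plus Normal(0, noise); samples add
  Normal(0, noise); FPKM = max(exp(x) − 0.05, 0).  Two coherence rules
  keep truth labels recoverable rather than blurred: a feature whose truth
  label is *not* ripening-inducible is never allowed to peak in the
  ripening group by accident (its ripening effect is swapped with the
  runner-up group), and co-expression status is drawn once per flanking
  *gene*, because a gene flanking two ripening elements shares the
  dominant ripening spike with both and a per-pair label could not be
  recovered from correlations.
* **Seeding.** One integer seed drives everything; stages reseed at fixed
  offsets (reference +0, accessions +1, fragmentation +2, expression +3)
  so any stage can be re-run in isolation, byte-identically.

What the generator does **not** emulate: read-level data and sequencing
error, recombination, target-site duplications, nested insertions, GC and
repeat structure of real genomes, and distributional realism of FPKM.
Passing tests therefore demonstrate that the pipeline's logic recovers
known events under controlled divergence — not that it is robust to every
artifact of real assemblies.

## Problem sizes and numerical choices

The test suite runs the full default scale (10 accessions × 2 Mb) for PAP
and orthology recovery once each (clean and ragged), 50 seeds for the
expression-fraction and clade-recovery checks (at low per-sample noise,
0.1, for the parameter-recovery checks), 100 constructed pairs for the
alignment-ratio sweep, and the exhaustive Fisher sweep to table total 40.
Unit tests use a smaller single-chromosome configuration (300 kb, 40
genes, 8 elements, 4 accessions).  Ties in the ripening argmax break to
"not inducible"; best-hit ties break by higher containment, longer
subject, then lexicographic id; chain ties by longer aligned length,
lexicographic sequence id, then smaller target start.  Correlations on
constant vectors are undefined and propagate as missing, excluded from
fraction denominators.

## Known limitations

* Exact k-mer anchoring degrades above a few percent divergence; the
  aligner is not a general-purpose WGA tool.
* `non_tandem_cnv_pap` is a single category with evidence sub-labels
  (`no_genomic_hit` vs `homologue_elsewhere`); the package does not
  attempt to split CNV from PAP beyond that evidence.
* Chance k-mer matches across excision junctions can graze an element
  span by a few bases, so "absent" ratios are near, not exactly, zero.
* The clustering stage assumes a complete ratio matrix after imputation;
  accessions with mostly missing cells will cluster on imputed means.
* Pearson correlation on raw FPKM is dominated by the largest values;
  that is intentional (it is what the assay prescribes), but users wanting
  scale-robust co-expression should pass `log2p1 = TRUE`.
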