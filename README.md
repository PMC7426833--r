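# retropap

Assembly-based genotyping of retrotransposon presence/absence
polymorphisms (PAPs), for comparative genomics of related plant
accessions.

## The problem

LTR retrotransposons copy themselves into new loci, so closely related
genomes differ in which insertions they carry.  Sequences carrying the
retrotransposon Gag domain (InterPro IPR005162) are of particular interest
in fruit crops: they are frequently induced during post-harvest fruit
ripening, and genes flanking them often share that expression pattern —
a plausible mechanism by which transposition rewires ripening physiology.

`retropap` implements the analysis chain around that observation as
tested R functions:

* **k-mer seed-and-chain alignment** with an *alignment ratio* score: the
  fraction of a query interval covered by aligned blocks (1.0 = the locus
  is completely present in the target genome, 0 = absent);
* **PAP genotyping**: each element plus 50 kb of flanking sequence is
  located in every target assembly, re-aligned, and scored over the
  element span; the elements × accessions ratio matrix is then clustered
  (`hclust`, complete linkage, Euclidean) to a dendrogram of accessions;
* **orthology**: reciprocal best hits on transcript (DNA 15-mer) and
  protein (4-mer) containment plus transcript-to-genome confirmation give
  one-to-one orthologue pairs; unpartnered genes classify as tandem
  duplication CNVs, non-tandem CNV/PAP candidates, or unanchored; one-to-one
  partners receive consensus ids (`<partner_id>.jh1`);
* **expression**: FPKM filtering (≥ 0.1), fruit-ripening-inducible
  classification (ripening group strictly maximal), and Pearson
  co-expression (r > 0.8 on raw FPKM) between elements and their nearest
  flanking genes within 50 kb;
* **enrichment**: two-sided Fisher exact tests (hypergeometric
  enumeration) with Benjamini–Hochberg control;
* **assembly rules**: contig splitting where read depth < 4, and
  hint-guided scaffold joining (identity ≥ 0.99, aligned length ≥ 5 kb,
  score ≥ 1000, 100-N gaps);
* **a synthetic-genome simulator** producing a reference, derived
  accession genomes with known element presence flips, duplications,
  losses, SNPs and indels, fragmented contig assemblies, and a tissue-wide
  expression matrix with configurable ripening (default 38.6%) and
  neighbor co-expression (default 59.4%) fractions — with exact truth
  tables, so every pipeline stage is validated by recovery.

## Worked example

A complete synthetic experiment on the default study conditions
(10 accessions, two 1-Mb chromosomes, 200 genes, 40 Gag-like elements):

```r
library(retropap)

cfg <- run_config(seed = 1, sim = sim_config(seed = 1))
res <- run_end_to_end(cfg, "run1")
```

The run log prints one line per stage; with seed 1 the headline numbers
are:

```
[simulate] seed=1 accessions=10
[simulate] genes=200 elements=40
[pap] cells=400 concordance=1.0000 sign_errors=0
[cluster] planted_clade_recovered=TRUE
[orthology] acc01 recall=1.0000 false_pairs=0
[expression] ripening_fraction=0.2250 neighbor_coexpr=0.5000
[enrichment] top_term=IPR005162 p=3.46e-37
```

Reading these: all 400 element × accession PAP calls match the simulated
truth with no present/absent sign errors; the three accessions planted as
a tight clade are monophyletic in the PAP dendrogram; every simulated
one-to-one orthologue pair between the reference and accession 1 is
recovered with no false pairs; and the Gag-domain term ranks first among
over-represented terms in the CNV/PAP candidate set.  The expression
fractions estimate the simulated parameters (0.386 and 0.594): at this
seed the truth draw itself was 9/40 ripening elements and the classifier
recovered exactly those 9 — single-seed fractions scatter with the
binomial draw, and the acceptance script below aggregates over many
seeds (recovering 39.8% and 62.8% at seed 1).  `run1/` holds the PAP ratio/call matrices, the accession dendrogram
in Newick, partner calls, ripening calls, neighbor-pair correlations with
the histogram table, the enrichment table, truth tables, and a JSON
manifest echoing every parameter.

Individual stages are plain functions (`simulate_reference`,
`derive_accessions`, `build_pap_matrix`, `cluster_accessions`,
`call_one_to_one`, `classify_cnv_pap`, `filter_expressed`,
`call_ripening_inducible`, `neighbor_coexpression`, `enrich`,
`split_low_depth`, `hint_join`, …) that also accept data read from
standard formats via `read_fasta`, `read_gff3`, `read_bed_elements`,
`read_expression_tsv`, and `read_term_table`.

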