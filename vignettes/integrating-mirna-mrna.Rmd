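---
title: "Integrating miRNA and mRNA experiments against local database snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating miRNA and mRNA experiments against local database snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmerge)
```

## The problem

MicroRNAs (miRNAs) repress mRNAs post-transcriptionally, mostly through
partial complementarity between the miRNA's 5' *seed* (mature positions 2-8)
and sites in the target's 3'UTR. When a profiling experiment yields a list of
differentially expressed miRNAs and a list of differentially expressed
mRNAs, the standard integration question is: *which of the altered mRNAs are
plausible targets of the altered miRNAs, and what biology do they point to?*

Answering that requires stitching together several reference resources —
target-prediction databases, miRNA sequence metadata, identifier
cross-reference tables, ortholog maps, GO/KEGG annotation — each with its own
identifier conventions. mirmerge packages that stitching as a set of
composable, pipe-friendly functions that query a *snapshot*: a frozen local
directory of TSV tables standing in for live database queries. Everything is
reproducible offline, and a deterministic synthetic-snapshot generator with a
planted-fact ledger makes every step testable end to end.

The pipeline has three steps, available individually or wired together by
`run_workflow()`:

1. **Consensus target prediction.** Individual prediction algorithms
   (TargetScan-like, microCosm/miRBase-like, miRNA.org-like) have high false
   positive rates; requiring a (miRNA, gene) prediction to appear in at least
   *k* of the consulted sources is the usual remedy. For species that the
   human-centric databases do not cover (zebrafish in the motivating use
   case), experiment miRNAs are first mapped to well-covered homologs through
   a seed-preserving sequence filter.
2. **Multi-level merge** of the target list with the mRNA table: an ordered
   cascade of join relations with per-relation match accounting.
3. **Downstream analysis**: hypergeometric gene-set enrichment against a
   declared background universe, and centroid-linkage hierarchical clustering
   of the merged expression profiles.

## Consensus model

`predict_targets()` evaluates, for each key (a (miRNA, gene) pair at
`level = "pair"`, a gene at `level = "gene"`), a membership flag per source
and an `agreement_count`; keys below `min_agreement` are dropped. Gene-level
flags are unions over the queried miRNAs: a gene "is in" a source if *any*
queried miRNA targets it there. Both levels are exposed because published
consensus counts are often reported on "targets with unique gene symbols"
(a gene-level union) while mechanistic follow-up needs pair-level detail; the
two levels answer different questions and neither is derivable from the
other's output.

Retrievals are truncated at a configurable cap (default 500,000 rows,
`retrieval_cap()`), always with a warning and a `truncated` attribute — a
guard against accidentally materializing a whole database cross-product.

## Seed-preserving homology filter

Cross-species miRNA mapping compares candidate homolog pairs of *mature
sequences* (it does not model miRNA:mRNA hybridization — both sequences are
miRNAs, so the natural comparison is identity, not complementarity):

* sequences are 5'-aligned; `n_mismatch` = Hamming distance over the overlap
  plus the absolute length difference. Mature 3' ends are heterogeneous
  across species and miRBase versions, while the 5' end defines the seed;
  anchoring at the 5' end and charging length differences as mismatches is
  the conservative convention.
* `seed_identical` requires positions 2-8 to agree exactly. A pair passes
  only when `n_mismatch <= max_mismatch` (default 1) *and* the seed is
  identical — one seed edit fails the pair even with a total mismatch budget
  to spare, because seed identity is what preserves the target repertoire.
* DNA alphabet (`T`) and lowercase are normalized silently; a non-ACGU
  character after normalization is an error naming the offending record. A
  mature sequence shorter than 8 nt cannot have an identical full seed and is
  marked `seed_identical = FALSE`; lengths outside 18-26 nt warn but do not
  error.

## The multi-level merge engine

`merge_datasets()` applies relations in the order given: left rows are
compared with all right rows on relation 1's keys; rows still unmatched fall
through to relation 2, and so on. A relation can translate the left key
through the cross-reference table first (e.g. Entrez to gene symbol),
which is how identifiers that failed a direct join get a second chance.
Design choices that the merge semantics leave open:

* **Duplicate keys expand cartesian**, one output row per matching right
  row. This is lossless; `dedupe_rows()` gives the caller the first-match
  alternative explicitly. The per-level `matched` counts are *left rows first
  matched at that level*, so `matched_total + left_unmatched = nrow(left)`
  always holds even when the output has more rows than the left table.
* **Case sensitivity follows the key's namespace**: gene symbols compare
  case-insensitively (zebrafish symbols are lowercase, human uppercase —
  `tp53` and `TP53` are the same join key), everything else exactly. For a
  translated relation the effective namespace is the translation target; for
  a plain relation it is inferred from the column name (contains "symbol"),
  and `merge_relation(case_insensitive = )` overrides the inference.
* Column collisions get `_left`/`_right` suffixes; union mode appends
  unmatched rows from both sides with `NA` fill; the output carries a
  `.merge_level` column for provenance.

## Enrichment

`enrich()` computes, per gene set, the exact hypergeometric upper tail
P(X >= k) with universe size N (the *declared* background — for array
experiments, the genes on the platform, not the genome), set size K, query
size n after intersecting with the universe, and overlap k. P-values are
BH-adjusted across all tested sets; both a raw-p significance flag (to mirror
the common p <= 0.05 reporting convention) and an FDR flag are returned.
This is a deliberately plain stand-in for annotation-clustering tools such
as DAVID: no EASE-style penalized score and no term clustering are
implemented, and no claim is made that its term ranking reproduces such
tools' output. The plain hypergeometric has the advantage of being exactly
checkable against combinatorial enumeration, which the test suite does for
every (N <= 30, K, n, k) configuration at 1e-12.

## Clustering

`hcluster()` implements agglomerative clustering with Euclidean distance and
*exact* centroid linkage (UPGMC): at every step the two clusters with the
closest centroids merge, and the new centroid is the size-weighted mean of
its members. The implementation updates centroids incrementally; the test
oracle recomputes every centroid from the raw member rows at every step, so
agreement between the two is informative. No Lance-Williams update is used —
`stats::hclust(method = "centroid")` expects *squared* Euclidean input and
would not be a drop-in — and heights are genuine Euclidean distances.
Numerical conventions:

* ties (distances within 1e-12) break deterministically toward the
  lexicographically smallest pair of node ids; leaves are numbered 1..n in
  input row order, internal nodes from n+1 in merge order;
* centroid linkage is not monotone: *inversions* (a merge lower than its
  predecessor) are legitimate, kept, and flagged per merge;
* leaf display order is the recursive left-first traversal; Newick export
  (`write_newick()`, via ape) uses height differences as branch lengths,
  which can be negative across inversions;
* a single row, a missing value, or a non-numeric column is an error naming
  the offender — imputation is the caller's decision, not the cluster
  routine's.

## The synthetic snapshot generator

`generate_snapshot()` and `generate_experiment()` produce the whole reference
and experiment universe from a `fixture_spec()`, recording every planted fact
in a TSV ledger so any downstream result can be recounted independently.
Defaults describe a zebrafish-to-human integration study at desk scale:

| parameter | default | rationale |
|---|---|---|
| `n_mirnas`, `n_sig_mirnas` | 42, 42 | a realistically sized significant-miRNA panel for a multi-stage exposure design |
| `mismatch_profile` | 24/9/5/4 | 33 of 42 cross-species pairs survive the seed-preserving <=1-mismatch filter; the failing 9 split between seed edits (5) and two out-of-seed edits (4) |
| `n_sig_genes`, `target_enrichment` | 100, 0.4 | 40 of 100 significant mRNAs are planted consensus targets |
| `n_conserved_pairs`, `n_two_source_pairs` | 25, 30 | planted 3-source and exactly-2-source pairs, each on a distinct gene, so consensus membership is fully ledger-recorded |
| `background_rate` | 0.02 | sparse single-source noise; a background candidate already present anywhere is skipped, keeping background pairs single-source by construction |
| `n_genes`, `n_terms`, `mean_terms_per_gene` | 300, 40, 3 | small enough for sub-second generation, large enough that unions, backgrounds and annotation overlaps are non-trivial |
| `ortholog_fraction` | 0.8 | most but not all genes bridge to the other species, so the no-ortholog path is always exercised |

One GO term is *planted enriched*: its membership is built to cover the
planted consensus-target genes, and the experiment generator draws planted
target rows preferentially from it, so the integrated pipeline should rank it
first. The source species is annotated at 30% of the destination's term
rate, emulating the sparse annotation that motivates ortholog-bridged
annotation in poorly annotated model organisms.

What the synthetic data does **not** emulate: real sequence composition
(sequences are uniform random 22-mers), the heavy-tailed degree
distributions of real target databases, miRNA families with shared seeds,
many-to-many orthology, or database-version drift. Passing tests demonstrate
the *bookkeeping* is exact — set logic, merge accounting, planted-structure
recovery — not that any biological prediction is accurate; prediction quality
is entirely inherited from whichever real snapshot tables the user supplies.

## Workflow conventions

`run_workflow()` uses the merge cascade gene symbol, then Entrez, then
Entrez translated to gene symbol — direct joins first, a translated join to
catch rows whose symbol was missing. An optional anti-correlation filter
(off by default) keeps only merged genes with at least one significant
regulator whose mean fold change has the opposite sign; repression is the
primary miRNA mechanism, but transcripts are retained by default since
indirect and feed-forward effects need not anti-correlate. Every artifact is
written with a provenance header (semantic config hash and snapshot version;
the timestamp line is the single permitted difference between re-runs), and
an empty miRNA input propagates to empty, well-formed outputs rather than an
error.

Test-suite problem sizes were chosen to keep the whole suite fast while
leaving no code path unexercised: 20 random snapshots of up to 20 miRNAs and
200 genes for the consensus oracle, 1,000 random sequence pairs for the
homology oracle, 50 random matrices of up to 12 rows for the clustering
oracle, and exhaustive hypergeometric enumeration up to N = 30.

## Known limitations

* Predictions come only from snapshot tables; there is no de novo 3'UTR
  site scanning, so a miRNA absent from every source simply warns.
* Homolog candidates are paired by name stem (`dre-miR-21` with
  `hsa-miR-21`) before sequence filtering; divergently named homologs are
  not discovered.
* Percent identity in the ortholog table is carried opaquely — whether it is
  nucleotide or amino-acid identity is a property of the upstream resource,
  not interpreted here.
* The workflow attaches one Entrez id per target gene (the lexicographic
  minimum) for its merge cascade; genes with genuinely multiple Entrez ids
  rely on the symbol relation.
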