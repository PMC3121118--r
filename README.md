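# bidipromoter

Genome-wide analysis of **bidirectional promoters** — the short intergenic
regions shared by head-to-head gene pairs — for researchers studying
promoter architecture and co-regulation. Two genes on opposite strands whose
TSSs lie less than 1 kb apart share the intervening sequence as one
promoter; this package classifies such pairs from a refGene-style transcript
table, contrasts their promoters against uni-directional promoters (the
fixed 1 kb upstream of genes with no opposing TSS within 10 kb and no
same-strand TSS within 1 kb upstream), and characterizes what distinguishes
them.

The quantities at its core:

* **CpG islands** under two presets — Gardiner-Garden (GC ≥ 0.50,
  Obs/Exp ≥ 0.60, ≥ 500 bp) and strict (GC ≥ 0.55) — with
  Obs/Exp = (#CpG × L) / (#C × #G), called by a pinned
  window–merge–verify–trim algorithm.
* **GO enrichment** of pair genes: hypergeometric upper tail P(X ≥ k) on
  propagated annotations, Benjamini–Yekutieli adjusted per namespace, plus
  within-pair shared-term analysis on direct annotations and Fisher/BH
  gene-set (GMT) enrichment.
* **TFBS fold enrichment**: both-strand log-odds PWM scanning
  (JASPAR- and TRANSFAC-dialect matrices), hits per kb of promoter sequence,
  fold = bidirectional rate / uni rate, classified over-represented
  (fold ≥ 2), shared, or under-represented (fold ≤ 0.5).

A seeded synthetic-data generator plants gene layouts
(divergent/convergent/tandem/isolated), promoter composition contrasts,
motif instances, and ontology annotations with a ground-truth manifest, so
the entire pipeline is testable without any external genome downloads.

## Worked example

The numbered scripts under `analysis/` run the study end to end on the
synthetic bundle (seed 1):

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_classify_pairs.R
Rscript analysis/03_promoters_cpg.R
Rscript analysis/04_go_enrichment.R
Rscript analysis/05_tfbs.R
```

which prints, among other things:

```
60 transcripts -> 60 clusters -> 15 bidirectional pairs, 29 uni-directional genes
planted-pair recovery: 15/15 (100.0%)
gardiner_garden  islands in 86.7% of bidirectional vs 0.0% of uni promoters (mean GC 49.7% vs 45.4%)
strict           islands in 73.3% of bidirectional vs 0.0% of uni promoters (mean GC 49.7% vs 45.4%)
7/15 pairs (46.7%) share at least one direct GO term
  MOTIF1    4.28 vs  0.86 hits/kb, fold  4.96 -> over-represented
  MOTIF2    3.17 vs  3.28 hits/kb, fold  0.97 -> shared
  MOTIF3    0.41 vs  3.03 hits/kb, fold  0.14 -> under-represented
```

Reading: all 15 planted head-to-head pairs are recovered exactly; CpG
islands concentrate in the bidirectional promoters under both criteria
(pairs whose intergenic gap is too short to host a 500 bp island account for
the remainder); the within-pair GO sharing matches the planted 0.5
probability; and the motif planted at 5× the uni rate comes out
over-represented while the equal-rate motif stays shared. Stage tables land
under `results/` as plain TSV/BED.

The same flow is available as one call:

```r
library(bidipromoter)
bundle <- generate_bundle(simulation_config(seed = 1), "synthetic")
res <- run_pipeline(pipeline_config(
  genes = bundle$paths$genes, genome = bundle$paths$genome,
  obo = bundle$paths$obo, annotations = bundle$paths$annotations,
  jaspar = bundle$paths$jaspar, transfac = bundle$paths$transfac,
  out_dir = "out"))
```

See `vignettes/bidirectional-promoters.Rmd` for the model definitions,
parameter choices and the algorithm pinned for island calling.

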