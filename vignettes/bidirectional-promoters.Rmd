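---
title: "Classifying bidirectional promoters and their regulatory signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bidirectional promoters and their regulatory signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidipromoter)
```

## The problem

A sizeable fraction of vertebrate genes sit head-to-head: two genes on
opposite strands whose 5' ends face each other with transcription start
sites (TSSs) less than 1 kb apart. The intervening sequence — the
*bidirectional promoter* — drives both genes at once, and such promoters are
reported to be unusually CpG-rich, to regulate functionally related gene
pairs, and to carry a distinctive complement of transcription-factor binding
sites (TFBS). `bidipromoter` implements that whole analysis as a reusable,
tested pipeline:

1. collapse a refGene-style transcript table into strand-specific,
   non-overlapping gene clusters;
2. classify bidirectional gene pairs and uni-directional genes;
3. extract promoter sequences from a genome FASTA;
4. detect CpG islands under two criteria presets and contrast the classes;
5. test GO term enrichment of pair genes and within-pair term sharing;
6. scan promoters with position weight matrices (PWMs) and classify each
   motif's fold enrichment.

Because the genome-scale inputs (assembly FASTA, refGene table, GO releases,
commercial matrix libraries) are large, versioned, external downloads, the
package ships a seeded synthetic-data generator that plants every signal the
pipeline is supposed to detect, with a ground-truth manifest. All tests and
the acceptance script run against that generator.

## Definitions and the classification model

All coordinates are 0-based half-open throughout (the refGene and BED
convention); 1-based coordinates exist only in rendered reports. The TSS of
a plus-strand feature is its span start; of a minus-strand feature, its span
end.

**Clusters.** Within each (chromosome, strand), transcripts whose spans
overlap *or abut* merge transitively into one cluster (under the half-open
convention abutting spans leave no intergenic base, so they are one
transcription unit). The cluster TSS is the 5'-most member TSS. Transcript
tables often assess multiple TSSs per gene; taking the 5'-most maximizes the
intergenic promoter and is the common convention — the alternative
(per-transcript TSSs, relying on pair deduplication to absorb the
redundancy) would multiply borderline pairs without changing the intergenic
intervals analysed. The cluster's evidence class is the best among members
(`NM` curated mRNA > `NR` curated non-coding > `XM`/`XR` predicted >
other); predicted models are always excluded from analysis, and the default
analysis set is NM-only.

**Bidirectional pair.** Two adjacent clusters on opposite strands in
divergent orientation — the minus-strand TSS at or below the plus-strand
TSS — with TSS distance strictly below 1 kb (`max_distance = 1000`, so a
999 bp gap pairs and a 1000 bp gap does not). Adjacency means no third
cluster's TSS lies strictly between the two. Divergent clusters whose gene
bodies overlap are accepted as long as the TSS order is divergent with
distance ≥ 0; a negative distance (minus TSS downstream of the plus TSS) is
convergent geometry and never pairs. Pairs sharing an identical intergenic
interval are redundant; exactly one is kept (lexicographically smallest
(plus symbol, minus symbol) — an arbitrary but deterministic tie-break).

**Uni-directional gene.** The field definition is usually quoted as a
disjunction ("no opposite TSS within 10 kb upstream, or a same-strand TSS at
least 1 kb upstream"), whose two clauses pull in opposite directions; read
literally it classifies almost everything. We implement the conjunction —
*both* no opposite-strand TSS within 10 kb upstream *and* no same-strand TSS
within 1 kb upstream — because only that reading guarantees the clean 1 kb
of 5'-flanking DNA that the definition exists to provide. Upstream distances
are tested as 0 < d ≤ window, so a neighbour exactly at the window boundary
still violates it. Because the 10 kb opposite-strand window subsumes the
1 kb pairing bound, a pair member can never be uni-directional; a property
test asserts this disjointness on random layouts.

## Promoter extraction

The bidirectional promoter is the entire intergenic interval
`[minus TSS, plus TSS)`; a distance-0 pair has no promoter and is skipped
with a warning. For CpG analysis, intervals shorter than 1 kb are extended
symmetrically to exactly 1 kb so they can host a full-length island; an odd
deficit puts the extra base on the left (arbitrary, fixed for determinism),
and clamping at a chromosome end shifts the shortfall to the other side.
Extension is idempotent. A `pure_ig` switch skips extension so composition
can be compared on unmodified intergenic sequence. Extension may run into
the flanking gene bodies; no avoidance is attempted because none is defined
— a known limitation.

The uni-directional promoter is the fixed `[TSS − 1000, TSS)` window
(mirrored for minus-strand genes), truncated and flagged at chromosome ends.

Sequences are always fetched from the forward strand: a bidirectional
promoter has no canonical strand, GC and CpG observed/expected are invariant
under reverse complement (CpG is its own reverse complement), and motif
scanning covers both strands, so the choice is observable only in logged
sequences, never in statistics.

Motif scanning uses the *unextended* intergenic promoters: the extension
exists solely to satisfy the island length definition, and padding the
intervals with flanking sequence would dilute per-kb motif rates with bases
that are not promoter.

## CpG islands

Two presets follow the classic thresholds: `gardiner_garden`
(GC ≥ 0.50, observed/expected CpG ≥ 0.60, length ≥ 500 bp) and `strict`
(GC ≥ 0.55, same ratio and length). The ratio uses the Gardiner-Garden
denominator,

$$\mathrm{Obs/Exp} = \frac{\#\mathrm{CpG} \times L}{\#C \times \#G},$$

with `L` the length excluding `N`; the alternative `((#C+#G)/2)^2`
denominator is *not* used anywhere. `N` bases are excluded from both sides
of the GC fraction, break the CpG dinucleotide (an `N` between `C` and `G`
is not a CpG), and a sequence with no `C` or no `G` has ratio 0 by
definition rather than a division error.

Island callers in the literature are scripts without pseudocode, so the
algorithm is pinned exactly here for reproducibility:

1. slide a window of exactly `min_length` bp in 1-bp steps; mark windows
   meeting both thresholds;
2. merge overlapping or abutting marked windows into candidates;
3. verify each merged candidate as a whole; while it fails, trim 1 bp from
   whichever end most improves the currently failing statistic (GC is
   checked before Obs/Exp; ties trim the left end), discarding candidates
   that drop below `min_length`;
4. report the surviving disjoint regions left to right.

The trim rule in step 3 is stated ambiguously in most descriptions
("alternately" versus "whichever end"); we pin the greedy best-end variant
with the fixed statistic order and tie-break above, which makes the caller
deterministic. Window statistics are computed from cumulative sums whose
arithmetic is bit-identical to a naive per-window recount; the test suite
verifies the covered-base set against an exhaustive brute-force oracle on
hundreds of seeded sequences spanning GC 0.3–0.7 under both presets, plus
monotonicity in the thresholds and strand symmetry of island coordinates.

## Functional enrichment

Term enrichment uses the upper-tail hypergeometric probability
$P(X \ge k)$ for `k` of `n` study genes carrying a term that `K` of `N`
population genes carry (delegated to `stats::phyper`, exact and stable; an
exhaustive draw-enumeration oracle covers every parameter combination with
N ≤ 12 in the tests). The population defaults to all clusters surviving the
evidence filter. Annotations are propagated to `is_a` ancestors first (the
true-path rule, as any GO enrichment requires). Multiple testing uses
Benjamini–Yekutieli — Benjamini–Hochberg scaled by the harmonic sum
$c(m)=\sum_{i=1}^m 1/i$, valid under arbitrary dependence, which matters
because GO terms are nested — applied within each namespace separately.
Gene-set (GMT) collections are tested with the one-sided Fisher exact test,
which on 2×2 margins *is* the hypergeometric upper tail, under
Benjamini–Hochberg across the collection; the tests assert the identity
against `stats::fisher.test`.

Within-pair similarity intersects the two members' **direct** term sets:
under propagation every annotated pair would trivially share the namespace
roots and the shared-count distribution would collapse. The per-pair records
carry overall and per-namespace shared counts, the histogram over pairs, and
the fraction of pairs sharing ≥ 1 term. Unannotated members count as empty
sets and are flagged rather than dropped.

## TFBS fold enrichment

Count matrices from JASPAR- and TRANSFAC-dialect files parse to one
representation and are converted to log-odds scores

$$s(b, j) = \log_2 \frac{(c_{bj} + 0.8\,\pi_b) / (\sum_b c_{bj} + 0.8)}{\pi_b},$$

with uniform background $\pi_b = 0.25$ and total pseudocount 0.8 distributed
by background (a common default; both are arguments). Every offset is scored
on the forward sequence and its reverse complement; reverse hits map back to
forward coordinates with strand `-`. A window hits when its score reaches
`min + 0.8 × (max − min)` of the achievable score range; the published
genome scanners do not document their thresholds, so this fraction is pinned
and configurable. Score comparisons use a 1e-9 tolerance so that summation
order cannot flip a hit exactly at the threshold (relevant at fraction 1.0,
where only the consensus scores `max`). Windows containing `N` never hit.
Overlapping hits of one motif all count — occurrence counting, not
once-per-promoter.

Rates are hits per kb of total promoter sequence in each class. Per-kb
normalization is what removes the length asymmetry between variable-length
bidirectional promoters and fixed 1 kb uni promoters, which is the asymmetry
a "normalized number of binding sites" must exist to fix; a per-promoter
alternative is provided. The fold is bidirectional rate / uni rate:
fold ≥ 2 is over-represented, fold ≤ 0.5 under-represented, otherwise
shared, with both boundaries inclusive. A motif absent from uni promoters
but present in bidirectional ones has infinite fold (over-represented); a
motif absent from both is reported as shared with a `both_zero` flag so the
table keeps one row per motif. Cross-collection comparison intersects
over-represented motif *names* case-insensitively.

## The synthetic generator

`simulation_config()` pins the study conditions; `generate_bundle()` writes
a complete input set plus a ground-truth manifest. Defaults: two 500 kb
chromosomes, 60 genes, half in head-to-head pairs with TSS gaps uniform on
100–900 bp, one convergent and one tandem two-gene layout among the rest,
background GC 0.40, bidirectional promoters at GC 0.60 / CpG Obs/Exp 0.9
versus uni promoters at GC 0.45 / 0.3, three motifs planted at
(bidirectional : uni) rates of 3 : 0.6, 3 : 3, and 0.6 : 3 hits per kb, and
an ontology in which pairs share a direct term with probability 0.5. This
scale runs the whole pipeline in seconds while leaving every contrast
several standard deviations wide; the composition values mirror the
qualitative structure reported for real promoter classes (CpG-island-dense
GC-rich bidirectional promoters over a GC-poor background).

Promoter sequences come from a first-order Markov (dinucleotide) sampler
built from a joint dinucleotide distribution with the target base
composition as both marginals and the `(C,G)` cell set to
`obs_exp × π_C × π_G`, with the displaced mass spread over the
complementary rows and columns in proportion to the stationary frequencies.
An i.i.d. base sampler cannot decouple GC from CpG Obs/Exp; this one hits
the configured GC within about ±0.02 and Obs/Exp within ±0.1 at kb scale
(asserted in the tests). Motif insertions overwrite background bases at
non-overlapping offsets (no indels), so manifest coordinates are exact;
insertion counts per region use deterministic fractional rounding
(`floor(rate × len/1000)` plus a Bernoulli remainder), which meets the
configured expectation with far less variance than Poisson counts. Gene
layouts keep ≥ 12 kb between unrelated units so every planted non-pair gene
(except the tandem downstream gene, planted 900 bp behind a same-strand
TSS on purpose) satisfies the uni-directional windows by construction.

What the generator does **not** emulate: isochore structure, repeats,
CpG-island methylation, multi-transcript clusters with staggered TSSs,
realistic chromosome counts, or motif co-occurrence structure. Passing the
planted-truth tests therefore demonstrates that the *implementations* are
correct and the pipeline wiring recovers known signal; it does not reproduce
any genome-scale count from real annotation releases, which depend on the
specific assembly, transcript set and matrix library versions used.

## Numerical and degenerate-input choices

* All generators and the pipeline are pure functions of their inputs and the
  seed; reruns are byte-identical, and the suite asserts it.
* Empty sequences error; all-`N` sequences return GC 0 with a warning.
* An empty promoter class yields `NA` summary fractions, never silent 0s.
* Unknown accession prefixes are kept with evidence class `other` (synthetic
  fixtures need not mimic RefSeq numbering); malformed strands and inverted
  coordinates are format errors naming the line.
* Cyclic `is_a` relations and edges to undeclared terms are errors at parse
  time; obsolete terms are dropped.

## Worked example

```{r example, eval = FALSE}
library(bidipromoter)

cfg <- simulation_config(seed = 1)
bundle <- generate_bundle(cfg, "synthetic")
res <- run_pipeline(pipeline_config(
  genes = bundle$paths$genes, genome = bundle$paths$genome,
  obo = bundle$paths$obo, annotations = bundle$paths$annotations,
  jaspar = bundle$paths$jaspar, transfac = bundle$paths$transfac,
  out_dir = "out"))

res$cpg$gardiner_garden$summary$by_class
res$tfbs$jaspar
```

The same flow, stage by stage with narrative output, lives in the numbered
scripts under `analysis/`; `scripts/acceptance.R` condenses the headline
numbers into one JSON report.

## Limitations

* The uni-directional definition is a documented conjunction reading of an
  ambiguous sentence, not a claim about any particular prior study's intent.
* The island caller and the PWM score threshold are pinned stand-ins for
  unpublished script internals; both are configurable.
* Whether within-pair sharing should use direct or propagated annotations is
  genuinely open; direct is the default, and a propagated mode would need
  root/shallow-term exclusion to stay informative.
* No plotting is provided; every table is plain TSV and diffs cleanly.
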