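#!/usr/bin/env Rscript
# Stage 3: extract promoters and contrast CpG islands between classes.
#
# Bidirectional promoters are the intergenic TSS-to-TSS intervals,
# symmetrically extended to 1 kb (the minimum CpG-island length) for island
# calling; uni-directional promoters are the fixed 1 kb upstream of the TSS.
# Islands are called under the Gardiner-Garden preset (GC >= 0.50,
# Obs/Exp >= 0.60, >= 500 bp) and a stricter GC >= 0.55 variant.

suppressMessages(library(bidipromoter))

genome <- read_genome_fasta("results/synthetic/genome.fa")
clen <- chromosome_lengths(genome)
pairs <- read.delim("results/pairs.tsv")
uni <- read.delim("results/uni_genes.tsv")

bidir <- fetch_sequences(
  extend_symmetric(bidirectional_promoters(pairs), clen), genome)
unip <- fetch_sequences(unidirectional_promoters(uni, clen), genome)
write_bed(bidir, "results/bidir_promoters.bed")
write_bed(unip, "results/uni_promoters.bed")

for (cn in c("gardiner_garden", "strict")) {
  crit <- cpg_criteria(cn)
  bi <- find_cpg_islands_regions(bidir, crit)
  ui <- find_cpg_islands_regions(unip, crit)
  s <- summarize_by_class(bidir, bi, unip, ui)
  write.table(rbind(bi, ui), sprintf("results/cpg_islands_%s.tsv", cn),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(s$by_class, sprintf("results/cpg_summary_%s.tsv", cn),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%-16s islands in %.1f%% of bidirectional vs %.1f%% of uni promoters (mean GC %.1f%% vs %.1f%%)\n",
    cn, 100 * s$by_class$fraction_with_island[1],
    100 * s$by_class$fraction_with_island[2],
    100 * s$by_class$mean_gc[1], 100 * s$by_class$mean_gc[2]))
}
cat(sprintf("promoters: %d bidirectional (%d bp extended), %d uni-directional\n",
            nrow(bidir), sum(bidir$end - bidir$start), nrow(unip)))
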