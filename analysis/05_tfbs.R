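#!/usr/bin/env Rscript
# Stage 5: transcription-factor binding-site fold enrichment.
#
# Scans the pure intergenic bidirectional promoters and the 1 kb uni
# promoters with both matrix collections (JASPAR- and TRANSFAC-dialect
# files) on both strands at 0.8 of the min-max log-odds range, normalizes
# hit counts per kb of promoter sequence, and classifies each motif as
# over-represented (fold >= 2), shared, or under-represented (fold <= 0.5)
# in bidirectional promoters. The two dialects carry the same matrices here,
# so the cross-collection overlap doubles as a parser consistency check.

suppressMessages(library(bidipromoter))

genome <- read_genome_fasta("results/synthetic/genome.fa")
pairs <- read.delim("results/pairs.tsv")
uni <- read.delim("results/uni_genes.tsv")
clen <- chromosome_lengths(genome)

bidir <- fetch_sequences(bidirectional_promoters(pairs), genome)
unip <- fetch_sequences(unidirectional_promoters(uni, clen), genome)

tables <- list(jaspar = read_pwm_jaspar("results/synthetic/motifs.jaspar"),
               transfac = read_pwm_transfac("results/synthetic/motifs.transfac"))
tables <- lapply(tables, function(pwms) enrichment_table(bidir, unip, pwms))
for (nm in names(tables)) {
  write.table(tables[[nm]], sprintf("results/tfbs_enrichment_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
overlap <- overrepresented_overlap(tables$jaspar, tables$transfac)
writeLines(overlap, "results/tfbs_overlap.txt")

tab <- tables$jaspar
cat(sprintf("scanned %d bidirectional (%.1f kb) and %d uni promoters (%.1f kb)\n",
            nrow(bidir), sum(bidir$end - bidir$start) / 1000,
            nrow(unip), sum(unip$end - unip$start) / 1000))
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %-8s %5.2f vs %5.2f hits/kb, fold %5.2f -> %s\n",
              tab$motif_id[i], tab$bidir_rate[i], tab$uni_rate[i],
              tab$fold[i], tab$category[i]))
}
cat(sprintf("over-represented in both collections: %s\n",
            paste(overlap, collapse = ", ")))
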