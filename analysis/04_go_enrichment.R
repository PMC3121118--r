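#!/usr/bin/env Rscript
# Stage 4: functional enrichment and within-pair similarity.
#
# Pair-member genes are tested for term over-representation against all
# curated genes (hypergeometric upper tail on propagated annotations,
# Benjamini-Yekutieli adjusted per namespace). Within-pair functional
# similarity intersects the two members' direct term sets; the fraction of
# pairs sharing at least one term is the headline statistic.

suppressMessages(library(bidipromoter))

ontology <- read_obo("results/synthetic/ontology.obo")
direct <- read_annotations("results/synthetic/annotations.tsv", ontology)
pairs <- read.delim("results/pairs.tsv")
clusters <- read.delim("results/clusters.tsv")

study <- unique(c(pairs$plus_symbol, pairs$minus_symbol))
population <- unique(filter_evidence(clusters, "curated-mRNA")$gene_symbol)
propagated <- propagate_annotations(direct, ontology)
enrichment <- enrich_terms(study, population, propagated, ontology)
write.table(enrichment, "results/go_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

shared <- pair_shared_terms(pairs, direct, ontology)
write.table(shared$records, "results/pair_shared_terms.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(shared_count = names(shared$histogram),
                       n_pairs = as.integer(shared$histogram)),
            "results/shared_term_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("enrichment: %d terms tested for %d study genes in a %d-gene population\n",
            nrow(enrichment), length(study), length(population)))
cat(sprintf("top term: %s (%s), k/K = %d/%d, adjusted p = %.3g\n",
            enrichment$term_id[1], enrichment$namespace[1],
            enrichment$k[1], enrichment$K[1], enrichment$p_adjusted[1]))
cat(sprintf("%d/%d pairs (%.1f%%) share at least one direct GO term\n",
            sum(shared$records$shared_count >= 1), nrow(shared$records),
            100 * shared$fraction_sharing))
truth <- read.delim("results/synthetic/truth_ontology.tsv")
cat(sprintf("planted sharing rate in the manifest: %.1f%%\n",
            100 * mean(truth$shares)))
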