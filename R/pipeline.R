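#' Pipeline configuration
#'
#' Validates input paths and stage parameters for [run_pipeline()].
#'
#' @param genes,genome,obo,annotations,jaspar,transfac Input file paths
#'   (`jaspar`/`transfac`/`gmt` optional, `NULL` to skip the stage).
#' @param gmt Optional GMT gene-set collection path.
#' @param out_dir Output directory for stage tables.
#' @param mode Evidence filter mode (see [filter_evidence()]).
#' @param max_distance Pair TSS distance bound (bp, exclusive).
#' @param min_length CpG-island length / promoter extension target (bp).
#' @param pure_ig If `TRUE`, skip symmetric extension and compute CpG
#'   statistics on unextended intergenic sequence.
#' @param threshold_fraction,fold_threshold,normalization TFBS scan settings.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, genome, obo = NULL, annotations = NULL,
                            jaspar = NULL, transfac = NULL, gmt = NULL,
                            out_dir = tempfile("bidipromoter_"),
                            mode = "curated-mRNA", max_distance = 1000L,
                            min_length = 1000L, pure_ig = FALSE,
                            threshold_fraction = 0.8, fold_threshold = 2.0,
                            normalization = "per-kb") {
  for (p in c(genes, genome, obo, annotations, jaspar, transfac, gmt)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  stopifnot(max_distance > 0, min_length >= 1,
            threshold_fraction > 0, threshold_fraction <= 1, fold_threshold > 1)
  structure(list(genes = genes, genome = genome, obo = obo,
                 annotations = annotations, jaspar = jaspar,
                 transfac = transfac, gmt = gmt, out_dir = out_dir,
                 mode = mode, max_distance = max_distance,
                 min_length = min_length, pure_ig = pure_ig,
                 threshold_fraction = threshold_fraction,
                 fold_threshold = fold_threshold,
                 normalization = normalization),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full bidirectional-promoter pipeline
#'
#' Executes classification, promoter extraction, CpG-island detection under
#' both criteria presets, GO enrichment with within-pair shared-term
#' analysis, optional GMT gene-set enrichment, and PWM fold-enrichment for
#' each supplied matrix collection, writing one TSV per stage under
#' `config$out_dir` and returning all tables.
#'
#' @param config A `pipeline_config`.
#' @return List of stage results: `clusters`, `pairs`, `uni_genes`,
#'   `bidir_promoters`, `uni_promoters`, `cpg` (per criteria: islands and
#'   class summary), `pair_counts` (per chromosome x evidence mode),
#'   `go` (enrichment, shared-term records/histogram/fraction), `gene_sets`,
#'   `tfbs` (per collection enrichment table, plus `overlap`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## classification
  records <- stage("classify", read_gene_table(config$genes))
  clusters <- stage("classify", collapse_clusters(records))
  filtered <- stage("classify", filter_evidence(clusters, config$mode))
  pairs <- stage("classify",
                 deduplicate_pairs(classify_bidirectional(filtered,
                                                          config$max_distance)))
  uni <- stage("classify", classify_unidirectional(filtered))
  # Table-1-shaped breakdown: pairs per chromosome under each evidence mode
  pair_counts <- stage("classify", do.call(rbind, lapply(
    c("all", "curated", "curated-mRNA"), function(m) {
      pm <- deduplicate_pairs(classify_bidirectional(
        filter_evidence(clusters, m), config$max_distance))
      if (nrow(pm) == 0) {
        return(data.frame(mode = m, chrom = NA_character_, n_pairs = 0L,
                          stringsAsFactors = FALSE))
      }
      tab <- table(pm$chrom)
      data.frame(mode = m, chrom = names(tab), n_pairs = as.integer(tab),
                 stringsAsFactors = FALSE)
    })))
  write_tsv(clusters, file.path(config$out_dir, "clusters.tsv"))
  write_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))
  write_tsv(uni, file.path(config$out_dir, "uni_genes.tsv"))
  write_tsv(pair_counts, file.path(config$out_dir, "pair_counts.tsv"))

  ## promoters
  genome <- stage("promoters", read_genome_fasta(config$genome))
  clen <- chromosome_lengths(genome)
  # pure intergenic promoters are scanned for motifs; the symmetric extension
  # exists only to give short intergenic regions a full CpG-island-length
  # window, so CpG statistics use the extended intervals (unless pure_ig)
  bidir_ig <- stage("promoters",
                    fetch_sequences(bidirectional_promoters(pairs), genome))
  bidir <- if (config$pure_ig) bidir_ig else {
    stage("promoters", fetch_sequences(
      extend_symmetric(bidirectional_promoters(pairs), clen, config$min_length),
      genome))
  }
  unip <- stage("promoters", unidirectional_promoters(uni, clen))
  unip <- stage("promoters", fetch_sequences(unip, genome))
  write_bed(bidir, file.path(config$out_dir, "bidir_promoters.bed"))
  write_bed(unip, file.path(config$out_dir, "uni_promoters.bed"))

  ## CpG islands under both presets
  cpg <- lapply(c("gardiner_garden", "strict"), function(cn) {
    crit <- cpg_criteria(cn)
    bi <- stage("cpg", find_cpg_islands_regions(bidir, crit))
    ui <- stage("cpg", find_cpg_islands_regions(unip, crit))
    summ <- stage("cpg", summarize_by_class(bidir, bi, unip, ui))
    write_tsv(rbind(bi, ui), file.path(config$out_dir,
                                       paste0("cpg_islands_", cn, ".tsv")))
    write_tsv(summ$by_class, file.path(config$out_dir,
                                       paste0("cpg_summary_", cn, ".tsv")))
    list(criteria = cn, bidir_islands = bi, uni_islands = ui, summary = summ)
  })
  names(cpg) <- c("gardiner_garden", "strict")

  ## GO enrichment and pair similarity
  go <- NULL
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    ontology <- stage("go", read_obo(config$obo))
    direct <- stage("go", read_annotations(config$annotations, ontology))
    study <- unique(c(pairs$plus_symbol, pairs$minus_symbol))
    population <- unique(filtered$gene_symbol)
    propagated <- stage("go", propagate_annotations(direct, ontology))
    enrichment <- stage("go", enrich_terms(study, population, propagated, ontology))
    shared <- stage("go", pair_shared_terms(pairs, direct, ontology))
    write_tsv(enrichment, file.path(config$out_dir, "go_enrichment.tsv"))
    write_tsv(shared$records, file.path(config$out_dir, "pair_shared_terms.tsv"))
    write_tsv(data.frame(shared_count = names(shared$histogram),
                         n_pairs = as.integer(shared$histogram)),
              file.path(config$out_dir, "shared_term_histogram.tsv"))
    go <- list(enrichment = enrichment, shared = shared)
  }

  ## gene-set (pathway) enrichment
  gene_sets <- NULL
  if (!is.null(config$gmt)) {
    gmt <- stage("gsea", read_gmt(config$gmt))
    study <- unique(c(pairs$plus_symbol, pairs$minus_symbol))
    population <- unique(filtered$gene_symbol)
    gene_sets <- stage("gsea", enrich_gene_sets(study, population, gmt))
    write_tsv(gene_sets, file.path(config$out_dir, "gene_set_enrichment.tsv"))
  }

  ## TFBS fold enrichment per matrix collection
  tfbs <- NULL
  collections <- list()
  if (!is.null(config$jaspar)) collections$jaspar <- read_pwm_jaspar(config$jaspar)
  if (!is.null(config$transfac)) collections$transfac <- read_pwm_transfac(config$transfac)
  if (length(collections) > 0) {
    tables <- lapply(collections, function(pwms) {
      stage("tfbs", enrichment_table(
        bidir_ig, unip, pwms,
        threshold_fraction = config$threshold_fraction,
        fold_threshold = config$fold_threshold,
        normalization = config$normalization))
    })
    for (nm in names(tables)) {
      write_tsv(tables[[nm]], file.path(config$out_dir,
                                        paste0("tfbs_enrichment_", nm, ".tsv")))
    }
    overlap <- if (length(tables) == 2) {
      stage("tfbs", overrepresented_overlap(tables[[1]], tables[[2]]))
    } else character()
    writeLines(overlap, file.path(config$out_dir, "tfbs_overlap.txt"))
    tfbs <- c(tables, list(overlap = overlap))
  }

  list(clusters = clusters, pairs = pairs, uni_genes = uni,
       bidir_promoters = bidir, uni_promoters = unip, cpg = cpg,
       pair_counts = pair_counts, go = go, gene_sets = gene_sets, tfbs = tfbs)
}
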