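#' Simulation configuration
#'
#' Parameters of the synthetic genome bundle. Defaults define a compact study
#' condition that exercises every pipeline stage: two 500 kb chromosomes, 60
#' genes with half placed in divergent (head-to-head) pairs at TSS gaps of
#' 100-900 bp, intergenic bidirectional promoters with elevated GC (0.60) and
#' CpG Obs/Exp (0.9) against uni-directional promoters (GC 0.45, Obs/Exp 0.3)
#' on a GC 0.40 background, three planted motifs (one at 5x the rate in
#' bidirectional promoters, one at equal rate, one at one-fifth the rate),
#' and an ontology in which each pair shares a direct term with probability
#' 0.5.
#'
#' @param seed Integer seed; all outputs are pure functions of config + seed.
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param n_genes Total gene count.
#' @param fraction_bidirectional Fraction of genes placed in head-to-head pairs.
#' @param n_convergent,n_tandem Extra two-gene layouts carved from the
#'   non-paired genes: convergent (3' ends facing) and tandem (same strand,
#'   downstream TSS within 1 kb of the upstream gene's TSS, so the downstream
#'   gene is not uni-directional).
#' @param tss_gap_range Uniform range of pair TSS gaps in bp (within (0, 1000)).
#' @param gene_length_range,spacing_range Gene span lengths and inter-unit
#'   spacing in bp; spacing must exceed 10 kb plus the 1 kb promoter so that
#'   planted non-pair genes satisfy the uni-directional windows.
#' @param background_gc Background genome GC fraction.
#' @param bidir_gc,bidir_obs_exp Composition planted in intergenic
#'   (bidirectional promoter) sequence.
#' @param uni_gc,uni_obs_exp Composition planted in 1 kb uni promoters.
#' @param motif_rates List with elements `bidir` and `uni`: named numeric
#'   vectors, motif id -> expected insertions per kb in that promoter class.
#' @param ontology_size Leaf terms per namespace.
#' @param p_share Probability a pair shares >= 1 direct ontology term.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 2L, chromosome_length = 500000L,
    n_genes = 60L, fraction_bidirectional = 0.5,
    n_convergent = 1L, n_tandem = 1L,
    tss_gap_range = c(100L, 900L),
    gene_length_range = c(2000L, 4500L),
    spacing_range = c(12000L, 14000L),
    background_gc = 0.40,
    bidir_gc = 0.60, bidir_obs_exp = 0.9,
    uni_gc = 0.45, uni_obs_exp = 0.3,
    motif_rates = list(
      bidir = c(MOTIF1 = 3.0, MOTIF2 = 3.0, MOTIF3 = 0.6),
      uni = c(MOTIF1 = 0.6, MOTIF2 = 3.0, MOTIF3 = 3.0)
    ),
    ontology_size = 40L, p_share = 0.5) {
  stopifnot(
    fraction_bidirectional >= 0, fraction_bidirectional <= 1,
    tss_gap_range[1] > 0, tss_gap_range[2] < 1000,
    spacing_range[1] > 11000,
    background_gc > 0, background_gc < 1, p_share >= 0, p_share <= 1,
    identical(sort(names(motif_rates$bidir)), sort(names(motif_rates$uni)))
  )
  structure(as.list(environment()), class = "sim_config")
}

# First-order (dinucleotide) Markov sampler with stationary base composition
# pi = ((1-gc)/2, gc/2, gc/2, (1-gc)/2) and P(CpG) = obs_exp * pi_C * pi_G.
# Built from a joint dinucleotide distribution with both marginals pi: start
# from the independent joint, set the (C,G) cell to its target, and spread
# the displaced mass delta over the complementary rows/columns proportionally
# to pi (add delta*pi_y/(1-pi_G) along row C, delta*pi_x/(1-pi_C) down column
# G, subtract the product term from the remaining block), which leaves both
# marginals intact and stays non-negative for any obs_exp in [0, 1/pi_G].
# An i.i.d. sampler cannot decouple GC from CpG Obs/Exp; this one hits the
# target GC within ~0.02 and Obs/Exp within ~0.1 for kb-scale sequences.
markov_transitions <- function(gc, obs_exp) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  J <- outer(p, p)
  delta <- (1 - obs_exp) * p[["C"]] * p[["G"]]
  other_x <- setdiff(names(p), "C")
  other_y <- setdiff(names(p), "G")
  J["C", "G"] <- J["C", "G"] - delta
  J["C", other_y] <- J["C", other_y] + delta * p[other_y] / (1 - p[["G"]])
  J[other_x, "G"] <- J[other_x, "G"] + delta * p[other_x] / (1 - p[["C"]])
  J[other_x, other_y] <- J[other_x, other_y] -
    delta * outer(p[other_x], p[other_y]) / ((1 - p[["C"]]) * (1 - p[["G"]]))
  if (any(J < -1e-12)) {
    stop("infeasible (gc, obs_exp) combination for the dinucleotide sampler")
  }
  J[J < 0] <- 0
  list(pi = p, P = J / rowSums(J))
}

#' Sample a sequence with controlled GC and CpG Obs/Exp
#'
#' @param len Sequence length in bp.
#' @param gc Target GC fraction.
#' @param obs_exp Target CpG observed/expected ratio.
#' @return Character vector of single bases (length `len`).
#' @export
sample_dinucleotide_seq <- function(len, gc, obs_exp) {
  mt <- markov_transitions(gc, obs_exp)
  bases <- c("A", "C", "G", "T")
  cp <- t(apply(mt$P, 1, cumsum))
  s <- integer(len)
  s[1] <- sample.int(4, 1, prob = mt$pi)
  if (len > 1) {
    u <- stats::runif(len)
    for (i in 2:len) {
      r <- cp[s[i - 1L], ]
      s[i] <- 1L + (u[i] > r[1L]) + (u[i] > r[2L]) + (u[i] > r[3L])
    }
  }
  bases[s]
}

runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

#' Generate PWM collections with planted consensus motifs
#'
#' Information-rich matrices (near-consensus columns: 97% of the count mass
#' on one base) whose consensus strings are exactly what
#' [generate_genome()] inserts. Widths 10-12 keep chance background matches
#' rare at the default scan threshold.
#'
#' @param config A `sim_config`.
#' @return List of `pwm` objects, one per motif id in `config$motif_rates`.
#' @export
generate_pwms <- function(config) {
  set.seed(config$seed + 1000003L)
  ids <- names(config$motif_rates$bidir)
  lapply(ids, function(id) {
    w <- runif_int(1, c(10L, 12L))
    cons <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    counts <- matrix(1, nrow = 4, ncol = w,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(cons, rownames(counts)), seq_len(w))] <- 97
    make_pwm(id, counts, name = tolower(id))
  })
}

#' Generate a synthetic genome with planted gene layouts
#'
#' Lays out head-to-head pairs, isolated, convergent and tandem genes along
#' the chromosomes with inter-unit spacing wide enough that every non-pair
#' gene (except the tandem downstream gene) satisfies the uni-directional
#' windows. Intergenic pair promoters and 1 kb uni promoters are emitted from
#' the dinucleotide sampler at their configured compositions; motif consensus
#' strings are inserted (overwriting background, no indels) at the configured
#' per-kb rates using deterministic fractional rounding. Fully reproducible
#' from the config seed.
#'
#' @param config A `sim_config`.
#' @return List: `genome` (DNAStringSet), `records` (transcript table),
#'   `pwms`, and `truth` — a manifest with `pairs`, `uni_genes`, `genes`
#'   (layout per gene), `promoters` (planted intervals) and `insertions`
#'   (motif id, region id, genomic offset, strand).
#' @export
generate_genome <- function(config) {
  pwms <- generate_pwms(config)
  consensus <- lapply(pwms, pwm_consensus)
  names(consensus) <- vapply(pwms, `[[`, "", "id")
  set.seed(config$seed)

  n_pairs <- floor(round(config$n_genes * config$fraction_bidirectional) / 2)
  n_two_unit <- config$n_convergent + config$n_tandem
  n_iso <- config$n_genes - 2L * n_pairs - 2L * n_two_unit
  if (n_iso < 0) stop("n_genes too small for the requested layouts")
  units <- sample(c(rep("pair", n_pairs), rep("convergent", config$n_convergent),
                    rep("tandem", config$n_tandem), rep("isolated", n_iso)))

  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  margin <- 16000L
  cursor <- margin
  chrom_i <- 1L
  glen <- function() runif_int(1, config$gene_length_range)

  genes <- list(); pairs <- list(); promoters <- list()
  gid <- 0L
  new_gene <- function(chrom, strand, start, end, layout) {
    gid <<- gid + 1L
    data.frame(accession = sprintf("NM_%06d", gid),
               gene_symbol = sprintf("GENE%04d", gid),
               chrom = chrom, strand = strand, tx_start = start, tx_end = end,
               layout = layout,
               is_unidirectional = layout %in% c("isolated", "convergent", "tandem_up"),
               stringsAsFactors = FALSE)
  }
  for (u in units) {
    # unit footprint incl. flanking 1 kb promoters; move on when it won't fit
    max_unit <- 2L * max(config$gene_length_range) + 1000L + 2000L
    while (cursor + max_unit > config$chromosome_length - margin) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > config$n_chromosomes) {
        stop("layout infeasible: genes do not fit on ", config$n_chromosomes,
             " chromosome(s) of ", config$chromosome_length, " bp")
      }
      cursor <- margin
    }
    chrom <- chrom_names[chrom_i]
    if (u == "pair") {
      l1 <- glen(); l2 <- glen()
      gap <- runif_int(1, config$tss_gap_range)
      g_minus <- new_gene(chrom, "-", cursor, cursor + l1, "pair_minus")
      s2 <- cursor + l1 + gap
      g_plus <- new_gene(chrom, "+", s2, s2 + l2, "pair_plus")
      genes <- c(genes, list(g_minus, g_plus))
      pairs[[length(pairs) + 1L]] <- data.frame(
        chrom = chrom, minus_symbol = g_minus$gene_symbol,
        plus_symbol = g_plus$gene_symbol,
        minus_tss = cursor + l1, plus_tss = s2, gap = gap,
        stringsAsFactors = FALSE)
      promoters[[length(promoters) + 1L]] <- data.frame(
        chrom = chrom, start = cursor + l1, end = s2, class = "bidir",
        region = paste0("ig_", g_minus$gene_symbol), stringsAsFactors = FALSE)
      cursor <- s2 + l2
    } else if (u == "convergent") {
      l1 <- glen(); l2 <- glen()
      g1 <- new_gene(chrom, "+", cursor, cursor + l1, "convergent")
      s2 <- cursor + l1 + 500L
      g2 <- new_gene(chrom, "-", s2, s2 + l2, "convergent")
      genes <- c(genes, list(g1, g2))
      promoters <- c(promoters, list(
        data.frame(chrom = chrom, start = cursor - 1000L, end = cursor,
                   class = "uni", region = paste0("up_", g1$gene_symbol),
                   stringsAsFactors = FALSE),
        data.frame(chrom = chrom, start = s2 + l2, end = s2 + l2 + 1000L,
                   class = "uni", region = paste0("up_", g2$gene_symbol),
                   stringsAsFactors = FALSE)))
      cursor <- s2 + l2 + 1000L
    } else if (u == "tandem") {
      # short upstream gene, downstream TSS 900 bp away: downstream gene
      # fails the 1 kb same-strand window, upstream gene stays uni
      l2 <- glen()
      g1 <- new_gene(chrom, "+", cursor, cursor + 400L, "tandem_up")
      g2 <- new_gene(chrom, "+", cursor + 900L, cursor + 900L + l2, "tandem_down")
      genes <- c(genes, list(g1, g2))
      promoters[[length(promoters) + 1L]] <- data.frame(
        chrom = chrom, start = cursor - 1000L, end = cursor, class = "uni",
        region = paste0("up_", g1$gene_symbol), stringsAsFactors = FALSE)
      cursor <- cursor + 900L + l2
    } else {
      l <- glen()
      strand <- sample(c("+", "-"), 1)
      g <- new_gene(chrom, strand, cursor, cursor + l, "isolated")
      genes <- c(genes, list(g))
      prom <- if (strand == "+") c(cursor - 1000L, cursor)
              else c(cursor + l, cursor + l + 1000L)
      promoters[[length(promoters) + 1L]] <- data.frame(
        chrom = chrom, start = prom[1], end = prom[2], class = "uni",
        region = paste0("up_", g$gene_symbol), stringsAsFactors = FALSE)
      cursor <- cursor + l + if (strand == "-") 1000L else 0L
    }
    cursor <- cursor + runif_int(1, config$spacing_range)
  }
  genes <- do.call(rbind, genes)
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  promoters <- do.call(rbind, promoters)

  # background genome: i.i.d. bases at background_gc
  bg <- config$background_gc
  chrom_seq <- lapply(chrom_names, function(ch) {
    sample(c("A", "C", "G", "T"), config$chromosome_length, replace = TRUE,
           prob = c((1 - bg) / 2, bg / 2, bg / 2, (1 - bg) / 2))
  })
  names(chrom_seq) <- chrom_names

  # plant promoter compositions
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    comp <- if (p$class == "bidir") c(config$bidir_gc, config$bidir_obs_exp)
            else c(config$uni_gc, config$uni_obs_exp)
    chrom_seq[[p$chrom]][(p$start + 1L):p$end] <-
      sample_dinucleotide_seq(p$end - p$start, comp[1], comp[2])
  }

  # plant motif instances: floor(rate * kb) + Bernoulli(fractional part),
  # non-overlapping offsets, random strand, consensus overwrites background
  insertions <- list()
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    rates <- if (p$class == "bidir") config$motif_rates$bidir
             else config$motif_rates$uni
    len <- p$end - p$start
    occupied <- integer(0)
    for (mid in names(rates)) {
      expect <- rates[[mid]] * len / 1000
      n_ins <- floor(expect) + (stats::runif(1) < (expect - floor(expect)))
      w <- nchar(consensus[[mid]])
      for (k in seq_len(n_ins)) {
        for (try in 1:100) {
          off <- runif_int(1, c(0L, len - w))
          if (!any(abs(off - occupied) < w + 2L)) break
          off <- NA_integer_
        }
        if (is.na(off)) next
        occupied <- c(occupied, off)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") consensus[[mid]] else revcomp(consensus[[mid]])
        pos <- p$start + off
        chrom_seq[[p$chrom]][(pos + 1L):(pos + w)] <- strsplit(ins, "")[[1]]
        insertions[[length(insertions) + 1L]] <- data.frame(
          motif_id = mid, region = p$region, chrom = p$chrom,
          start = pos, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  insertions <- if (length(insertions)) do.call(rbind, insertions)
                else data.frame(motif_id = character(), region = character(),
                                chrom = character(), start = integer(),
                                strand = character(), stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seq, paste, "", collapse = ""))
  records <- genes[, c("accession", "gene_symbol", "chrom", "strand",
                       "tx_start", "tx_end")]
  records$evidence_class <- evidence_class(records$accession)
  list(
    genome = genome, records = records, pwms = pwms,
    truth = list(
      pairs = pairs,
      uni_genes = genes$gene_symbol[genes$is_unidirectional],
      genes = genes, promoters = promoters, insertions = insertions
    )
  )
}

#' Generate a synthetic ontology with controlled within-pair sharing
#'
#' Three namespaces, each a two-level DAG (root, five mid-level terms,
#' `ontology_size` leaves). Each supplied pair shares one direct leaf term
#' with probability `p_share` (independent Bernoulli); otherwise its members
#' receive disjoint leaves. Every gene gets one extra private leaf so
#' annotation sets are never single-term by construction.
#'
#' @param config A `sim_config`.
#' @param pairs Data.frame with columns `plus_symbol`, `minus_symbol`.
#' @param extra_genes Optional additional gene symbols to annotate.
#' @return List: `ontology`, `annotations` (direct), `truth` (per-pair
#'   sharing flag and shared term).
#' @export
generate_ontology <- function(config, pairs, extra_genes = character()) {
  stopifnot(config$ontology_size >= 3)
  set.seed(config$seed + 2000003L)
  namespaces <- c("biological_process", "molecular_function", "cellular_component")
  terms <- list(); edges <- list(); leaves <- list()
  tid <- 0L
  next_id <- function() { tid <<- tid + 1L; sprintf("SYN:%07d", tid) }
  for (ns in namespaces) {
    root <- next_id()
    terms[[length(terms) + 1L]] <- data.frame(
      id = root, name = paste0(ns, "_root"), namespace = ns,
      stringsAsFactors = FALSE)
    mids <- character(5)
    for (m in 1:5) {
      mids[m] <- next_id()
      terms[[length(terms) + 1L]] <- data.frame(
        id = mids[m], name = sprintf("%s_mid_%d", ns, m), namespace = ns,
        stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- data.frame(
        child = mids[m], parent = root, stringsAsFactors = FALSE)
    }
    lv <- character(config$ontology_size)
    for (l in seq_len(config$ontology_size)) {
      lv[l] <- next_id()
      terms[[length(terms) + 1L]] <- data.frame(
        id = lv[l], name = sprintf("%s_leaf_%d", ns, l), namespace = ns,
        stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- data.frame(
        child = lv[l], parent = sample(mids, 1), stringsAsFactors = FALSE)
    }
    leaves[[ns]] <- lv
  }
  ontology <- make_ontology(do.call(rbind, terms), do.call(rbind, edges))
  all_leaves <- unlist(leaves, use.names = FALSE)

  annotations <- list()
  add <- function(gene, term) {
    annotations[[gene]] <<- sort(unique(c(annotations[[gene]], term)))
  }
  truth <- lapply(seq_len(nrow(pairs)), function(i) {
    plus <- pairs$plus_symbol[i]; minus <- pairs$minus_symbol[i]
    share <- stats::runif(1) < config$p_share
    picks <- sample(all_leaves, 3)  # distinct within the pair
    if (share) {
      add(plus, picks[1]); add(minus, picks[1])
    }
    add(plus, picks[2]); add(minus, picks[3])
    data.frame(plus_symbol = plus, minus_symbol = minus, shares = share,
               shared_term = if (share) picks[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  for (g in extra_genes) add(g, sample(all_leaves, 2))
  list(ontology = ontology, annotations = annotations,
       truth = do.call(rbind, truth))
}

#' Generate and write the full synthetic bundle
#'
#' Writes `genome.fa`, `genes.tsv`, `ontology.obo`, `annotations.tsv`,
#' `motifs.jaspar`, `motifs.transfac` under `dir` and returns the in-memory
#' objects plus the ground-truth manifest.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if absent).
#' @return The [generate_genome()] result plus `ontology`, `annotations`,
#'   `ontology_truth` and `paths`.
#' @export
generate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  ont <- generate_ontology(
    config,
    pairs = if (is.null(gen$truth$pairs))
      data.frame(plus_symbol = character(), minus_symbol = character())
      else gen$truth$pairs,
    extra_genes = setdiff(gen$records$gene_symbol,
                          c(gen$truth$pairs$plus_symbol,
                            gen$truth$pairs$minus_symbol))
  )
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.tsv"),
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    jaspar = file.path(dir, "motifs.jaspar"),
    transfac = file.path(dir, "motifs.transfac")
  )
  write_genome_fasta(gen$genome, paths$genome)
  write_gene_table(gen$records, paths$genes)
  write_obo(ont$ontology, paths$obo)
  write_annotations(ont$annotations, paths$annotations)
  write_pwm_jaspar(gen$pwms, paths$jaspar)
  write_pwm_transfac(gen$pwms, paths$transfac)
  c(gen, list(ontology = ont$ontology, annotations = ont$annotations,
              ontology_truth = ont$truth, paths = paths))
}
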