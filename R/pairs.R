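#' Transcription start site of a transcript or cluster
#'
#' Under the 0-based half-open convention the TSS of a plus-strand feature is
#' its span start; for a minus-strand feature it is the span end (the
#' coordinate just past the last base, i.e. the 5'-most position on the minus
#' strand).
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param start,end 0-based half-open span.
#' @return Integer TSS coordinate(s).
#' @export
tss_of <- function(strand, start, end) {
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+", start, end)
}

evidence_rank <- function(cls) {
  match(cls, c("curated-mRNA", "curated-noncoding", "predicted", "other"))
}

#' Collapse transcripts into non-overlapping gene clusters
#'
#' Within each (chromosome, strand), transcripts whose spans overlap or abut
#' are merged transitively into one cluster (interval union via
#' [IRanges::reduce()]). The cluster span is the union hull; the cluster TSS
#' is the 5'-most member TSS; the cluster symbol is that of the member whose
#' TSS equals the cluster TSS (ties broken by lexicographically smallest
#' accession); the evidence class is the best among members
#' (curated-mRNA > curated-noncoding > predicted > other).
#'
#' @param records Transcript data.frame from [read_gene_table()].
#' @return Data.frame of clusters with columns `cluster_id`, `gene_symbol`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `evidence_class`, `n_members`,
#'   `members`, sorted by (chromosome, span start).
#' @export
collapse_clusters <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(cluster_id = character(), gene_symbol = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(), tss = integer(),
                      evidence_class = character(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  key <- paste(records$chrom, records$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, ]
    # IRanges is 1-based closed; abutting half-open intervals become adjacent
    # closed intervals, which reduce() merges by default (min.gapwidth = 1)
    ir <- IRanges::IRanges(start = r$tx_start + 1L, end = r$tx_end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    do.call(rbind, lapply(seq_along(red), function(i) {
      m <- r[revmap[[i]], ]
      strand <- m$strand[1]
      span_start <- IRanges::start(red)[i] - 1L
      span_end <- IRanges::end(red)[i]
      tss <- if (strand == "+") span_start else span_end
      m_tss <- tss_of(m$strand, m$tx_start, m$tx_end)
      at_tss <- m[m_tss == tss, , drop = FALSE]
      rep_tx <- at_tss[order(at_tss$accession), , drop = FALSE][1, ]
      data.frame(
        gene_symbol = rep_tx$gene_symbol, chrom = m$chrom[1], strand = strand,
        start = span_start, end = span_end, tss = tss,
        evidence_class = m$evidence_class[which.min(evidence_rank(m$evidence_class))],
        n_members = nrow(m),
        members = paste(sort(m$accession), collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  })
  clusters <- do.call(rbind, out)
  clusters <- clusters[order(clusters$chrom, clusters$start, clusters$strand), ]
  clusters <- cbind(
    cluster_id = sprintf("CL%05d", seq_len(nrow(clusters))), clusters,
    stringsAsFactors = FALSE
  )
  rownames(clusters) <- NULL
  clusters
}

#' Filter clusters by transcript evidence class
#'
#' Predicted models (XM/XR) are always excluded — the analysis is restricted
#' to genes with clear transcript evidence. Modes: `"all"` keeps every
#' non-predicted class, `"curated"` keeps curated mRNA plus curated
#' non-coding (the NR+NM set), `"curated-mRNA"` keeps NM-backed clusters only.
#'
#' @param clusters Cluster data.frame from [collapse_clusters()].
#' @param mode One of `"all"`, `"curated"`, `"curated-mRNA"`.
#' @return Filtered cluster data.frame.
#' @export
filter_evidence <- function(clusters, mode = c("all", "curated", "curated-mRNA")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    "all" = clusters$evidence_class != "predicted",
    "curated" = clusters$evidence_class %in% c("curated-mRNA", "curated-noncoding"),
    "curated-mRNA" = clusters$evidence_class == "curated-mRNA"
  )
  clusters[keep, , drop = FALSE]
}

#' Classify bidirectional (head-to-head) gene pairs
#'
#' A bidirectional pair is two adjacent clusters on opposite strands in
#' divergent orientation — the minus-strand TSS at or below the plus-strand
#' TSS — with TSS distance strictly below `max_distance`. Adjacency means no
#' other cluster's TSS lies strictly between the two TSSs. The intergenic
#' interval `[minus TSS, plus TSS)` is the putative bidirectional promoter.
#'
#' @param clusters Cluster data.frame.
#' @param max_distance Maximum TSS distance in bp (exclusive; default 1000).
#' @return Data.frame of pairs with columns `pair_id`, `chrom`,
#'   `minus_cluster`, `minus_symbol`, `minus_tss`, `plus_cluster`,
#'   `plus_symbol`, `plus_tss`, `distance`, `ig_start`, `ig_end`.
#' @export
classify_bidirectional <- function(clusters, max_distance = 1000L) {
  stopifnot(max_distance > 0)
  empty <- data.frame(pair_id = character(), chrom = character(),
                      minus_cluster = character(), minus_symbol = character(),
                      minus_tss = integer(), plus_cluster = character(),
                      plus_symbol = character(), plus_tss = integer(),
                      distance = integer(), ig_start = integer(),
                      ig_end = integer(), stringsAsFactors = FALSE)
  if (nrow(clusters) < 2) return(empty)
  res <- list()
  for (chrom in unique(clusters$chrom)) {
    cc <- clusters[clusters$chrom == chrom, ]
    cc <- cc[order(cc$tss, cc$cluster_id), ]
    tss_vals <- sort(unique(cc$tss))
    # candidate (minus, plus) combinations with no TSS strictly between:
    # both TSSs equal, or at consecutive distinct TSS values
    for (vi in seq_along(tss_vals)) {
      t_lo <- tss_vals[vi]
      at_lo <- cc[cc$tss == t_lo, ]
      # distance-0 pairs within one TSS value
      m0 <- at_lo[at_lo$strand == "-", , drop = FALSE]
      p0 <- at_lo[at_lo$strand == "+", , drop = FALSE]
      if (nrow(m0) > 0 && nrow(p0) > 0) {
        for (i in seq_len(nrow(m0))) for (j in seq_len(nrow(p0))) {
          res[[length(res) + 1L]] <- list(m = m0[i, ], p = p0[j, ])
        }
      }
      if (vi < length(tss_vals)) {
        t_hi <- tss_vals[vi + 1L]
        if (t_hi - t_lo < max_distance) {
          at_hi <- cc[cc$tss == t_hi, ]
          m <- at_lo[at_lo$strand == "-", , drop = FALSE]
          p <- at_hi[at_hi$strand == "+", , drop = FALSE]
          if (nrow(m) > 0 && nrow(p) > 0) {
            for (i in seq_len(nrow(m))) for (j in seq_len(nrow(p))) {
              res[[length(res) + 1L]] <- list(m = m[i, ], p = p[j, ])
            }
          }
        }
      }
    }
  }
  if (length(res) == 0) return(empty)
  pairs <- do.call(rbind, lapply(res, function(x) {
    data.frame(chrom = x$m$chrom, minus_cluster = x$m$cluster_id,
               minus_symbol = x$m$gene_symbol, minus_tss = x$m$tss,
               plus_cluster = x$p$cluster_id, plus_symbol = x$p$gene_symbol,
               plus_tss = x$p$tss, distance = x$p$tss - x$m$tss,
               ig_start = x$m$tss, ig_end = x$p$tss,
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(pairs$chrom, pairs$minus_tss, pairs$plus_tss), ]
  pairs <- cbind(pair_id = sprintf("pair_%04d", seq_len(nrow(pairs))), pairs,
                 stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs
}

#' Classify uni-directional genes
#'
#' A cluster is uni-directional iff no opposite-strand TSS lies within
#' `opposite_window` bp upstream of its TSS AND no same-strand TSS lies
#' within `same_window` bp upstream. Upstream means lower coordinates for a
#' plus-strand gene and higher coordinates for a minus-strand gene; a
#' neighbour at upstream distance d violates a window when 0 < d <= window.
#'
#' @param clusters Cluster data.frame.
#' @param opposite_window Opposite-strand exclusion window (default 10000).
#' @param same_window Same-strand exclusion window (default 1000).
#' @return The subset of `clusters` classified uni-directional.
#' @export
classify_unidirectional <- function(clusters, opposite_window = 10000L,
                                    same_window = 1000L) {
  if (nrow(clusters) == 0) return(clusters)
  keep <- vapply(seq_len(nrow(clusters)), function(i) {
    g <- clusters[i, ]
    others <- clusters[-i, , drop = FALSE]
    others <- others[others$chrom == g$chrom, , drop = FALSE]
    if (nrow(others) == 0) return(TRUE)
    # signed upstream distance from the neighbour TSS to this TSS
    d <- if (g$strand == "+") g$tss - others$tss else others$tss - g$tss
    win <- ifelse(others$strand == g$strand, same_window, opposite_window)
    !any(d > 0 & d <= win)
  }, logical(1))
  clusters[keep, , drop = FALSE]
}

#' Remove redundant pairs sharing an intergenic interval
#'
#' Among pairs with identical (chromosome, intergenic start, intergenic end),
#' exactly one is kept: the one with lexicographically smallest
#' (plus symbol, minus symbol). Order is otherwise preserved.
#'
#' @param pairs Pair data.frame from [classify_bidirectional()].
#' @return Deduplicated pair data.frame.
#' @export
deduplicate_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  key <- paste(pairs$chrom, pairs$ig_start, pairs$ig_end, sep = "\r")
  pick <- unlist(lapply(split(seq_len(nrow(pairs)), key), function(idx) {
    sub <- pairs[idx, ]
    idx[order(sub$plus_symbol, sub$minus_symbol)][1]
  }))
  out <- pairs[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}
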