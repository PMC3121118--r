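#' Bidirectional promoter of a gene pair
#'
#' The entire intergenic interval between the two TSSs, `[minus TSS,
#' plus TSS)`, is taken as the putative bidirectional promoter. Distance-0
#' pairs have an empty intergenic region and are rejected.
#'
#' @param pairs Pair data.frame from [classify_bidirectional()].
#' @return Promoter data.frame with columns `region_id`, `source`, `chrom`,
#'   `start`, `end`, `kind`, `extended`, `truncated`. Degenerate (distance-0)
#'   pairs are dropped with a warning.
#' @export
bidirectional_promoters <- function(pairs) {
  degen <- pairs$distance == 0
  if (any(degen)) {
    warning("skipping ", sum(degen), " distance-0 pair(s) with empty intergenic region: ",
            paste(pairs$pair_id[degen], collapse = ", "))
    pairs <- pairs[!degen, , drop = FALSE]
  }
  out <- data.frame(
    region_id = paste0("bp_", pairs$pair_id), source = pairs$pair_id,
    chrom = pairs$chrom, start = pairs$ig_start, end = pairs$ig_end,
    kind = "bidirectional", extended = FALSE, truncated = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Symmetrically extend short promoter regions
#'
#' Intergenic promoters shorter than `min_length` are padded on both sides to
#' exactly `min_length` so they can host a full-length CpG island. An odd
#' deficit puts the extra base on the left. Padding is clamped at chromosome
#' bounds, shifting the shortfall to the other side where possible; if the
#' whole chromosome is shorter than `min_length` the region covers it
#' entirely, with a warning. Idempotent: already-long regions are unchanged.
#'
#' @param regions Promoter data.frame (kind bidirectional).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param min_length Target minimum length in bp (default 1000).
#' @return The regions with updated intervals and `extended` flags.
#' @export
extend_symmetric <- function(regions, chrom_lengths, min_length = 1000L) {
  if (nrow(regions) == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    if (len >= min_length) next
    clen <- chrom_lengths[[regions$chrom[i]]]
    if (is.null(clen)) stop("unknown chromosome: ", regions$chrom[i])
    if (clen < min_length) {
      warning("chromosome ", regions$chrom[i], " shorter than ", min_length,
              " bp; region ", regions$region_id[i], " covers it entirely")
      regions$start[i] <- 0L
      regions$end[i] <- clen
      regions$extended[i] <- TRUE
      regions$truncated[i] <- TRUE
      next
    }
    deficit <- min_length - len
    pad_left <- ceiling(deficit / 2)
    pad_right <- deficit - pad_left
    s <- regions$start[i] - pad_left
    e <- regions$end[i] + pad_right
    if (s < 0) { e <- e - s; s <- 0L }
    if (e > clen) { s <- s - (e - clen); e <- clen }
    s <- max(s, 0L)
    regions$start[i] <- as.integer(s)
    regions$end[i] <- as.integer(e)
    regions$extended[i] <- TRUE
  }
  regions
}

#' Uni-directional promoters
#'
#' The fixed-length window immediately upstream of the TSS:
#' `[TSS - length, TSS)` for plus-strand genes, `[TSS, TSS + length)` for
#' minus-strand genes, clamped at chromosome bounds with truncation flagged.
#'
#' @param genes Cluster data.frame (classified uni-directional).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param length Promoter length in bp (default 1000).
#' @return Promoter data.frame (see [bidirectional_promoters()]), plus a
#'   `strand` column carrying the gene strand.
#' @export
unidirectional_promoters <- function(genes, chrom_lengths, length = 1000L) {
  if (nrow(genes) == 0) {
    return(data.frame(region_id = character(), source = character(),
                      chrom = character(), start = integer(), end = integer(),
                      kind = character(), extended = logical(),
                      truncated = logical(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  s <- ifelse(genes$strand == "+", genes$tss - length, genes$tss)
  e <- ifelse(genes$strand == "+", genes$tss, genes$tss + length)
  clen <- unname(chrom_lengths[genes$chrom])
  if (anyNA(clen)) stop("unknown chromosome in uni-directional genes")
  truncated <- s < 0 | e > clen
  s <- pmax(s, 0L)
  e <- pmin(e, clen)
  if (any(e - s < 1)) stop("uni-directional promoter collapsed to zero length")
  data.frame(
    region_id = paste0("up_", genes$cluster_id), source = genes$cluster_id,
    chrom = genes$chrom, start = as.integer(s), end = as.integer(e),
    kind = "unidirectional", extended = FALSE, truncated = truncated,
    strand = genes$strand, stringsAsFactors = FALSE
  )
}

#' Fetch promoter sequences from the genome
#'
#' Attaches the forward-strand genome substring to every region regardless of
#' gene strand: bidirectional promoters have no canonical strand, composition
#' statistics are strand-symmetric, and motif scanning covers both strands.
#'
#' @param regions Promoter data.frame.
#' @param genome A `DNAStringSet` from [read_genome_fasta()].
#' @return The regions with a `seq` character column added.
#' @export
fetch_sequences <- function(regions, genome) {
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  }
  clen <- chromosome_lengths(genome)[regions$chrom]
  if (nrow(regions) > 0 &&
      any(regions$start < 0 | regions$end > clen | regions$start >= regions$end)) {
    stop("region interval outside chromosome bounds (clamp upstream)")
  }
  regions$seq <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, "")
  regions
}
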