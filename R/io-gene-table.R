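#' Evidence class of a RefSeq-style accession
#'
#' RefSeq accession prefixes carry the curation status of a transcript:
#' `NM_` curated mRNA, `NR_` curated non-coding RNA, `XM_`/`XR_` model
#' (computationally predicted) transcripts. Anything else is kept with class
#' `"other"` so that non-RefSeq fixtures pass through unharmed.
#'
#' @param accession Character vector of transcript accessions.
#' @return Character vector, one of `"curated-mRNA"`, `"curated-noncoding"`,
#'   `"predicted"`, `"other"`.
#' @export
evidence_class <- function(accession) {
  prefix <- sub("_.*$", "", accession)
  cls <- rep("other", length(accession))
  cls[prefix == "NM"] <- "curated-mRNA"
  cls[prefix == "NR"] <- "curated-noncoding"
  cls[prefix %in% c("XM", "XR")] <- "predicted"
  cls
}

#' Read a refGene-style transcript table
#'
#' Parses a tab-separated transcript annotation table with columns
#' accession, gene symbol, chromosome, strand, transcript start, transcript
#' end. Coordinates are interpreted as 0-based half-open (the UCSC database
#' convention) and kept that way throughout the package. A header line, if
#' present, is detected by a non-numeric start coordinate and skipped.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `accession`, `gene_symbol`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `evidence_class`, one row per transcript,
#'   in file order.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_gene_table())
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 5 && is.na(suppressWarnings(as.numeric(first[[5]])))
  offset <- if (has_header) 1L else 0L
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    stop(sprintf("gene table line %d: expected 6 tab-separated fields, got %d",
                 bad + offset, nf[bad]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  strand <- m[, 4]
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    stop(sprintf("gene table line %d: malformed strand %s (must be + or -)",
                 bad + offset, sQuote(strand[bad])))
  }
  tx_start <- suppressWarnings(as.integer(m[, 5]))
  tx_end <- suppressWarnings(as.integer(m[, 6]))
  if (anyNA(tx_start) || anyNA(tx_end)) {
    bad <- which(is.na(tx_start) | is.na(tx_end))[1]
    stop(sprintf("gene table line %d: non-integer coordinates", bad + offset))
  }
  if (any(tx_start < 0)) {
    bad <- which(tx_start < 0)[1]
    stop(sprintf("gene table line %d: negative tx_start", bad + offset))
  }
  if (any(tx_start >= tx_end)) {
    bad <- which(tx_start >= tx_end)[1]
    stop(sprintf("gene table line %d: tx_start >= tx_end", bad + offset))
  }
  cls <- evidence_class(m[, 1])
  if (any(cls == "other")) {
    warning(sprintf("%d transcript(s) with unrecognised accession prefix kept with evidence class 'other'",
                    sum(cls == "other")))
  }
  data.frame(
    accession = m[, 1], gene_symbol = m[, 2], chrom = m[, 3],
    strand = strand, tx_start = tx_start, tx_end = tx_end,
    evidence_class = cls, stringsAsFactors = FALSE
  )
}

empty_gene_table <- function() {
  data.frame(
    accession = character(), gene_symbol = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    evidence_class = character(), stringsAsFactors = FALSE
  )
}

#' Write a transcript table
#'
#' Inverse of [read_gene_table()]: writes the six annotation columns as
#' headerless TSV so that read-after-write is the identity on records.
#'
#' @param records Data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @export
write_gene_table <- function(records, path) {
  utils::write.table(
    records[, c("accession", "gene_symbol", "chrom", "strand", "tx_start", "tx_end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
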