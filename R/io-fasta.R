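#' Read a genome from FASTA
#'
#' Loads a multi-record FASTA into a [Biostrings::DNAStringSet], keyed by the
#' first whitespace-delimited token of each header. Sequences are case-folded
#' to uppercase; only `A`, `C`, `G`, `T`, `N` (either case) are accepted.
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet` with one entry per chromosome.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(names(gs))) {
    stop("duplicate chromosome name in FASTA: ",
         names(gs)[duplicated(names(gs))][1])
  }
  if (any(Biostrings::width(gs) == 0)) {
    stop("empty sequence record in FASTA: ",
         names(gs)[Biostrings::width(gs) == 0][1])
  }
  # DNAStringSet accepts IUPAC ambiguity codes; restrict to the ACGTN alphabet
  freq <- Biostrings::alphabetFrequency(gs)
  extra <- colnames(freq)[!colnames(freq) %in% c("A", "C", "G", "T", "N")]
  if (sum(freq[, extra, drop = FALSE]) > 0) {
    stop("FASTA contains characters outside {A,C,G,T,N}")
  }
  # toupper: lowercase (soft-masked) input is folded on read
  Biostrings::DNAStringSet(toupper(as.character(gs)))
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named integer vector of chromosome lengths.
#' @export
chromosome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
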