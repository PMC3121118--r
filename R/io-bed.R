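#' Write genomic intervals as BED6
#'
#' Intervals are 0-based half-open internally, matching BED, so coordinates
#' pass through unchanged. Regions without a meaningful strand (bidirectional
#' promoters) are written with strand `.`.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `name` (or `region_id`), `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$name)) regions$name
          else if (!is.null(regions$region_id)) regions$region_id
          else paste0("region_", seq_len(nrow(regions)))
  score <- if (!is.null(regions$score)) regions$score else 0L
  strand <- if (!is.null(regions$strand)) regions$strand else "."
  utils::write.table(
    data.frame(regions$chrom, regions$start, regions$end, name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
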