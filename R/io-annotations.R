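#' Read gene-to-term annotations
#'
#' Two-column TSV of `gene_symbol`, `term_id` (direct annotations). Duplicate
#' rows collapse into sets; extra columns are ignored with a warning.
#'
#' @param path TSV path.
#' @param ontology Optional `ontology` to validate term ids against.
#' @return Named list: gene symbol -> character vector of distinct term ids.
#' @export
read_annotations <- function(path, ontology = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop(sprintf("annotation line %d: expected 2 columns", which(nf < 2)[1]))
  }
  if (any(nf > 2)) {
    warning(sprintf("%d annotation line(s) with extra columns; extras ignored",
                    sum(nf > 2)))
  }
  gene <- vapply(fields, `[`, "", 1L)
  term <- vapply(fields, `[`, "", 2L)
  if (!is.null(ontology)) {
    missing <- setdiff(unique(term), ontology$terms$id)
    if (length(missing) > 0) {
      stop("annotation uses term id(s) absent from ontology: ",
           paste(missing, collapse = ", "))
    }
  }
  lapply(split(term, gene), function(x) sort(unique(x)))
}

#' Write gene-to-term annotations
#'
#' @param annotations Named list, gene symbol -> term id vector.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  gene <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  utils::write.table(data.frame(gene, term), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene-set collections in GMT format
#'
#' One set per line: set name, description, then member genes, tab-separated.
#' Duplicate members within a line are collapsed.
#'
#' @param path GMT path.
#' @return Named list: set name -> list(description, genes).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", ln)
    list(description = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}
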