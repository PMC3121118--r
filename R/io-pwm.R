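#' Position weight matrices
#'
#' A PWM here is a list with elements `id`, `name` and `counts`, a 4 x L
#' numeric matrix of per-base, per-position counts with rownames
#' `A`, `C`, `G`, `T`. Both the JASPAR and TRANSFAC text dialects parse to
#' this one representation so downstream scanning is dialect-agnostic.
#'
#' @param id Motif identifier.
#' @param name Motif name (defaults to the id).
#' @param counts 4 x L matrix, rownames A,C,G,T, finite non-negative.
#' @return An object of class `pwm`.
#' @export
make_pwm <- function(id, counts, name = id) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PWM ", id, ": counts must be finite and non-negative")
  }
  if (any(colSums(counts) <= 0)) {
    stop("PWM ", id, ": every position needs a positive count for some base")
  }
  structure(list(id = id, name = name, counts = counts), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d\n", x$id, x$name, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Consensus string of a PWM
#'
#' Highest-count base at each position (ties broken A<C<G<T).
#'
#' @param pwm A `pwm`.
#' @return Character scalar of length equal to the motif width.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Read PWMs in the JASPAR text dialect
#'
#' Blocks of the form `>ID name` followed by four rows
#' `A  [ 10  0  3 ]` (brackets optional), one per base.
#'
#' @param path File path.
#' @return List of `pwm` objects in file order.
#' @export
read_pwm_jaspar <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no JASPAR matrix headers ('>') found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body, function(ln) {
      base <- sub("^([ACGTacgt]).*$", "\\1", ln)
      rest <- sub("^[ACGTacgt]", "", ln)
      nums <- regmatches(rest, gregexpr("-?[0-9.]+", rest))[[1]]
      list(base = toupper(base), vals = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop("JASPAR matrix ", id, ": need exactly one row per base A,C,G,T")
    }
    widths <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(widths)) != 1) {
      stop("JASPAR matrix ", id, ": rows of unequal width")
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    pwms[[i]] <- make_pwm(id, counts[c("A", "C", "G", "T"), , drop = FALSE], name)
  }
  pwms
}

#' Read PWMs in the TRANSFAC text dialect
#'
#' Blocks with an `ID` line, a `P0  A  C  G  T` column header, numbered
#' position rows (`01  10  0  0  0  A`), terminated by `//`. An optional
#' `NA` line supplies the motif name.
#'
#' @param path File path.
#' @return List of `pwm` objects in file order.
#' @export
read_pwm_transfac <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  pwms <- list()
  id <- NULL; name <- NULL; rows <- list(); col_order <- NULL
  flush <- function() {
    if (is.null(id)) return(NULL)
    if (length(rows) == 0) stop("TRANSFAC matrix ", id, ": no position rows")
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- col_order
    make_pwm(id, counts[c("A", "C", "G", "T"), , drop = FALSE],
             if (is.null(name)) id else name)
  }
  for (ln in lines) {
    if (grepl("^ID\\b", ln)) {
      id <- strsplit(ln, "\\s+")[[1]][2]
      name <- NULL; rows <- list(); col_order <- NULL
    } else if (grepl("^NA\\b", ln)) {
      name <- sub("^NA\\s+", "", ln)
    } else if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) {
      col_order <- strsplit(ln, "\\s+")[[1]][-1]
      if (!setequal(col_order, c("A", "C", "G", "T"))) {
        stop("TRANSFAC matrix ", id, ": P0 header must list A C G T")
      }
    } else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(vals)) stop("TRANSFAC matrix ", id, ": malformed row: ", ln)
      rows[[length(rows) + 1L]] <- vals
    } else if (ln == "//") {
      p <- flush()
      if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
      id <- NULL
    }
  }
  p <- flush()
  if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
  pwms
}

#' Write PWMs in the JASPAR text dialect
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_pwm_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write PWMs in the TRANSFAC text dialect
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_pwm_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("ID", p$id), paste("NA", p$name),
                 "P0\tA\tC\tG\tT"), con)
    cons <- strsplit(pwm_consensus(p), "")[[1]]
    for (j in seq_len(ncol(p$counts))) {
      writeLines(paste(c(sprintf("%02d", j),
                         format(p$counts[, j], trim = TRUE), cons[j]),
                       collapse = "\t"), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
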