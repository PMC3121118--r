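#' Convert a count PWM to a log-odds scoring matrix
#'
#' `score(b, j) = log2( (count(b,j) + pseudocount * bg(b)) /
#' (colsum(j) + pseudocount) / bg(b) )`. The maximum (minimum) achievable
#' score is the sum over positions of the per-position maxima (minima).
#'
#' @param pwm A `pwm` object.
#' @param background Base frequencies (A, C, G, T), positive, summing to 1.
#' @param pseudocount Total pseudocount, distributed by background (> 0).
#' @return A list of class `log_odds_matrix`: `id`, `name`, `width`, `mat`
#'   (4 x L), `max_score`, `min_score`.
#' @export
pwm_to_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(pwm, "pwm"), length(background) == 4,
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  if (pseudocount <= 0) {
    if (any(colSums(pwm$counts) == 0)) {
      stop("zero column sum with zero pseudocount")
    }
    stop("pseudocount must be > 0")
  }
  bg <- stats::setNames(background, c("A", "C", "G", "T"))
  colsum <- colSums(pwm$counts)
  mat <- log2(sweep(
    sweep(pwm$counts + outer(bg, rep(1, ncol(pwm$counts))) * pseudocount,
          2, colsum + pseudocount, "/"),
    1, bg, "/"
  ))
  structure(list(id = pwm$id, name = pwm$name, width = ncol(mat), mat = mat,
                 max_score = sum(apply(mat, 2, max)),
                 min_score = sum(apply(mat, 2, min))),
            class = "log_odds_matrix")
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Forward-strand scores at every offset; windows containing N score -Inf.
score_offsets <- function(seq, lom) {
  n <- nchar(seq)
  L <- lom$width
  if (n < L) return(numeric(0))
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  n_off <- n - L + 1L
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    sc <- sc + lom$mat[cbind(code[j:(j + n_off - 1L)], j)]
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' Scan a sequence with a log-odds matrix on both strands
#'
#' Every offset on the forward sequence and on its reverse complement is
#' scored; a window qualifies when its score reaches the absolute threshold
#' `min_score + threshold_fraction * (max_score - min_score)` (a tolerance of
#' 1e-9 absorbs floating-point summation order). Reverse-complement hits are
#' reported with strand `-` and offsets mapped back to forward coordinates.
#' Windows containing N never hit.
#'
#' @param seq DNA string.
#' @param lom A `log_odds_matrix`.
#' @param threshold_fraction Fraction of the min-max score range, in (0, 1\].
#' @return Data.frame of hits: `offset` (0-based forward coordinate),
#'   `strand`, `score`, sorted by offset then strand (`+` before `-`).
#' @export
scan_sequence <- function(seq, lom, threshold_fraction = 0.8) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  thr <- lom$min_score + threshold_fraction * (lom$max_score - lom$min_score)
  n <- nchar(seq)
  L <- lom$width
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  fwd <- score_offsets(seq, lom)
  rev <- score_offsets(revcomp(seq), lom)
  hf <- which(fwd >= thr - 1e-9)
  hr <- which(rev >= thr - 1e-9)
  hits <- rbind(
    if (length(hf)) data.frame(offset = hf - 1L, strand = "+",
                               score = fwd[hf], stringsAsFactors = FALSE),
    if (length(hr)) data.frame(offset = n - (hr - 1L) - L, strand = "-",
                               score = rev[hr], stringsAsFactors = FALSE)
  )
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of promoter regions with one matrix
#'
#' @param regions Promoter data.frame with `seq`.
#' @param lom A `log_odds_matrix`.
#' @param threshold_fraction See [scan_sequence()].
#' @return Data.frame of hits with a leading `region_id` column.
#' @export
scan_regions <- function(regions, lom, threshold_fraction = 0.8) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    h <- scan_sequence(regions$seq[i], lom, threshold_fraction)
    if (nrow(h) == 0) return(NULL)
    cbind(region_id = regions$region_id[i], motif_id = lom$id, h,
          stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(region_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Hits per kilobase of promoter sequence
#'
#' @param n_hits Total hit count across regions.
#' @param regions The scanned regions (for total length).
#' @return Hits per kb.
#' @export
normalized_count <- function(n_hits, regions) {
  total <- sum(regions$end - regions$start)
  if (total <= 0) stop("zero total region length")
  n_hits / (total / 1000)
}

#' Classify a motif's fold enrichment
#'
#' fold = bidirectional rate / uni-directional rate. A fold at or above
#' `threshold` is over-represented, at or below `1/threshold`
#' under-represented, otherwise shared. A zero uni rate with positive bidir
#' rate gives infinite fold (over-represented); both-zero is reported as
#' shared with `both_zero = TRUE` so tables keep one row per motif.
#'
#' @param bidir_rate,uni_rate Normalised hit rates (>= 0).
#' @param threshold Fold threshold (default 2).
#' @return List: `fold`, `category`, `both_zero`.
#' @export
classify_fold <- function(bidir_rate, uni_rate, threshold = 2.0) {
  if (bidir_rate < 0 || uni_rate < 0) stop("rates must be non-negative")
  if (bidir_rate == 0 && uni_rate == 0) {
    return(list(fold = NA_real_, category = "shared", both_zero = TRUE))
  }
  fold <- if (uni_rate == 0) Inf else bidir_rate / uni_rate
  category <- if (fold >= threshold) "over-represented"
              else if (fold <= 1 / threshold) "under-represented"
              else "shared"
  list(fold = fold, category = category, both_zero = FALSE)
}

#' Motif fold-enrichment table
#'
#' Scans both promoter classes with every PWM and classifies each motif as
#' over-represented, shared or under-represented in bidirectional promoters
#' at the fold threshold. Normalisation is hits per kb of total promoter
#' sequence by default, or hits per promoter.
#'
#' @param bidir_regions,uni_regions Promoter data.frames with sequences.
#' @param pwms List of `pwm` objects.
#' @param threshold_fraction PWM score threshold fraction (default 0.8).
#' @param fold_threshold Fold threshold (default 2).
#' @param background,pseudocount Passed to [pwm_to_log_odds()].
#' @param normalization `"per-kb"` or `"per-promoter"`.
#' @return Data.frame, one row per PWM, sorted by fold descending:
#'   `motif_id`, `name`, `bidir_rate`, `uni_rate`, `fold`, `category`,
#'   `both_zero`, `too_wide` (PWM wider than every promoter).
#' @export
enrichment_table <- function(bidir_regions, uni_regions, pwms,
                             threshold_fraction = 0.8, fold_threshold = 2.0,
                             background = rep(0.25, 4), pseudocount = 0.8,
                             normalization = c("per-kb", "per-promoter")) {
  normalization <- match.arg(normalization)
  stopifnot(nrow(bidir_regions) > 0, nrow(uni_regions) > 0,
            !is.null(bidir_regions$seq), !is.null(uni_regions$seq))
  rate <- function(n_hits, regions) {
    if (normalization == "per-kb") normalized_count(n_hits, regions)
    else n_hits / nrow(regions)
  }
  rows <- lapply(pwms, function(p) {
    lom <- pwm_to_log_odds(p, background, pseudocount)
    too_wide <- lom$width > max(nchar(bidir_regions$seq)) &&
                lom$width > max(nchar(uni_regions$seq))
    hb <- nrow(scan_regions(bidir_regions, lom, threshold_fraction))
    hu <- nrow(scan_regions(uni_regions, lom, threshold_fraction))
    cf <- classify_fold(rate(hb, bidir_regions), rate(hu, uni_regions),
                        fold_threshold)
    data.frame(motif_id = p$id, name = p$name,
               bidir_rate = rate(hb, bidir_regions),
               uni_rate = rate(hu, uni_regions),
               fold = cf$fold, category = cf$category,
               both_zero = cf$both_zero, too_wide = too_wide,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$fold), -Inf, tab$fold), tab$motif_id), ]
  rownames(tab) <- NULL
  tab
}

#' Overlap of over-represented motifs between two collections
#'
#' Intersection by motif name, case-insensitive — the cross-database
#' comparison of over-represented TFBS sets.
#'
#' @param table1,table2 Enrichment tables from [enrichment_table()].
#' @return Character vector of shared over-represented motif names
#'   (lower-cased).
#' @export
overrepresented_overlap <- function(table1, table2) {
  over <- function(tab) tolower(tab$name[tab$category == "over-represented"])
  sort(intersect(over(table1), over(table2)))
}
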