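#' CpG island criteria presets
#'
#' Two named criteria sets: the classic Gardiner-Garden definition
#' (GC >= 0.50, Obs/Exp >= 0.60, length >= 500 bp) and a stricter variant
#' raising the GC threshold to 0.55.
#'
#' @param name `"gardiner_garden"` or `"strict"`, or omit and supply the
#'   thresholds directly.
#' @param min_gc Minimum GC fraction.
#' @param min_obs_exp Minimum CpG observed/expected ratio.
#' @param min_length Minimum island length in bp.
#' @return A list of class `cpg_criteria`.
#' @export
cpg_criteria <- function(name = c("gardiner_garden", "strict"),
                         min_gc = NULL, min_obs_exp = 0.60, min_length = 500L) {
  if (is.null(min_gc)) {
    name <- match.arg(name)
    min_gc <- switch(name, gardiner_garden = 0.50, strict = 0.55)
  } else {
    name <- if (is.character(name) && length(name) == 1 &&
                !name[1] %in% c("gardiner_garden", "strict")) name else "custom"
    if (identical(name, c("gardiner_garden", "strict"))) name <- "custom"
  }
  stopifnot(min_gc > 0, min_gc <= 1, min_obs_exp > 0, min_length >= 1)
  structure(list(name = name, min_gc = min_gc, min_obs_exp = min_obs_exp,
                 min_length = as.integer(min_length)), class = "cpg_criteria")
}

#' GC content of a sequence
#'
#' (#C + #G) / (#A + #C + #G + #T); N bases are excluded from both numerator
#' and denominator. An all-N sequence yields 0 with a warning.
#'
#' @param seq DNA string over A,C,G,T,N.
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("gc_content needs one non-empty sequence")
  }
  b <- base_counts(seq)
  denom <- sum(b[c("A", "C", "G", "T")])
  if (denom == 0) {
    warning("all-N sequence: GC content reported as 0")
    return(0)
  }
  (b[["C"]] + b[["G"]]) / denom
}

#' CpG observed/expected ratio
#'
#' Gardiner-Garden definition: `Obs/Exp = #CpG * L / (#C * #G)` with L the
#' sequence length excluding N. `#CpG` counts occurrences of the dinucleotide
#' CG on the forward strand; an N between C and G breaks the dinucleotide.
#' When the sequence has no C or no G the expected count is zero and the
#' ratio is defined as 0 (never a division error).
#'
#' @param seq DNA string over A,C,G,T,N.
#' @return Observed/expected CpG ratio (>= 0).
#' @export
cpg_obs_exp <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("cpg_obs_exp needs one non-empty sequence")
  }
  b <- base_counts(seq)
  if (b[["C"]] == 0 || b[["G"]] == 0) return(0)
  L <- sum(b[c("A", "C", "G", "T")])
  n_cpg <- count_cpg(seq)
  n_cpg * L / (b[["C"]] * b[["G"]])
}

base_counts <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
    T = sum(v == "T"), N = sum(v == "N"))
}

count_cpg <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  if (length(v) < 2) return(0L)
  sum(v[-length(v)] == "C" & v[-1] == "G")
}

# Per-window GC and Obs/Exp over [a, b] (1-based closed), from cumulative
# sums; used by the sliding-window scan and the verify-trim step so both see
# bit-identical statistics.
region_stats <- function(cums, a, b) {
  at <- function(x, i) if (i == 0) 0 else x[i]
  nC <- at(cums$C, b) - at(cums$C, a - 1)
  nG <- at(cums$G, b) - at(cums$G, a - 1)
  nN <- at(cums$N, b) - at(cums$N, a - 1)
  L <- (b - a + 1) - nN
  gc <- if (L == 0) 0 else (nC + nG) / L
  # CpG at position i spans bases i, i+1; count those fully inside [a, b]
  ncpg <- if (b - a < 1) 0 else at(cums$CG, b - 1) - at(cums$CG, a - 1)
  oe <- if (nC == 0 || nG == 0) 0 else ncpg * L / (nC * nG)
  list(gc = gc, obs_exp = oe)
}

seq_cumsums <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  cg <- if (n < 2) numeric(0) else cumsum(v[-n] == "C" & v[-1] == "G")
  list(C = cumsum(v == "C"), G = cumsum(v == "G"), N = cumsum(v == "N"),
       CG = cg)
}

#' Find CpG islands in a sequence
#'
#' Sliding-window island caller, pinned for reproducibility:
#' \enumerate{
#'   \item slide a window of exactly `min_length` bp in 1-bp steps and mark
#'     windows meeting both the GC and Obs/Exp thresholds;
#'   \item merge overlapping or abutting marked windows into candidates;
#'   \item verify each merged candidate as a whole; if it fails, trim 1 bp at
#'     a time from whichever end most improves the failing statistic (GC is
#'     checked before Obs/Exp; ties trim left) until it qualifies or drops
#'     below `min_length` (then discard);
#'   \item report the surviving maximal disjoint regions left to right.
#' }
#'
#' @param seq DNA string over A,C,G,T,N.
#' @param criteria A `cpg_criteria` object.
#' @return Data.frame with columns `start`, `end` (0-based half-open, local
#'   to `seq`), `gc`, `obs_exp`, `criteria`.
#' @export
find_cpg_islands <- function(seq, criteria = cpg_criteria("gardiner_garden")) {
  stopifnot(inherits(criteria, "cpg_criteria"))
  empty <- data.frame(start = integer(), end = integer(), gc = numeric(),
                      obs_exp = numeric(), criteria = character(),
                      stringsAsFactors = FALSE)
  n <- nchar(seq)
  L <- criteria$min_length
  if (n < L) return(empty)
  cums <- seq_cumsums(seq)
  starts <- seq_len(n - L + 1L)
  # window stats via cumulative sums (identical arithmetic to region_stats)
  at0 <- function(x, i) c(0, x)[i + 1L]
  nC <- at0(cums$C, starts + L - 1L) - at0(cums$C, starts - 1L)
  nG <- at0(cums$G, starts + L - 1L) - at0(cums$G, starts - 1L)
  nN <- at0(cums$N, starts + L - 1L) - at0(cums$N, starts - 1L)
  Leff <- L - nN
  gc <- ifelse(Leff == 0, 0, (nC + nG) / Leff)
  ncpg <- at0(cums$CG, starts + L - 2L) - at0(cums$CG, starts - 1L)
  oe <- ifelse(nC == 0 | nG == 0, 0, ncpg * Leff / (nC * nG))
  ok <- gc >= criteria$min_gc & oe >= criteria$min_obs_exp
  if (!any(ok)) return(empty)
  # merge overlapping/abutting marked windows: marked starts s1 <= s2 merge
  # when s2 <= s1_end + 1, i.e. consecutive marked runs within L of each other
  ms <- starts[ok]
  brk <- c(TRUE, diff(ms) > L)
  grp <- cumsum(brk)
  out <- list()
  for (g in unique(grp)) {
    s <- ms[grp == g]
    isl <- verify_trim(cums, min(s), max(s) + L - 1L, criteria)
    if (!is.null(isl)) out[[length(out) + 1L]] <- isl
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  df$criteria <- criteria$name
  df
}

# Step-3 verification: [a, b] 1-based closed candidate; returns a one-row
# data.frame (0-based half-open) or NULL if the candidate is discarded.
verify_trim <- function(cums, a, b, criteria) {
  repeat {
    if (b - a + 1 < criteria$min_length) return(NULL)
    st <- region_stats(cums, a, b)
    gc_ok <- st$gc >= criteria$min_gc
    oe_ok <- st$obs_exp >= criteria$min_obs_exp
    if (gc_ok && oe_ok) {
      return(data.frame(start = a - 1L, end = b, gc = st$gc,
                        obs_exp = st$obs_exp, stringsAsFactors = FALSE))
    }
    left <- region_stats(cums, a + 1L, b)
    right <- region_stats(cums, a, b - 1L)
    if (!gc_ok) {
      if (left$gc >= right$gc) a <- a + 1L else b <- b - 1L
    } else {
      if (left$obs_exp >= right$obs_exp) a <- a + 1L else b <- b - 1L
    }
  }
}

#' Summarise CpG islands by promoter class
#'
#' @param bidir_regions,uni_regions Promoter data.frames with sequences.
#' @param bidir_islands,uni_islands Island tables (one row per island, with a
#'   `region_id` column), computed under one criteria set.
#' @return A list with `by_class` (per-class promoter count, count with at
#'   least one island, fraction with island, islands per promoter, islands
#'   per kb, mean GC) and `difference` (bidirectional minus uni-directional,
#'   for the numeric summaries). Fractions for an empty class are `NA`.
#' @export
summarize_by_class <- function(bidir_regions, bidir_islands,
                               uni_regions, uni_islands) {
  one <- function(regions, islands, class) {
    n <- nrow(regions)
    if (n == 0) {
      return(data.frame(class = class, n_promoters = 0L, n_with_island = 0L,
                        fraction_with_island = NA_real_,
                        islands_per_promoter = NA_real_,
                        islands_per_kb = NA_real_, mean_gc = NA_real_,
                        stringsAsFactors = FALSE))
    }
    with_isl <- length(intersect(regions$region_id, islands$region_id))
    total_kb <- sum(regions$end - regions$start) / 1000
    data.frame(
      class = class, n_promoters = n, n_with_island = with_isl,
      fraction_with_island = with_isl / n,
      islands_per_promoter = nrow(islands) / n,
      islands_per_kb = nrow(islands) / total_kb,
      mean_gc = mean(vapply(regions$seq, gc_content, 0)),
      stringsAsFactors = FALSE
    )
  }
  by_class <- rbind(one(bidir_regions, bidir_islands, "bidirectional"),
                    one(uni_regions, uni_islands, "unidirectional"))
  num <- c("fraction_with_island", "islands_per_promoter", "islands_per_kb",
           "mean_gc")
  diff <- unlist(by_class[1, num]) - unlist(by_class[2, num])
  list(by_class = by_class, difference = diff)
}

#' Call CpG islands across a set of promoter regions
#'
#' @param regions Promoter data.frame with a `seq` column.
#' @param criteria A `cpg_criteria` object.
#' @return Island data.frame with a leading `region_id` column; intervals are
#'   local to each region (0-based half-open).
#' @export
find_cpg_islands_regions <- function(regions, criteria) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    isl <- find_cpg_islands(regions$seq[i], criteria)
    if (nrow(isl) == 0) return(NULL)
    cbind(region_id = regions$region_id[i], isl, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(region_id = character(), start = integer(),
                      end = integer(), gc = numeric(), obs_exp = numeric(),
                      criteria = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
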