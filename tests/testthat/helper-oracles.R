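# Independent brute-force oracles and small fixture builders. These recompute
# everything naively (per-window recounts, exhaustive enumeration, O(n^2)
# pair search) so they share no code path with the package implementations.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# naive composition statistics on a character vector slice
naive_stats <- function(v) {
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  nC <- sum(v == "C"); nG <- sum(v == "G")
  gc <- if (acgt == 0) 0 else (nC + nG) / acgt
  ncpg <- if (length(v) < 2) 0 else sum(v[-length(v)] == "C" & v[-1] == "G")
  oe <- if (nC == 0 || nG == 0) 0 else ncpg * acgt / (nC * nG)
  list(gc = gc, obs_exp = oe)
}

# Exhaustive window oracle for CpG islands: recount every min_length window
# naively, union qualifying windows into candidates, then apply the
# verify-trim rule (greedy best-end, GC before Obs/Exp, ties left) with
# per-step naive recounts. Returns covered 1-based positions.
cpg_oracle_covered <- function(seq, min_gc, min_obs_exp, min_length) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  if (n < min_length) return(integer(0))
  ok <- vapply(seq_len(n - min_length + 1L), function(s) {
    st <- naive_stats(v[s:(s + min_length - 1L)])
    st$gc >= min_gc && st$obs_exp >= min_obs_exp
  }, logical(1))
  if (!any(ok)) return(integer(0))
  ms <- which(ok)
  grp <- cumsum(c(TRUE, diff(ms) > min_length))
  covered <- integer(0)
  for (g in unique(grp)) {
    s <- ms[grp == g]
    a <- min(s); b <- max(s) + min_length - 1L
    repeat {
      if (b - a + 1 < min_length) { a <- NA; break }
      st <- naive_stats(v[a:b])
      if (st$gc >= min_gc && st$obs_exp >= min_obs_exp) break
      lft <- naive_stats(v[(a + 1L):b])
      rgt <- naive_stats(v[a:(b - 1L)])
      if (st$gc < min_gc) {
        if (lft$gc >= rgt$gc) a <- a + 1L else b <- b - 1L
      } else {
        if (lft$obs_exp >= rgt$obs_exp) a <- a + 1L else b <- b - 1L
      }
    }
    if (!is.na(a)) covered <- c(covered, a:b)
  }
  sort(unique(covered))
}

# Exhaustive draw-enumeration distribution of the hypergeometric overlap:
# P(X >= k) by counting all C(N, n) draws with at least k marked elements.
hyper_enum_upper <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Per-offset brute-force PWM scan on both strands (independent loops; same
# ascending-position summation order as the contract pins).
scan_oracle <- function(seq, lom, threshold_fraction) {
  thr <- lom$min_score + threshold_fraction * (lom$max_score - lom$min_score)
  score_at <- function(v, s) {
    total <- 0
    for (j in seq_len(lom$width)) {
      b <- v[s + j - 1L]
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      total <- total + lom$mat[b, j]
    }
    total
  }
  n <- nchar(seq)
  if (n < lom$width) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  v <- strsplit(seq, "")[[1]]
  rc <- strsplit(revcomp(seq), "")[[1]]
  hits <- list()
  for (s in seq_len(n - lom$width + 1L)) {
    sc <- score_at(v, s)
    if (sc >= thr - 1e-9) {
      hits[[length(hits) + 1L]] <- data.frame(
        offset = s - 1L, strand = "+", score = sc, stringsAsFactors = FALSE)
    }
    sc <- score_at(rc, s)
    if (sc >= thr - 1e-9) {
      hits[[length(hits) + 1L]] <- data.frame(
        offset = n - (s - 1L) - lom$width, strand = "-", score = sc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# O(n^2) brute-force bidirectional pair search over all cluster pairs.
pairs_oracle <- function(clusters, max_distance = 1000L) {
  found <- list()
  n <- nrow(clusters)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- clusters[i, ]; p <- clusters[j, ]
    if (m$strand != "-" || p$strand != "+") next
    if (m$chrom != p$chrom) next
    d <- p$tss - m$tss
    if (d < 0 || d >= max_distance) next
    between <- clusters$chrom == m$chrom &
      clusters$tss > m$tss & clusters$tss < p$tss
    if (any(between)) next
    found[[length(found) + 1L]] <- paste(m$chrom, m$cluster_id, p$cluster_id)
  }
  out <- unlist(found)
  if (is.null(out)) character(0) else sort(out)
}

# quick cluster table builder for hand layouts
make_clusters <- function(df) {
  df$cluster_id <- sprintf("CL%05d", seq_len(nrow(df)))
  df$gene_symbol <- if (is.null(df$gene_symbol))
    sprintf("G%03d", seq_len(nrow(df))) else df$gene_symbol
  df$tss <- tss_of(df$strand, df$start, df$end)
  df$evidence_class <- if (is.null(df$evidence_class)) "curated-mRNA"
                       else df$evidence_class
  df
}

# sequence with a high-CpG block planted between AT-rich flanks
planted_cpg_seq <- function(flank = 250, block = 500) {
  paste0(paste(rep("AT", ceiling(flank / 2)), collapse = ""),
         paste(rep("CG", ceiling(block / 2)), collapse = ""),
         paste(rep("AT", ceiling(flank / 2)), collapse = ""))
}
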