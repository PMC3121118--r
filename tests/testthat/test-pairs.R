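test_that("TSS is the 5'-most coordinate under the half-open convention", {
  expect_equal(tss_of("+", 1000L, 5000L), 1000L)
  expect_equal(tss_of("-", 200L, 800L), 800L)
  expect_equal(tss_of("+", 7L, 8L), 7L)
  expect_error(tss_of("*", 0L, 1L))
})

tx <- function(acc, sym, chrom, strand, s, e) {
  data.frame(accession = acc, gene_symbol = sym, chrom = chrom,
             strand = strand, tx_start = s, tx_end = e,
             evidence_class = evidence_class(acc), stringsAsFactors = FALSE)
}

test_that("cluster collapse merges overlapping and abutting same-strand spans", {
  rec <- rbind(tx("NM_1", "a", "chr1", "+", 100L, 500L),
               tx("NM_2", "b", "chr1", "+", 400L, 900L))
  cl <- collapse_clusters(rec)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 900L)
  expect_equal(cl$tss, 100L)
  expect_equal(cl$gene_symbol, "a")

  # strands never merge
  rec <- rbind(tx("NM_1", "a", "chr1", "+", 100L, 500L),
               tx("NM_2", "b", "chr1", "-", 100L, 500L))
  expect_equal(nrow(collapse_clusters(rec)), 2)

  # abutting merge, disjoint stays apart
  rec <- rbind(tx("NM_1", "a", "chr1", "+", 0L, 10L),
               tx("NM_2", "b", "chr1", "+", 10L, 20L),
               tx("NM_3", "c", "chr1", "+", 30L, 40L))
  cl <- collapse_clusters(rec)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(0L, 30L))
  expect_equal(cl$end, c(20L, 40L))
})

test_that("cluster collapse matches an interval-union oracle on random input", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 30
    s <- sample(0:5000, n, replace = TRUE)
    rec <- do.call(rbind, lapply(seq_len(n), function(i) {
      tx(sprintf("NM_%03d", i), sprintf("g%03d", i), "chr1",
         sample(c("+", "-"), 1), s[i], s[i] + sample(50:800, 1))
    }))
    cl <- collapse_clusters(rec)
    # oracle: sweep the sorted endpoint list per strand
    for (std in c("+", "-")) {
      r <- rec[rec$strand == std, ]
      r <- r[order(r$tx_start), ]
      merged <- list()
      cur <- NULL
      for (i in seq_len(nrow(r))) {
        if (is.null(cur) || r$tx_start[i] > cur[2]) {
          cur <- c(r$tx_start[i], r$tx_end[i])
          merged[[length(merged) + 1L]] <- cur
        } else {
          cur[2] <- max(cur[2], r$tx_end[i])
          merged[[length(merged)]] <- cur
        }
      }
      got <- cl[cl$strand == std, c("start", "end")]
      exp <- do.call(rbind, merged)
      expect_equal(unname(as.matrix(got)), unname(exp))
    }
    # cluster evidence class is the best among members
    expect_true(all(cl$evidence_class == "curated-mRNA"))
  }
})

test_that("evidence filtering distinguishes all / curated / curated-mRNA", {
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = "+",
    start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L),
    evidence_class = c("curated-mRNA", "curated-noncoding", "predicted", "other"),
    stringsAsFactors = FALSE))
  expect_equal(filter_evidence(cl, "curated-mRNA")$evidence_class, "curated-mRNA")
  expect_setequal(filter_evidence(cl, "curated")$evidence_class,
                  c("curated-mRNA", "curated-noncoding"))
  # predicted models are excluded even in "all" mode
  expect_setequal(filter_evidence(cl, "all")$evidence_class,
                  c("curated-mRNA", "curated-noncoding", "other"))
  expect_equal(nrow(filter_evidence(cl[0, ], "all")), 0)
  expect_error(filter_evidence(cl, "everything"))
})

test_that("bidirectional classification obeys geometry and the strict distance bound", {
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = c("-", "+"),
    start = c(5000L, 10500L), end = c(10000L, 15500L),
    stringsAsFactors = FALSE))
  p <- classify_bidirectional(cl)
  expect_equal(nrow(p), 1)
  expect_equal(p$distance, 500L)
  expect_equal(p$ig_start, 10000L)
  expect_equal(p$ig_end, 10500L)

  # boundary exactness: distance max-1 pairs, distance max does not
  cl$start[2] <- 10999L; cl$end[2] <- 15999L
  cl$tss <- tss_of(cl$strand, cl$start, cl$end)
  expect_equal(classify_bidirectional(cl)$distance, 999L)
  cl$start[2] <- 11000L
  cl$tss <- tss_of(cl$strand, cl$start, cl$end)
  expect_equal(nrow(classify_bidirectional(cl)), 0)

  # convergent orientation (5' ends face away) is never a pair
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = c("+", "-"),
    start = c(10000L, 10500L), end = c(10400L, 10900L),
    stringsAsFactors = FALSE))
  expect_equal(nrow(classify_bidirectional(cl)), 0)
})

test_that("bidirectional classification agrees with the O(n^2) oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    tss <- sample(0:20000, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cl <- make_clusters(data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE), strand = strand,
      start = ifelse(strand == "+", tss, pmax(tss - 500L, 0L)),
      end = ifelse(strand == "+", tss + 500L, tss),
      stringsAsFactors = FALSE))
    got <- classify_bidirectional(cl)
    got_keys <- sort(paste(got$chrom, got$minus_cluster, got$plus_cluster))
    expect_equal(got_keys, pairs_oracle(cl))
  }
})

test_that("unidirectional classification applies both upstream windows", {
  iso <- make_clusters(data.frame(
    chrom = "chr1", strand = c("+", "+"),
    start = c(100000L, 150000L), end = c(105000L, 155000L),
    stringsAsFactors = FALSE))
  expect_equal(nrow(classify_unidirectional(iso)), 2)

  # opposite-strand TSS 9 kb upstream violates the 10 kb rule
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = c("+", "-"),
    start = c(100000L, 86000L), end = c(105000L, 91000L),
    stringsAsFactors = FALSE))
  expect_false("G001" %in% classify_unidirectional(cl)$gene_symbol)

  # boundary: opposite TSS exactly 10 kb upstream still violates; 10 kb + 1 is clear
  cl$end[2] <- 90000L; cl$start[2] <- 85000L
  cl$tss <- tss_of(cl$strand, cl$start, cl$end)
  expect_false(any(classify_unidirectional(cl)$strand == "+"))
  cl$end[2] <- 89999L; cl$start[2] <- 84999L
  cl$tss <- tss_of(cl$strand, cl$start, cl$end)
  expect_true(any(classify_unidirectional(cl)$strand == "+"))

  # same-strand TSS 1.5 kb upstream is allowed, exactly 1 kb is not
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = c("+", "+"),
    start = c(100000L, 98500L), end = c(105000L, 98900L),
    stringsAsFactors = FALSE))
  expect_equal(nrow(classify_unidirectional(cl)), 2)
  cl$start[2] <- 99000L; cl$end[2] <- 99400L; cl$tss[2] <- 99000L
  uni <- classify_unidirectional(cl)
  expect_false(100000L %in% uni$tss)
})

test_that("pair members are never classified unidirectional", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 40
    tss <- sample(0:60000, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cl <- make_clusters(data.frame(
      chrom = "chr1", strand = strand,
      start = ifelse(strand == "+", tss, pmax(tss - 300L, 0L)),
      end = ifelse(strand == "+", tss + 300L, tss),
      stringsAsFactors = FALSE))
    p <- classify_bidirectional(cl)
    u <- classify_unidirectional(cl)
    members <- c(p$minus_cluster, p$plus_cluster)
    expect_length(intersect(members, u$cluster_id), 0)
  }
})

test_that("pair deduplication keeps one pair per intergenic interval", {
  pairs <- data.frame(
    pair_id = c("p1", "p2", "p3"), chrom = "chr1",
    minus_cluster = c("c1", "c2", "c3"),
    minus_symbol = c("mB", "mA", "mC"),
    minus_tss = 100L,
    plus_cluster = c("c4", "c5", "c6"),
    plus_symbol = c("pA", "pA", "pB"),
    plus_tss = 600L, distance = 500L,
    ig_start = c(100L, 100L, 100L), ig_end = c(600L, 600L, 601L),
    stringsAsFactors = FALSE)
  dd <- deduplicate_pairs(pairs)
  expect_equal(nrow(dd), 2)
  # among the two [100,600) duplicates, (pA, mA) sorts before (pA, mB)
  expect_setequal(dd$minus_symbol, c("mA", "mC"))
  expect_equal(nrow(deduplicate_pairs(pairs[0, ])), 0)
})

test_that("classification is deterministic on identical input", {
  set.seed(5)
  n <- 30
  tss <- sample(0:30000, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cl <- make_clusters(data.frame(
    chrom = "chr1", strand = strand,
    start = ifelse(strand == "+", tss, pmax(tss - 400L, 0L)),
    end = ifelse(strand == "+", tss + 400L, tss),
    stringsAsFactors = FALSE))
  expect_identical(classify_bidirectional(cl), classify_bidirectional(cl))
  expect_identical(classify_unidirectional(cl), classify_unidirectional(cl))
})
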